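#' Events competing with relapse
#'
#' Death in first clinical remission (DCR1), secondary malignancy (SMN)
#' and resistant disease preclude observing relapse and are treated as
#' competing risks; `CR1` (still in first remission at last follow-up)
#' is censoring.
#'
#' @export
COMPETING_EVENTS <- c("DCR1", "SMN", "resistant")

#' Build a survival record table from patient metadata
#'
#' @param patients patient metadata.
#' @return data.frame patient_id, time (years), event (one of relapse,
#'   DCR1, SMN, resistant, censored).
#' @export
survival_records <- function(patients) {
  ev <- ifelse(patients$outcome == "CR1", "censored", patients$outcome)
  data.frame(patient_id = patients$patient_id,
             time = patients$time_to_event_years,
             event = ev, stringsAsFactors = FALSE)
}

check_survival_records <- function(records) {
  stopifnot(all(c("patient_id", "time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("non-positive follow-up time")
  if (anyDuplicated(records$patient_id)) stop("one record per patient required")
  bad <- setdiff(records$event, c("relapse", COMPETING_EVENTS, "censored"))
  if (length(bad)) stop("unknown event label: ", bad[1])
  records
}

#' Aalen-Johansen cumulative incidence of one event type
#'
#' The cumulative incidence function (CIF) accounts for competing
#' events: its increment at each event time is the overall
#' event-free-survival just before that time multiplied by the
#' cause-specific hazard. Computed via a multistate product-limit fit
#' (`survival::survfit`); at tied times events precede censorings.
#'
#' @param records survival records (see [survival_records()]).
#' @param event_of_interest event whose CIF is requested (default
#'   `"relapse"`).
#' @return object of class `cif_estimate`: data.frame with `time`,
#'   `cif` (non-decreasing, in \[0,1\]) and `n_risk`, plus the event
#'   type as attribute.
#' @export
cumulative_incidence <- function(records, event_of_interest = "relapse") {
  records <- check_survival_records(records)
  states <- unique(records$event[records$event != "censored"])
  f <- factor(records$event, levels = c("censored", states))
  times <- sort(unique(records$time))
  n_risk <- vapply(times, function(t) sum(records$time >= t), 0L)
  if (!event_of_interest %in% states) {
    out <- data.frame(time = times, cif = 0, n_risk = n_risk)
  } else {
    fit <- survival::survfit(survival::Surv(records$time, f) ~ 1)
    col <- match(event_of_interest, fit$states)
    out <- data.frame(time = fit$time, cif = fit$pstate[, col],
                      n_risk = vapply(fit$time,
                                      function(t) sum(records$time >= t), 0L))
  }
  structure(out, event = event_of_interest, class = c("cif_estimate",
                                                      class(out)))
}

gray_fstatus <- function(records, event_of_interest) {
  ifelse(records$event == event_of_interest, 1L,
         ifelse(records$event == "censored", 0L, 2L))
}

#' Gray's K-sample test for equality of cumulative incidence functions
#'
#' Compares the subdistribution hazards of the event of interest across
#' groups (Gray 1988), with a chi-square reference on k - 1 degrees of
#' freedom. A permutation mode re-computes the statistic under random
#' (or, for two small groups, all) relabelings of the group assignment
#' and reports the permutation tail probability instead of the
#' asymptotic one.
#'
#' @param records survival records.
#' @param group group label per record (>= 2 non-empty groups).
#' @param event_of_interest default `"relapse"`.
#' @param rho weighting parameter of the Gray family (0 = standard).
#' @param mode `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutations for permutation mode.
#' @param exact in permutation mode with two groups, enumerate all
#'   assignments when their number is at most `max_exact`.
#' @param max_exact enumeration cap.
#' @param seed RNG seed for Monte-Carlo permutations.
#' @return object of class `gray_result`: list with `statistic`, `df`,
#'   `p`, `n_groups`, `mode`.
#' @export
gray_test <- function(records, group, event_of_interest = "relapse",
                      rho = 0, mode = c("asymptotic", "permutation"),
                      n_perm = 1000L, exact = TRUE, max_exact = 20000L,
                      seed = 1L) {
  mode <- match.arg(mode)
  records <- check_survival_records(records)
  group <- as.character(group)
  stopifnot(length(group) == nrow(records))
  tab <- table(group)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab == 0)) stop("empty group")
  fstatus <- gray_fstatus(records, event_of_interest)
  if (!any(fstatus == 1L))
    stop("no events of interest: all events are competing or censored")
  stat_fun <- function(g) {
    ci <- cmprsk::cuminc(records$time, fstatus, g, rho = rho, cencode = 0L)
    tests <- ci$Tests
    tests["1", , drop = TRUE]
  }
  obs <- stat_fun(group)
  res <- list(statistic = unname(obs["stat"]), df = unname(obs["df"]),
              p = unname(obs["pv"]), n_groups = length(tab), mode = mode)
  if (mode == "permutation") {
    labels <- names(tab)
    stat_of <- function(g) stat_fun(g)["stat"]
    if (exact && length(tab) == 2 &&
        choose(sum(tab), tab[1]) <= max_exact) {
      idx <- utils::combn(length(group), tab[1])
      stats_perm <- apply(idx, 2, function(i) {
        g <- rep(labels[2], length(group)); g[i] <- labels[1]
        stat_of(g)
      })
      res$p <- mean(stats_perm >= res$statistic - 1e-12)
      res$mode <- "exact-permutation"
    } else {
      old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
      set.seed(seed)
      hits <- 0L
      for (b in seq_len(n_perm))
        if (stat_of(sample(group)) >= res$statistic - 1e-12) hits <- hits + 1L
      res$p <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(res, class = "gray_result")
}

#' @export
print.gray_result <- function(x, ...) {
  cat(sprintf("Gray's test: chi2 = %.4g, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p, x$mode))
  invisible(x)
}

#' Collapse gene-level mutations to per-patient pathway flags
#'
#' A patient is mutated in a pathway iff they carry at least one
#' non-silent mutation in any member gene. Genes absent from the map are
#' ignored; their count is returned as attribute `n_unmapped`.
#'
#' @param mutations mutation records.
#' @param pathway_map data.frame with columns `gene` and `pathway` (a
#'   KEGG-like many-to-many map).
#' @return data.frame of unique (patient_id, pathway) pairs.
#' @export
pathway_collapse <- function(mutations, pathway_map) {
  stopifnot(all(c("gene", "pathway") %in% names(pathway_map)))
  ns <- mutations[classify_non_silent(mutations), , drop = FALSE]
  merged <- merge(ns[, c("patient_id", "gene")], pathway_map, by = "gene")
  unmapped <- setdiff(unique(ns$gene[!is.na(ns$gene)]), pathway_map$gene)
  out <- unique(merged[, c("patient_id", "pathway")])
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Patient subgroups for the relapse association screen
#'
#' @param patients patient metadata.
#' @return named list of patient-id vectors: complete, T-ALL, BCP-ALL,
#'   HeH, t(12;21), normal.
#' @export
survival_subgroups <- function(patients) {
  bcp <- patients$immunophenotype == "BCP"
  list(
    complete = patients$patient_id,
    "T-ALL" = patients$patient_id[patients$subtype == "T-ALL"],
    "BCP-ALL" = patients$patient_id[bcp],
    "HeH" = patients$patient_id[bcp & patients$subtype == "HeH"],
    "t(12;21)" = patients$patient_id[bcp & patients$subtype == "t(12;21)"],
    "normal" = patients$patient_id[bcp & patients$subtype == "normal"])
}

#' Screen genes or pathways for association with relapse
#'
#' Within one patient subgroup, infants (< 1 year at diagnosis) are
#' excluded, then every gene (or pathway) with non-silent mutations in
#' at least `min_mutated` patients is tested by Gray's test comparing
#' mutated vs non-mutated patients, with Bonferroni correction over the
#' number of units actually tested in that subgroup.
#'
#' @param mutations mutation records (diagnostic timepoint; non-silent
#'   filter applied internally).
#' @param patients patient metadata.
#' @param unit `"gene"` or `"pathway"`.
#' @param pathway_map required when `unit = "pathway"`.
#' @param min_mutated minimum mutated patients per unit (default 5).
#' @param subgroup one of the names of [survival_subgroups()].
#' @param event_of_interest default `"relapse"`.
#' @param rho Gray weighting parameter.
#' @return data.frame: unit, n_mutated, statistic, p, bonferroni_p, m.
#' @export
relapse_screen <- function(mutations, patients, unit = c("gene", "pathway"),
                           pathway_map = NULL, min_mutated = 5L,
                           subgroup = "complete",
                           event_of_interest = "relapse", rho = 0) {
  unit <- match.arg(unit)
  ids <- survival_subgroups(patients)[[subgroup]]
  if (is.null(ids)) stop("unknown subgroup: ", subgroup)
  pts <- patients[patients$patient_id %in% ids & patients$age_years >= 1, ,
                  drop = FALSE]
  if (!nrow(pts)) stop("empty subgroup after filters")
  mut <- mutations[mutations$patient_id %in% pts$patient_id &
                     mutations$timepoint == "diagnosis" &
                     classify_non_silent(mutations), , drop = FALSE]
  flags <- if (unit == "gene") {
    unique(data.frame(patient_id = mut$patient_id, unit = mut$gene,
                      stringsAsFactors = FALSE))
  } else {
    if (is.null(pathway_map)) stop("pathway_map required for unit='pathway'")
    pc <- pathway_collapse(mut, pathway_map)
    data.frame(patient_id = pc$patient_id, unit = pc$pathway,
               stringsAsFactors = FALSE)
  }
  flags <- flags[!is.na(flags$unit), , drop = FALSE]
  counts <- table(flags$unit)
  units <- names(counts)[counts >= min_mutated]
  m <- length(units)
  if (!m) {
    return(data.frame(unit = character(0), n_mutated = integer(0),
                      statistic = numeric(0), p = numeric(0),
                      bonferroni_p = numeric(0), m = integer(0)))
  }
  records <- survival_records(pts)
  out <- lapply(units, function(u) {
    mutated <- records$patient_id %in%
      flags$patient_id[flags$unit == u]
    gr <- gray_test(records, ifelse(mutated, "mutated", "wildtype"),
                    event_of_interest = event_of_interest, rho = rho)
    data.frame(unit = u, n_mutated = sum(mutated),
               statistic = gr$statistic, p = gr$p,
               bonferroni_p = min(1, gr$p * m), m = m,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$p), , drop = FALSE]
}
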