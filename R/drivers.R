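#' Poisson burden excess test for a gene
#'
#' Tests whether a gene carries more non-silent mutations than expected
#' from a cohort-wide background rate and the gene's coding length
#' (upper-tail Poisson). This is a deliberately simple burden statistic:
#' it captures the "more mutations than expected" axis of driver
#' detection without per-gene covariate modelling.
#'
#' @param coding_length_bp gene coding length (> 0).
#' @param observed_nonsilent observed non-silent mutation count.
#' @param background_rate_per_bp per-patient per-bp background mutation
#'   rate, typically estimated from silent and noncoding mutations
#'   cohort-wide (see [background_rate()]).
#' @param n_patients number of patients in the subgroup.
#' @return upper-tail p-value, `P(X >= observed)` for
#'   `X ~ Poisson(rate * length * n)`.
#' @export
burden_test <- function(coding_length_bp, observed_nonsilent,
                        background_rate_per_bp, n_patients) {
  if (coding_length_bp <= 0) stop("coding length must be > 0")
  stopifnot(background_rate_per_bp > 0, observed_nonsilent >= 0)
  lambda <- background_rate_per_bp * coding_length_bp * n_patients
  stats::ppois(observed_nonsilent - 1, lambda, lower.tail = FALSE)
}

#' Cohort-wide background mutation rate per patient per coding bp
#'
#' Estimated from silent and noncoding mutations, which are assumed
#' selectively neutral, divided by the total coding territory and the
#' number of patients. A 0.5-count floor keeps the rate positive in
#' small subgroups.
#'
#' @param mutations mutation records of the subgroup.
#' @param genes gene model table.
#' @param n_patients patients in the subgroup.
#' @return rate per patient per bp.
#' @export
background_rate <- function(mutations, genes, n_patients) {
  n_neutral <- sum(mutations$effect %in% c("silent", "noncoding"))
  total_bp <- sum(genes$coding_length_bp)
  max(n_neutral, 0.5) / (total_bp * n_patients)
}

#' Functional-impact bias test for a gene
#'
#' One-sided rank-sum test for the gene's per-mutation impact scores
#' exceeding the cohort-wide background scores (mid-ranks, tie-corrected
#' normal approximation). When the pooled scores are completely tied the
#' observed statistic cannot be exceeded by any permutation and the
#' p-value is 1. Genes with fewer than two scored mutations are not
#' tested (`NA`).
#'
#' @param gene_scores impact scores in \[0, 1\] of the gene's mutations.
#' @param cohort_scores background impact scores (cohort-wide).
#' @return one-sided p-value, or `NA` if the gene has < 2 scored
#'   mutations.
#' @export
impact_bias_test <- function(gene_scores, cohort_scores) {
  gene_scores <- gene_scores[!is.na(gene_scores)]
  cohort_scores <- cohort_scores[!is.na(cohort_scores)]
  if (length(gene_scores) < 2) return(NA_real_)
  stopifnot(all(gene_scores >= 0 & gene_scores <= 1),
            all(cohort_scores >= 0 & cohort_scores <= 1))
  n1 <- length(gene_scores); n2 <- length(cohort_scores)
  pooled <- c(gene_scores, cohort_scores)
  r <- rank(pooled)                       # mid-ranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)              # all observations tied
  stats::pnorm((U - mu) / sqrt(sigma2), lower.tail = FALSE)
}

#' Positional clustering test for mutations within a coding sequence
#'
#' Statistic: the maximum, over all sliding windows of `window` bp along
#' the CDS, of the fraction of the gene's mutations inside the window.
#' Significance by Monte-Carlo permutation against uniform positions,
#' with add-one smoothing, so p >= 1/(n_perm + 1) always.
#'
#' @param positions_in_cds integer positions (1-based) of >= 3 mutations.
#' @param cds_length CDS length in bp.
#' @param window window width in bp (<= cds_length), default 50.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `statistic` (max window fraction) and `p`.
#' @export
clustering_test <- function(positions_in_cds, cds_length, window = 50L,
                            n_perm = 1000L, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (length(positions_in_cds) < 3) stop("need >= 3 mutation positions")
  if (window > cds_length) stop("window larger than the CDS")
  stat <- function(pos) {
    pos <- sort(pos)
    n <- length(pos)
    # for each left-most mutation, count mutations within window-1 bp
    best <- 0L
    j <- 1L
    for (i in seq_len(n)) {
      while (j < n && pos[j + 1L] - pos[i] <= window - 1L) j <- j + 1L
      best <- max(best, j - i + 1L)
    }
    best / n
  }
  obs <- stat(positions_in_cds)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(cds_length, length(positions_in_cds), replace = TRUE)
    if (stat(perm) >= obs) hits <- hits + 1L
  }
  list(statistic = obs, p = (hits + 1) / (n_perm + 1))
}

#' Per-subgroup driver statistics for every gene
#'
#' Runs the burden, impact-bias and clustering statistics for each gene
#' within each patient subgroup and adjusts p-values per (subgroup,
#' statistic) family by Benjamini-Hochberg. Subgroups follow the
#' five-subset convention for driver screening: T-ALL, all BCP-ALL, and
#' the BCP-ALL subtypes HeH, t(12;21) and normal karyotype.
#'
#' @param mutations mutation records (diagnostic timepoint).
#' @param patients patient metadata.
#' @param genes gene model.
#' @param impact_scores optional numeric vector of impact scores in
#'   \[0,1\], one per mutation row; defaults to the `impact_score`
#'   column of `mutations` when present, otherwise the impact-bias
#'   statistic is skipped (`NA`).
#' @param window,n_perm,seed clustering-test parameters.
#' @return data.frame of class `driver_calls`: gene, subgroup, statistic,
#'   p, q.
#' @export
driver_calls <- function(mutations, patients, genes, impact_scores = NULL,
                         window = 50L, n_perm = 1000L, seed = 1L) {
  subgroups <- driver_subgroups(patients)
  if (is.null(impact_scores))
    impact_scores <- if ("impact_score" %in% names(mutations))
      mutations$impact_score else rep(NA_real_, nrow(mutations))
  rows <- list()
  for (sg in names(subgroups)) {
    ids <- subgroups[[sg]]
    mut <- mutations[mutations$patient_id %in% ids &
                       mutations$timepoint == "diagnosis", , drop = FALSE]
    sc <- impact_scores[mutations$patient_id %in% ids &
                          mutations$timepoint == "diagnosis"]
    if (!nrow(mut)) next
    ns <- mut[classify_non_silent(mut), , drop = FALSE]
    ns_scores <- sc[classify_non_silent(mut)]
    total_bp <- sum(genes$coding_length_bp)
    for (g in unique(ns$gene[!is.na(ns$gene)])) {
      gi <- which(ns$gene == g)
      glen <- genes$coding_length_bp[match(g, genes$gene)]
      if (is.na(glen)) next
      # leave-one-out non-silent background: the tested gene's own
      # mutations do not contribute to its expected count
      rate <- max(nrow(ns) - length(gi), 0.5) /
        ((total_bp - glen) * length(ids))
      p_burden <- burden_test(glen, length(gi), rate, length(ids))
      p_impact <- impact_bias_test(ns_scores[gi], sc)
      p_clust <- if (length(gi) >= 3) {
        pos <- (ns$pos[gi] %% glen) + 1L   # CDS-relative proxy position
        clustering_test(pos, glen, window = min(window, glen),
                        n_perm = n_perm, seed = seed)$p
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, subgroup = sg,
        statistic = c("burden", "impact_bias", "clustering"),
        p = c(p_burden, p_impact, p_clust), stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  calls$q <- NA_real_
  for (sg in unique(calls$subgroup))
    for (st in unique(calls$statistic)) {
      i <- calls$subgroup == sg & calls$statistic == st & !is.na(calls$p)
      calls$q[i] <- stats::p.adjust(calls$p[i], method = "BH")
    }
  class(calls) <- c("driver_calls", class(calls))
  calls
}

#' The five patient subsets used for driver screening
#'
#' @param patients patient metadata.
#' @return named list of patient-id vectors: T-ALL, BCP-ALL, HeH,
#'   t(12;21), normal.
#' @export
driver_subgroups <- function(patients) {
  bcp <- patients$immunophenotype == "BCP"
  list(
    "T-ALL" = patients$patient_id[patients$subtype == "T-ALL"],
    "BCP-ALL" = patients$patient_id[bcp],
    "HeH" = patients$patient_id[bcp & patients$subtype == "HeH"],
    "t(12;21)" = patients$patient_id[bcp & patients$subtype == "t(12;21)"],
    "normal" = patients$patient_id[bcp & patients$subtype == "normal"])
}

#' Consensus driver rule
#'
#' A gene is a putative driver if it is predicted in at least one patient
#' subgroup (any statistic with q below `q_threshold`; or all statistics
#' in `strict` mode) and harbors at least three non-silent mutations in
#' the cohort.
#'
#' @param calls output of [driver_calls()] (or a data.frame with columns
#'   gene, subgroup, statistic, p, q).
#' @param mutations mutation records used to count non-silent mutations.
#' @param q_threshold FDR threshold per (subgroup, statistic) family.
#' @param min_non_silent the mutation-count gate (default 3).
#' @param strict require every non-missing statistic of a subgroup to
#'   pass, instead of any one.
#' @return data.frame: gene, supporting_subgroups (comma-joined),
#'   n_non_silent, is_driver.
#' @export
consensus_drivers <- function(calls, mutations, q_threshold = 0.1,
                              min_non_silent = 3L, strict = FALSE) {
  ns <- mutations[classify_non_silent(mutations) &
                    mutations$timepoint == "diagnosis", , drop = FALSE]
  ns_count <- table(ns$gene)
  genes <- unique(calls$gene)
  out <- lapply(genes, function(g) {
    gc <- calls[calls$gene == g, , drop = FALSE]
    pred <- vapply(split(gc, gc$subgroup), function(d) {
      ok <- !is.na(d$q)
      if (!any(ok)) return(FALSE)
      if (strict) all(d$q[ok] <= q_threshold) else any(d$q[ok] <= q_threshold)
    }, NA)
    n_ns <- if (g %in% names(ns_count)) as.integer(ns_count[[g]]) else 0L
    data.frame(gene = g,
               supporting_subgroups = paste(names(pred)[pred], collapse = ","),
               n_non_silent = n_ns,
               is_driver = any(pred) && n_ns >= min_non_silent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

round_half_up <- function(x) floor(x + 0.5)

#' Subtype summary of driver and Ras-pathway mutations
#'
#' Per subtype: number of patients, number (and percentage, rounded half
#' up) of patients with at least one non-silent mutation in the Ras
#' genes, mean number of non-silent driver-gene mutations per patient,
#' and number (and percentage) of patients without any driver mutation.
#' A `total` row summarizes the whole cohort.
#'
#' @param driver_genes character vector of driver genes (e.g. the
#'   `is_driver` genes from [consensus_drivers()]).
#' @param mutations mutation records (diagnostic timepoint).
#' @param patients patient metadata.
#' @param ras_genes the Ras-pathway gene set.
#' @return data.frame, one row per subtype plus `total`.
#' @export
driver_summary <- function(driver_genes, mutations, patients,
                           ras_genes = c("KRAS", "NRAS", "PTPN11", "FLT3")) {
  if (!all(patients$subtype %in% SUBTYPES))
    stop("unknown subtype label: ",
         paste(setdiff(patients$subtype, SUBTYPES), collapse = ", "))
  ns <- mutations[classify_non_silent(mutations) &
                    mutations$timepoint == "diagnosis", , drop = FALSE]
  per_subtype <- function(ids, label) {
    m <- ns[ns$patient_id %in% ids, , drop = FALSE]
    n <- length(ids)
    ras_patients <- unique(m$patient_id[m$gene %in% ras_genes])
    driver_counts <- table(factor(
      m$patient_id[m$gene %in% driver_genes], levels = ids))
    n_zero <- sum(driver_counts == 0)
    data.frame(
      subtype = label, n_patients = n,
      n_ras = length(ras_patients),
      pct_ras = if (n) round_half_up(100 * length(ras_patients) / n) else 0,
      mean_driver_mutations = if (n) round(mean(driver_counts), 2) else NA,
      n_no_driver = n_zero,
      pct_no_driver = if (n) round_half_up(100 * n_zero / n) else 0,
      stringsAsFactors = FALSE)
  }
  rows <- lapply(unique(patients$subtype), function(st)
    per_subtype(patients$patient_id[patients$subtype == st], st))
  rows[[length(rows) + 1L]] <- per_subtype(patients$patient_id, "total")
  do.call(rbind, rows)
}
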