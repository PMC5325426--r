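#' Classify diagnosis/relapse status of mutations in paired patients
#'
#' For every patient with samples at two or more timepoints, each
#' mutation is assigned exactly one status from its per-timepoint
#' `called` flags: `shared` (called at diagnosis and at a relapse),
#' `diagnosis_only` (called at diagnosis only) or `relapse_gained`
#' (called only at relapse). Mutations first called at the second
#' relapse are classified against the first relapse (`gained_at =
#' "relapse2"`), mirroring the chained comparison of successive
#' relapses. Rows with `called = FALSE` everywhere are raw genotyping
#' support, not calls, and are dropped here (they feed
#' [rescue_low_af()]).
#'
#' @param records mutation records of paired patients; one row per
#'   (mutation, timepoint) that was assayed, with `called` flags.
#' @return data.frame of class `evolution_calls`: patient_id, key, gene,
#'   effect, status, gained_at, rescued, residual, rising, per-timepoint
#'   af/alt_reads/depth columns.
#' @export
classify_status <- function(records) {
  out <- lapply(split(records, records$patient_id), function(pr) {
    tps <- unique(pr$timepoint[pr$called])
    if (length(unique(pr$timepoint)) < 2)
      stop("patient ", pr$patient_id[1],
           " has a single timepoint; paired samples required")
    keys <- unique(variant_key(pr))
    per_tp <- function(key, tp, col) {
      i <- which(variant_key(pr) == key & pr$timepoint == tp)
      if (length(i)) pr[[col]][i[1]] else NA
    }
    rows <- lapply(keys, function(k) {
      called <- vapply(TIMEPOINTS, function(tp)
        isTRUE(per_tp(k, tp, "called")), NA)
      if (!any(called)) return(NULL)
      at_relapse <- called["relapse1"] || called["relapse2"]
      status <- if (called["diagnosis"] && at_relapse) "shared"
        else if (called["diagnosis"]) "diagnosis_only"
        else "relapse_gained"
      gained_at <- if (status != "relapse_gained") NA_character_
        else if (called["relapse1"]) "relapse1" else "relapse2"
      i1 <- which(variant_key(pr) == k)[1]
      af <- vapply(TIMEPOINTS, function(tp)
        as.numeric(per_tp(k, tp, "af")), 0)
      ar <- vapply(TIMEPOINTS, function(tp)
        as.numeric(per_tp(k, tp, "alt_reads")), 0)
      dp <- vapply(TIMEPOINTS, function(tp)
        as.numeric(per_tp(k, tp, "depth")), 0)
      data.frame(patient_id = pr$patient_id[1], key = k,
                 gene = pr$gene[i1], effect = pr$effect[i1],
                 status = status, gained_at = gained_at,
                 rescued = FALSE, residual = FALSE, rising = FALSE,
                 af_diagnosis = af[1], af_relapse1 = af[2],
                 af_relapse2 = af[3],
                 alt_diagnosis = ar[1], alt_relapse1 = ar[2],
                 alt_relapse2 = ar[3],
                 depth_diagnosis = dp[1], depth_relapse1 = dp[2],
                 depth_relapse2 = dp[3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  class(calls) <- c("evolution_calls", class(calls))
  calls
}

#' Rescue relapse-gained mutations detectable at low AF earlier
#'
#' Deep coverage makes a handful of supporting reads at an earlier
#' timepoint informative even when the variant was not called there. A
#' relapse-gained mutation with at least `min_alt_reads` supporting
#' reads and AF below `af_ceiling` at the earlier timepoint (diagnosis,
#' or first relapse for second-relapse gains) is flagged `rescued`:
#' the relapse clone pre-existed as a minor subclone. Symmetrically, a
#' diagnosis-only mutation with such support at relapse is flagged
#' `residual`. Missing read support leaves the flag FALSE; the number of
#' such records is returned as attribute `n_no_support`.
#'
#' @param calls [classify_status()] output.
#' @param support optional data.frame (patient_id, key, timepoint,
#'   alt_reads, depth) of re-genotyping output overriding the read
#'   support embedded in `calls`.
#' @param af_ceiling maximum AF to count as "low level" (default 0.02).
#' @param min_alt_reads minimum supporting reads (default 2).
#' @return updated calls.
#' @export
rescue_low_af <- function(calls, support = NULL, af_ceiling = 0.02,
                          min_alt_reads = 2L) {
  get_support <- function(patient, key, tp) {
    if (!is.null(support)) {
      i <- which(support$patient_id == patient & support$key == key &
                   support$timepoint == tp)
      if (length(i))
        return(c(alt = support$alt_reads[i[1]], depth = support$depth[i[1]]))
    }
    suffix <- tp
    i <- which(calls$patient_id == patient & calls$key == key)
    c(alt = calls[[paste0("alt_", suffix)]][i],
      depth = calls[[paste0("depth_", suffix)]][i])
  }
  n_no_support <- 0L
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] == "relapse_gained") {
      earlier <- if (identical(calls$gained_at[i], "relapse2"))
        "relapse1" else "diagnosis"
      s <- get_support(calls$patient_id[i], calls$key[i], earlier)
      if (any(is.na(s)) || s["depth"] == 0) {
        n_no_support <- n_no_support + 1L
      } else {
        af <- s["alt"] / s["depth"]
        calls$rescued[i] <- s["alt"] >= min_alt_reads && af < af_ceiling
      }
    } else if (calls$status[i] == "diagnosis_only") {
      later <- if (!is.na(calls$depth_relapse1[i]) &&
                   calls$depth_relapse1[i] > 0) "relapse1" else "relapse2"
      s <- get_support(calls$patient_id[i], calls$key[i], later)
      if (any(is.na(s)) || s["depth"] == 0) {
        n_no_support <- n_no_support + 1L
      } else {
        af <- s["alt"] / s["depth"]
        calls$residual[i] <- s["alt"] >= min_alt_reads && af < af_ceiling
      }
    }
  }
  if (n_no_support)
    warning(n_no_support, " records lacked read support at the other timepoint")
  attr(calls, "n_no_support") <- n_no_support
  calls
}

#' Flag mutations belonging to rising clones
#'
#' A shared mutation is part of a rising clone if its allele fraction at
#' (first) relapse is at least twice its allele fraction at diagnosis
#' (boundary inclusive). The rule is applied only to mutations called at
#' both timepoints with diagnostic AF > 0; rescued relapse-gained
#' mutations are rising by construction and are kept in their own class
#' rather than fed through the ratio.
#'
#' @param calls [classify_status()] output.
#' @return updated calls.
#' @export
flag_rising <- function(calls) {
  sel <- calls$status == "shared" & !is.na(calls$af_diagnosis) &
    calls$af_diagnosis > 0 & !is.na(calls$af_relapse1)
  calls$rising[sel] <-
    calls$af_relapse1[sel] >= 2 * calls$af_diagnosis[sel]
  calls
}

detectable_matrix <- function(calls) {
  dia <- (calls$status %in% c("shared", "diagnosis_only")) |
    (calls$status == "relapse_gained" & calls$rescued &
       calls$gained_at == "relapse1")
  r1 <- (calls$status == "shared" & !is.na(calls$af_relapse1) &
           calls$depth_relapse1 > 0 & calls$alt_relapse1 > 0) |
    (calls$status == "relapse_gained" & calls$gained_at == "relapse1") |
    (calls$status == "relapse_gained" & calls$gained_at == "relapse2" &
       calls$rescued) |
    (calls$status == "diagnosis_only" & calls$residual)
  r2 <- !is.na(calls$af_relapse2) & calls$depth_relapse2 > 0 &
    calls$alt_relapse2 > 0
  cbind(diagnosis = dia, relapse1 = r1, relapse2 = r2)
}

#' Group mutations of a patient into clones
#'
#' A deterministic, order-invariant proxy for manual clone clustering:
#' mutations are first grouped by their detectability pattern across
#' timepoints, then split by single-linkage clustering of their AF
#' trajectories (Chebyshev distance over the timepoints where the
#' pattern says they are detectable), cut at `af_tolerance`. Clone fate
#' is `eradicated` if the clone is undetectable (and unrescued) at the
#' patient's last timepoint, `expanding` if any member mutation is
#' rising or the clone is relapse-gained, else `persisting`.
#'
#' @param calls [classify_status()] output (after [rescue_low_af()] and
#'   [flag_rising()] for the flags to inform fate).
#' @param af_tolerance AF tolerance for same-clone membership (default
#'   0.05).
#' @return data.frame: patient_id, clone, keys (comma-joined),
#'   n_mutations, pattern, mean AF per timepoint, fate.
#' @export
group_clones <- function(calls, af_tolerance = 0.05) {
  res <- lapply(split(as.data.frame(calls), calls$patient_id), function(pc) {
    pc <- pc[order(pc$key), , drop = FALSE]
    det <- detectable_matrix(pc)
    pattern <- apply(det, 1, function(r) paste(as.integer(r), collapse = ""))
    # latest timepoint at which this patient was assayed at all
    last_tp <- max(which(c(TRUE, any(!is.na(pc$af_relapse1)),
                           any(!is.na(pc$af_relapse2)))))
    clone_counter <- 0L
    rows <- list()
    for (pat in sort(unique(pattern))) {
      idx <- which(pattern == pat)
      afm <- as.matrix(pc[idx, c("af_diagnosis", "af_relapse1",
                                 "af_relapse2")])
      use_tp <- which(det[idx[1], ])
      sub <- if (length(idx) == 1) list(idx) else {
        d <- stats::dist(afm[, use_tp, drop = FALSE], method = "maximum")
        cl <- stats::cutree(stats::hclust(d, method = "single"),
                            h = af_tolerance)
        split(idx, cl)
      }
      for (members in sub) {
        clone_counter <- clone_counter + 1L
        det_last <- det[members[1], last_tp]
        fate <- if (!det_last) "eradicated"
          else if (any(pc$rising[members]) ||
                   any(pc$status[members] == "relapse_gained")) "expanding"
          else "persisting"
        rows[[clone_counter]] <- data.frame(
          patient_id = pc$patient_id[1],
          clone = clone_counter,
          keys = paste(pc$key[members], collapse = ","),
          n_mutations = length(members),
          pattern = pat,
          af_diagnosis = if (det[members[1], 1]) mean(afm[, 1]) else NA_real_,
          af_relapse1 = if (det[members[1], 2])
            mean(afm[, 2], na.rm = TRUE) else NA_real_,
          af_relapse2 = if (det[members[1], 3])
            mean(afm[, 3], na.rm = TRUE) else NA_real_,
          fate = fate, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Identify genes putatively associated with relapse
#'
#' A gene is flagged when either criterion holds: (1) at least two
#' non-silent relapse-gained mutations; or (2) at least one non-silent
#' relapse-gained mutation plus additional non-silent diagnostic
#' mutations in patients (diagnostic or extension cohort) that relapsed
#' -- voided when any patient of the same immunophenotype who remained
#' in CR1 carries a non-silent diagnostic mutation in the gene.
#'
#' @param calls [classify_status()] output for the paired patients.
#' @param diagnostic_mutations mutation records of the full diagnostic
#'   plus extension cohorts at diagnosis (extension records may lack
#'   AF).
#' @param patients patient metadata covering both cohorts.
#' @return data.frame: gene, n_gained_non_silent, criterion1,
#'   criterion2, flagged.
#' @export
relapse_associated_genes <- function(calls, diagnostic_mutations, patients) {
  ns_calls <- calls[classify_non_silent(calls$effect), , drop = FALSE]
  gained <- ns_calls[ns_calls$status == "relapse_gained", , drop = FALSE]
  gained <- gained[!is.na(gained$gene), , drop = FALSE]
  if (!nrow(gained)) {
    return(data.frame(gene = character(0), n_gained_non_silent = integer(0),
                      criterion1 = logical(0), criterion2 = logical(0),
                      flagged = logical(0)))
  }
  dia <- diagnostic_mutations[
    diagnostic_mutations$timepoint == "diagnosis" &
      classify_non_silent(diagnostic_mutations), , drop = FALSE]
  pheno <- stats::setNames(patients$immunophenotype, patients$patient_id)
  outcome <- stats::setNames(patients$outcome, patients$patient_id)
  out <- lapply(unique(gained$gene), function(g) {
    gg <- gained[gained$gene == g, , drop = FALSE]
    n_gained <- nrow(gg)
    c1 <- n_gained >= 2
    dia_g <- dia[!is.na(dia$gene) & dia$gene == g, , drop = FALSE]
    extra <- setdiff(unique(dia_g$patient_id), unique(gg$patient_id))
    relapsed_extra <- extra[outcome[extra] == "relapse"]
    c2 <- n_gained >= 1 && length(relapsed_extra) >= 1
    if (c2) {
      gained_pheno <- unique(pheno[gg$patient_id])
      cr1_carriers <- unique(dia_g$patient_id[
        outcome[dia_g$patient_id] == "CR1"])
      if (any(pheno[cr1_carriers] %in% gained_pheno)) c2 <- FALSE
    }
    data.frame(gene = g, n_gained_non_silent = n_gained,
               criterion1 = c1, criterion2 = c2, flagged = c1 || c2,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$gene), , drop = FALSE]
}

#' Gained/lost mutation counts per driver gene
#'
#' Among paired patients: `lost` counts non-silent diagnosis-only
#' mutations, `gained` counts non-silent relapse-gained mutations, per
#' gene of the supplied driver list.
#'
#' @param calls [classify_status()] output.
#' @param driver_genes character vector of genes to tally.
#' @return data.frame: gene, lost, gained.
#' @export
driver_gain_loss_summary <- function(calls, driver_genes) {
  ns <- calls[classify_non_silent(calls$effect) & !is.na(calls$gene), ,
              drop = FALSE]
  out <- lapply(driver_genes, function(g) {
    gg <- ns[ns$gene == g, , drop = FALSE]
    data.frame(gene = g,
               lost = sum(gg$status == "diagnosis_only"),
               gained = sum(gg$status == "relapse_gained"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
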