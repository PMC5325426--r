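# Relapse-pair simulation: clone-level gains, losses, rescue and rising
# dynamics layered on top of a simulated diagnostic cohort.

RELAPSE_SPIKE_GENES <- c("EP300", "CREBBP", "NOTCH1", "NT5C2", "ARID1A",
                         "SYNE1", "KRAS", "NRAS")

# support reads for a variant present at low level (AF < 2%)
sim_low_support <- function(config) {
  depth <- max(sim_depth(1L, config), 400L)
  c(alt = sample(2:5, 1L), depth = depth)
}

# pick an AF level at least min_sep away from every level in `used`
pick_spaced_level <- function(grid, used, min_sep) {
  ok <- grid[vapply(grid, function(g)
    !length(used) || min(abs(g - used)) >= min_sep, NA)]
  if (length(ok)) ok[sample.int(length(ok), 1L)]
  else grid[which.max(vapply(grid, function(g)
    min(abs(g - used)), 0))]
}

new_gained_mutation <- function(gene_pool, genes, genome, used_pos, config,
                                gene = NULL, force_non_silent = FALSE) {
  g <- if (!is.null(gene)) gene
  else if (stats::runif(1) < 0.3)
    RELAPSE_SPIKE_GENES[sample.int(length(RELAPSE_SPIKE_GENES), 1L)]
  else gene_pool[sample.int(length(gene_pool), 1L)]
  gi <- match(g, genes$gene)
  repeat {
    pos <- sample(seq(genes$start[gi] + 1L, genes$end[gi] - 1L), 1L)
    if (!paste(genes$chrom[gi], pos) %in% used_pos) break
  }
  chrom <- genes$chrom[gi]
  ref <- substr(as.character(Biostrings::subseq(genome[[chrom]], pos, pos)),
                1, 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  effect <- if (force_non_silent) "nsSNV"
  else sample(c("nsSNV", "nonsense", "frameshift", "silent"),
              1L, prob = c(0.65, 0.1, 0.1, 0.15))
  vclass <- if (effect == "frameshift") "deletion" else "SNV"
  if (vclass == "deletion") {
    nxt <- substr(as.character(
      Biostrings::subseq(genome[[chrom]], pos + 1L, pos + 1L)), 1, 1)
    ref2 <- paste0(ref, nxt)
    list(gene = g, chrom = chrom, pos = pos, ref = ref2, alt = ref,
         effect = effect, vclass = vclass)
  } else {
    list(gene = g, chrom = chrom, pos = pos, ref = ref, alt = alt,
         effect = effect, vclass = vclass)
  }
}

#' Simulate relapse samples for a subset of relapsed patients
#'
#' Selects `relapse_pair_fraction` of the cohort's relapsed patients and
#' simulates a first (and for some pairs a second) relapse sample with
#' clone-level dynamics: the founding clone persists with AF tracking
#' the relapse blast fraction; whole subclones are eradicated (lost)
#' until roughly `Poisson(lost_per_relapse_mean)` mutations are gone;
#' about `Poisson(gained_per_relapse_mean)` mutations are gained in new
#' clones; `rescue_fraction` of gained clones were already present at
#' the earlier timepoint at AF < 2\% (>= 2 supporting reads, not
#' called); `residual_fraction` of eradicated clones remain detectable
#' at low AF at relapse; and one low-AF surviving subclone per pair (if
#' available) rises to at least twice its diagnostic AF. Uncalled
#' timepoints are emitted as `called = FALSE` rows carrying raw read
#' support, standing in for re-genotyping output.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config generator configuration; defaults to `cohort$config`.
#' @return the cohort with relapse-timepoint (and support) rows appended
#'   to `mutations`, plus `truth$pair_truth` (per-mutation status,
#'   rescued/residual/rising flags and clone label) and `pairs` (the
#'   selected patient ids).
#' @export
simulate_relapse_pairs <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "sim_cohort"))
  relapsed <- cohort$patients$patient_id[cohort$patients$outcome == "relapse"]
  if (!length(relapsed)) stop("no relapsed patients in the cohort")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed + 101L)

  n_pairs <- max(1L, round(config$relapse_pair_fraction * length(relapsed)))
  pairs <- sort(sample(relapsed, min(n_pairs, length(relapsed))))
  n_rel2 <- round(config$second_relapse_fraction * length(pairs))
  rel2_pairs <- if (n_rel2) sort(sample(pairs, n_rel2)) else character(0)

  plant <- config$plant_gain_loss
  lost_alloc <- gained_alloc <- NULL
  if (!is.null(plant)) {
    lost_alloc <- data.frame(
      gene = rep(plant$gene, plant$lost),
      pid = sample(pairs, sum(plant$lost), replace = TRUE),
      stringsAsFactors = FALSE)
    gained_alloc <- data.frame(
      gene = rep(plant$gene, plant$gained),
      pid = sample(pairs, sum(plant$gained), replace = TRUE),
      stringsAsFactors = FALSE)
  }

  genes <- cohort$genes
  genome <- cohort$genome
  truthm <- cohort$truth$mutation_truth
  gene_pool <- genes$gene
  sex <- stats::setNames(cohort$patients$sex, cohort$patients$patient_id)

  new_rows <- list(); truth_rows <- list()
  emit <- function(pid, tp, chrom, pos, ref, alt, vclass, effect, gene,
                   true_af, called, config, support = NULL) {
    if (!is.null(support)) {
      depth <- unname(support["depth"]); alt_reads <- unname(support["alt"])
    } else if (is.na(true_af)) {
      depth <- sim_depth(1L, config); alt_reads <- 0L
    } else {
      depth <- sim_depth(1L, config)
      alt_reads <- sim_reads(min(true_af, 0.98), depth, config)
    }
    new_rows[[length(new_rows) + 1L]] <<- data.frame(
      patient_id = pid, sample_id = paste0(pid, ".", tp), timepoint = tp,
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      variant_class = vclass, effect = effect, gene = gene,
      af = alt_reads / depth, alt_reads = as.integer(alt_reads),
      depth = as.integer(depth), called = called,
      impact_score = NA_real_, stringsAsFactors = FALSE)
  }

  for (pid in pairs) {
    has_rel2 <- pid %in% rel2_pairs
    dia <- cohort$mutations[cohort$mutations$patient_id == pid &
                              cohort$mutations$timepoint == "diagnosis", ,
                            drop = FALSE]
    tr <- truthm[truthm$patient_id == pid, , drop = FALSE]
    tr <- tr[match(variant_key(dia), tr$key), , drop = FALSE]
    blast_rel <- stats::runif(1, config$blast_range[1], config$blast_range[2])
    used_pos <- paste(dia$chrom, dia$pos)

    # clone labels: founder split by ploidy stratum, subclones by level
    clone_lab <- ifelse(tr$clone == 0L, paste0("F", tr$ploidy_factor),
                        paste0("S", tr$clone))
    clones <- unique(clone_lab)
    sub_clones <- grep("^S", clones, value = TRUE)
    level_of <- vapply(sub_clones, function(cl)
      tr$true_af[clone_lab == cl][1] / tr$ploidy_factor[clone_lab == cl][1],
      0)

    rising_clone <- NA_character_
    cand <- sub_clones[level_of <= 0.18]
    if (length(cand)) rising_clone <- cand[sample.int(length(cand), 1L)]

    # eradicate whole subclones until the lost target is reached
    target_lost <- stats::rpois(1, config$lost_per_relapse_mean)
    erad <- character(0)
    pool <- setdiff(sub_clones, rising_clone)
    pool <- pool[sample.int(length(pool))]
    for (cl in pool) {
      if (sum(clone_lab %in% erad) >= target_lost) break
      erad <- c(erad, cl)
    }
    residual_clones <- erad[stats::runif(length(erad)) <
                              config$residual_fraction]

    # per-clone relapse AF levels
    rel1_level <- stats::setNames(numeric(length(clones)), clones)
    for (cl in clones) {
      if (cl %in% erad) { rel1_level[cl] <- NA_real_; next }
      rel1_level[cl] <-
        if (cl == "F1") blast_rel / 2
        else if (cl == "F2") min(blast_rel, 0.98)
        else if (identical(cl, rising_clone)) 2.5 * level_of[cl]
        else level_of[cl] * stats::runif(1, 0.8, 1.25)
    }

    # emit relapse1 (and relapse2) rows for diagnostic mutations
    rel2_factor <- stats::setNames(stats::runif(length(clones), 0.9, 1.15),
                                   clones)
    for (j in seq_len(nrow(dia))) {
      cl <- clone_lab[j]
      eradicated <- cl %in% erad
      support <- if (eradicated && cl %in% residual_clones)
        sim_low_support(config) else NULL
      emit(pid, "relapse1", dia$chrom[j], dia$pos[j], dia$ref[j], dia$alt[j],
           dia$variant_class[j], dia$effect[j], dia$gene[j],
           if (eradicated) NA_real_ else rel1_level[cl],
           called = !eradicated, config, support = support)
      if (has_rel2)
        emit(pid, "relapse2", dia$chrom[j], dia$pos[j], dia$ref[j],
             dia$alt[j], dia$variant_class[j], dia$effect[j], dia$gene[j],
             if (eradicated) NA_real_ else rel1_level[cl] * rel2_factor[cl],
             called = !eradicated, config)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = pid, key = tr$key[j], gene = dia$gene[j],
        clone = cl,
        status = if (eradicated) "diagnosis_only" else "shared",
        gained_at = NA_character_,
        rescued = FALSE,
        residual = eradicated && cl %in% residual_clones,
        rising = identical(cl, rising_clone), stringsAsFactors = FALSE)
    }

    # gained clones at first relapse
    n_gained <- stats::rpois(1, config$gained_per_relapse_mean)
    gained_levels_grid <- seq(0.08, 0.44, by = 0.04)
    used_rel1 <- rel1_level[!is.na(rel1_level)]
    first_gained <- NULL
    if (n_gained > 0) {
      n_gclones <- if (n_gained > 4) 2L else 1L
      sizes <- if (n_gclones == 1L) n_gained else {
        a <- sample.int(n_gained - 1L, 1L); c(a, n_gained - a)
      }
      for (gc in seq_len(n_gclones)) {
        lev <- pick_spaced_level(gained_levels_grid, used_rel1,
                                 config$clone_af_separation)
        used_rel1 <- c(used_rel1, lev)
        rescued <- stats::runif(1) < config$rescue_fraction
        g2f <- stats::runif(1, 0.9, 1.15)
        if (gc == 1L)
          first_gained <- list(lev = lev, rescued = rescued, g2f = g2f)
        for (m in seq_len(sizes[gc])) {
          mut <- new_gained_mutation(gene_pool, genes, genome, used_pos,
                                     config)
          used_pos <- c(used_pos, paste(mut$chrom, mut$pos))
          support <- if (rescued) sim_low_support(config) else NULL
          emit(pid, "diagnosis", mut$chrom, mut$pos, mut$ref, mut$alt,
               mut$vclass, mut$effect, mut$gene, NA_real_, called = FALSE,
               config, support = support)
          emit(pid, "relapse1", mut$chrom, mut$pos, mut$ref, mut$alt,
               mut$vclass, mut$effect, mut$gene, lev, called = TRUE, config)
          if (has_rel2)
            emit(pid, "relapse2", mut$chrom, mut$pos, mut$ref, mut$alt,
                 mut$vclass, mut$effect, mut$gene, lev * g2f,
                 called = TRUE, config)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            patient_id = pid,
            key = paste(mut$chrom, mut$pos, mut$ref, mut$alt, sep = ":"),
            gene = mut$gene, clone = paste0("G", gc),
            status = "relapse_gained", gained_at = "relapse1",
            rescued = rescued, residual = FALSE, rising = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }

    # mutations planted with fixed gained/lost counts (attached to
    # existing clones so the clone structure stays coherent)
    if (!is.null(plant)) {
      pl <- lost_alloc$gene[lost_alloc$pid == pid]
      if (length(pl)) {
        if (length(erad)) {
          lost_cl <- erad[1]
          lost_lev <- level_of[lost_cl]
          lost_res <- lost_cl %in% residual_clones
        } else {
          lost_lev <- pick_spaced_level(
            seq(0.04, 0.28, by = 0.04),
            c(unname(level_of), blast_rel / 2),
            config$clone_af_separation)
          lost_cl <- "SPL"; lost_res <- FALSE
        }
        for (g in pl) {
          mut <- new_gained_mutation(gene_pool, genes, genome, used_pos,
                                     config, gene = g,
                                     force_non_silent = TRUE)
          used_pos <- c(used_pos, paste(mut$chrom, mut$pos))
          emit(pid, "diagnosis", mut$chrom, mut$pos, mut$ref, mut$alt,
               mut$vclass, mut$effect, mut$gene, lost_lev, called = TRUE,
               config)
          emit(pid, "relapse1", mut$chrom, mut$pos, mut$ref, mut$alt,
               mut$vclass, mut$effect, mut$gene, NA_real_, called = FALSE,
               config,
               support = if (lost_res) sim_low_support(config) else NULL)
          if (has_rel2)
            emit(pid, "relapse2", mut$chrom, mut$pos, mut$ref, mut$alt,
                 mut$vclass, mut$effect, mut$gene, NA_real_,
                 called = FALSE, config)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            patient_id = pid,
            key = paste(mut$chrom, mut$pos, mut$ref, mut$alt, sep = ":"),
            gene = mut$gene, clone = lost_cl, status = "diagnosis_only",
            gained_at = NA_character_, rescued = FALSE,
            residual = lost_res, rising = FALSE, stringsAsFactors = FALSE)
        }
      }
      pg <- gained_alloc$gene[gained_alloc$pid == pid]
      if (length(pg)) {
        if (is.null(first_gained)) {
          lev_g <- pick_spaced_level(gained_levels_grid, used_rel1,
                                     config$clone_af_separation)
          used_rel1 <- c(used_rel1, lev_g)
          first_gained <- list(lev = lev_g, rescued = FALSE,
                               g2f = stats::runif(1, 0.9, 1.15))
          gained_cl <- "GPL"
        } else gained_cl <- "G1"
        for (g in pg) {
          mut <- new_gained_mutation(gene_pool, genes, genome, used_pos,
                                     config, gene = g,
                                     force_non_silent = TRUE)
          used_pos <- c(used_pos, paste(mut$chrom, mut$pos))
          emit(pid, "diagnosis", mut$chrom, mut$pos, mut$ref, mut$alt,
               mut$vclass, mut$effect, mut$gene, NA_real_, called = FALSE,
               config,
               support = if (first_gained$rescued)
                 sim_low_support(config) else NULL)
          emit(pid, "relapse1", mut$chrom, mut$pos, mut$ref, mut$alt,
               mut$vclass, mut$effect, mut$gene, first_gained$lev,
               called = TRUE, config)
          if (has_rel2)
            emit(pid, "relapse2", mut$chrom, mut$pos, mut$ref, mut$alt,
                 mut$vclass, mut$effect, mut$gene,
                 first_gained$lev * first_gained$g2f, called = TRUE,
                 config)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            patient_id = pid,
            key = paste(mut$chrom, mut$pos, mut$ref, mut$alt, sep = ":"),
            gene = mut$gene, clone = gained_cl,
            status = "relapse_gained", gained_at = "relapse1",
            rescued = first_gained$rescued, residual = FALSE,
            rising = FALSE, stringsAsFactors = FALSE)
        }
      }
    }

    # one clone gained only at the second relapse
    if (has_rel2) {
      lev <- pick_spaced_level(gained_levels_grid, used_rel1,
                               config$clone_af_separation)
      rescued <- stats::runif(1) < config$rescue_fraction
      for (m in seq_len(1L + stats::rpois(1, 1))) {
        mut <- new_gained_mutation(gene_pool, genes, genome, used_pos, config)
        used_pos <- c(used_pos, paste(mut$chrom, mut$pos))
        support <- if (rescued) sim_low_support(config) else NULL
        emit(pid, "diagnosis", mut$chrom, mut$pos, mut$ref, mut$alt,
             mut$vclass, mut$effect, mut$gene, NA_real_, called = FALSE,
             config)
        emit(pid, "relapse1", mut$chrom, mut$pos, mut$ref, mut$alt,
             mut$vclass, mut$effect, mut$gene, NA_real_, called = FALSE,
             config, support = support)
        emit(pid, "relapse2", mut$chrom, mut$pos, mut$ref, mut$alt,
             mut$vclass, mut$effect, mut$gene, lev, called = TRUE, config)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          patient_id = pid,
          key = paste(mut$chrom, mut$pos, mut$ref, mut$alt, sep = ":"),
          gene = mut$gene, clone = "G2nd",
          status = "relapse_gained", gained_at = "relapse2",
          rescued = rescued, residual = FALSE, rising = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }

  pair_truth <- do.call(rbind, truth_rows)
  out <- cohort
  out$mutations <- mutation_records(rbind(cohort$mutations,
                                          do.call(rbind, new_rows)))
  out$truth$pair_truth <- pair_truth
  out$pairs <- pairs
  out
}
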