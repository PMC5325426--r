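#' Configuration of the synthetic ALL cohort generator
#'
#' Defaults emulate the structure of a deep-targeted-sequencing pediatric
#' ALL study: subtype composition of a 172-patient diagnostic cohort,
#' negative-binomial mutation burdens with phenotype means 6.4 (T-ALL)
#' and 3.5 (BCP-ALL), bimodal AF structure (clonal peak near
#' blast-fraction/2, subclonal levels below ~0.27), a CpG C>T process in
#' all groups plus an APOBEC-like TpC process confined to the t(12;21)
#' group, per-subtype spiked driver genes, a ~638x read-depth layer, one
#' hypermutated outlier patient, and competing-risks outcomes with an
#' elevated relapse hazard for Notch-pathway-mutated patients. All of
#' these are generator stand-ins, not estimates from real data.
#'
#' @param seed integer master seed.
#' @param n_patients_by_subtype named integer vector of patients per
#'   subtype.
#' @param burden_mean_by_phenotype named vector (`T`, `BCP`): mean total
#'   somatic mutations per patient.
#' @param burden_dispersion negative-binomial size parameter.
#' @param blast_range range of simulated blast fractions.
#' @param subclone_count_range min/max subclones per patient.
#' @param subclonal_af_ceiling subclonal AF levels stay below
#'   `ceiling * blast` (must be < 0.5).
#' @param clonal_fraction_by_phenotype probability a mutation belongs to
#'   the founding clone, per phenotype.
#' @param clone_af_separation minimum spacing between subclonal AF
#'   levels within a patient (keeps clones resolvable).
#' @param driver_genes_by_subtype named list: spiked driver genes per
#'   subtype.
#' @param driver_spike_prob per patient, per subtype driver gene,
#'   probability that one of the patient's mutations is a driver
#'   mutation in that gene.
#' @param driver_hotspot_prob probability a spiked driver SNV lands on
#'   one of the gene's two recurrent hotspot positions.
#' @param signature_mixtures_by_group named list of weights over the
#'   catalogue signatures; the entry `default` applies to groups without
#'   their own entry.
#' @param n_passenger_genes number of passenger genes in the panel.
#' @param n_hypermutators number of hypermutated HeH outlier patients.
#' @param hypermutator_burden mutations in a hypermutated patient.
#' @param mean_depth,depth_dispersion negative-binomial read-depth
#'   layer.
#' @param read_noise if TRUE alt reads are binomial draws; if FALSE
#'   reads are the rounded expectation (noise-free mode used by
#'   exactness checks).
#' @param relapse_pair_fraction fraction of relapsed patients for whom a
#'   relapse sample is simulated.
#' @param second_relapse_fraction fraction of pairs that also get a
#'   second relapse sample.
#' @param gained_per_relapse_mean,lost_per_relapse_mean Poisson means of
#'   relapse-gained and diagnosis-lost mutation counts per pair.
#' @param rescue_fraction fraction of gained clones seeded at AF < 0.02
#'   at the earlier timepoint.
#' @param residual_fraction fraction of eradicated clones still
#'   detectable at low AF at relapse.
#' @param pathway_genes gene set whose non-silent mutation raises the
#'   relapse hazard (default: Notch-pathway genes).
#' @param pathway_hazard_ratio multiplicative relapse-hazard increase
#'   for pathway-mutated patients.
#' @param baseline_relapse_hazard,competing_hazard cause-specific
#'   exponential hazards (per year).
#' @param censor_time_years administrative censoring horizon.
#' @param plant_gain_loss optional data.frame (gene, lost, gained) of
#'   additional relapse-pair mutations to plant with fixed counts.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(
    seed = 1L,
    n_patients_by_subtype = c("T-ALL" = 24L, "HeH" = 47L, "t(12;21)" = 36L,
                              "other" = 22L, "normal" = 19L, "t(9;22)" = 8L,
                              "11q23/MLL" = 4L, "iAMP21" = 4L,
                              "t(1;19)" = 4L, "dic(9;20)" = 3L,
                              "gt67chr" = 1L),
    burden_mean_by_phenotype = c(T = 6.4, BCP = 3.5),
    burden_dispersion = 1.5,
    blast_range = c(0.80, 0.95),
    subclone_count_range = c(1L, 3L),
    subclonal_af_ceiling = 0.30,
    clonal_fraction_by_phenotype = c(T = 0.65, BCP = 0.45),
    clone_af_separation = 0.12,
    driver_genes_by_subtype = list(
      "T-ALL" = c("NOTCH1", "PTEN", "PHF6", "FBXW7"),
      "HeH" = c("KRAS", "NRAS", "PTPN11", "FLT3", "CREBBP"),
      "t(12;21)" = "WHSC1",
      "normal" = c("NRAS", "IL7R"),
      "other" = c("KRAS", "NRAS"),
      "dic(9;20)" = c("KRAS", "NRAS"),
      "gt67chr" = "KRAS"),
    driver_spike_prob = 0.25,
    driver_hotspot_prob = 0.7,
    signature_mixtures_by_group = list(
      default = c(AgingLike = 0.7, Flat = 0.3),
      "t(12;21)" = c(AgingLike = 0.4, APOBECLike = 0.4, Flat = 0.2)),
    n_passenger_genes = 200L,
    n_hypermutators = 1L,
    hypermutator_burden = 120L,
    mean_depth = 638,
    depth_dispersion = 10,
    read_noise = TRUE,
    relapse_pair_fraction = 0.5,
    second_relapse_fraction = 0.15,
    gained_per_relapse_mean = 5,
    lost_per_relapse_mean = 3.6,
    rescue_fraction = 0.21,
    residual_fraction = 0.09,
    pathway_genes = c("NOTCH1", "NOTCH2", "CREBBP", "EP300", "MAML2",
                      "HDAC2", "DTX1"),
    pathway_hazard_ratio = 3,
    baseline_relapse_hazard = 0.03,
    competing_hazard = 0.015,
    censor_time_years = 10,
    plant_gain_loss = NULL) {
  cfg <- as.list(environment())
  if (!length(cfg$n_patients_by_subtype) ||
      is.null(names(cfg$n_patients_by_subtype)))
    stop("n_patients_by_subtype must be a non-empty named vector")
  stopifnot(all(names(cfg$n_patients_by_subtype) %in% SUBTYPES),
            all(cfg$n_patients_by_subtype >= 0),
            cfg$burden_dispersion > 0,
            cfg$subclonal_af_ceiling > 0, cfg$subclonal_af_ceiling < 0.5,
            cfg$driver_spike_prob >= 0, cfg$driver_spike_prob <= 1,
            cfg$relapse_pair_fraction >= 0, cfg$relapse_pair_fraction <= 1,
            cfg$rescue_fraction >= 0, cfg$rescue_fraction <= 1,
            cfg$pathway_hazard_ratio > 0,
            cfg$baseline_relapse_hazard > 0, cfg$competing_hazard > 0)
  structure(cfg, class = "sim_config")
}

KNOWN_GENES <- data.frame(
  gene = c("NOTCH1", "PTEN", "PHF6", "FBXW7", "NRAS", "KRAS", "PTPN11",
           "FLT3", "CREBBP", "KMT2D", "WHSC1", "IL7R", "ATRX", "EP300",
           "NOTCH2", "MAML2", "HDAC2", "DTX1", "NT5C2", "SH2B3", "EBF1",
           "AFF3", "ARID1A", "SYNE1", "ETV6"),
  chrom = c("chr1", "chr1", "chrX", "chr1", "chr1", "chr2", "chr2", "chr2",
            "chr2", "chr3", "chr3", "chr3", "chrX", "chr3", "chr4", "chr4",
            "chr4", "chr4", "chr1", "chr2", "chr3", "chr4", "chr1", "chr2",
            "chr3"),
  stringsAsFactors = FALSE)

#' Synthetic gene model for the simulated panel
#'
#' A set of recognisable leukemia genes plus `n_passenger` passenger
#' genes, tiled contiguously along synthetic chromosomes so every
#' genomic position belongs to exactly one gene.
#'
#' @param n_passenger number of passenger genes.
#' @return gene model data.frame with interval columns `start`/`end`.
#' @keywords internal
sim_gene_model <- function(n_passenger = 200L) {
  pass <- data.frame(
    gene = sprintf("PSG%03d", seq_len(n_passenger)),
    chrom = paste0("chr", (seq_len(n_passenger) %% 4) + 1),
    stringsAsFactors = FALSE)
  genes <- rbind(KNOWN_GENES, pass)
  genes$coding_length_bp <- pmin(pmax(round(
    stats::rlnorm(nrow(genes), log(1500), 0.45)), 400L), 8000L)
  genes$expressed_fpkm <- round(stats::rlnorm(nrow(genes), log(15), 1), 1)
  genes <- genes[order(genes$chrom), , drop = FALSE]
  genes$start <- NA_integer_; genes$end <- NA_integer_
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    ends <- cumsum(genes$coding_length_bp[i])
    genes$start[i] <- c(1L, utils::head(ends, -1) + 1L)
    genes$end[i] <- ends
  }
  rownames(genes) <- NULL
  genes
}

sim_genome <- function(genes) {
  seqs <- lapply(split(genes, genes$chrom), function(g) {
    paste(sample(c("A", "C", "G", "T"), max(g$end), replace = TRUE),
          collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

# position index: map each trinucleotide motif to the genomic sites whose
# reference context is that motif on the forward (pyrimidine) or reverse
# strand, pooled across chromosomes
sim_position_index <- function(genome) {
  per_chrom <- lapply(as.list(as.character(genome)), function(s) {
    n <- nchar(s)
    tri <- substring(s, seq_len(n - 2L), seq_len(n - 2L) + 2L)
    idx <- split(seq_len(n - 2L) + 1L, tri)
    idx[!grepl("N", names(idx))]
  })
  motifs <- sort(unique(unlist(lapply(per_chrom, names))))
  pooled <- lapply(stats::setNames(nm = motifs), function(m) {
    chs <- character(0); ps <- integer(0)
    for (ch in names(per_chrom)) {
      p <- per_chrom[[ch]][[m]]
      if (!is.null(p)) {
        chs <- c(chs, rep(ch, length(p))); ps <- c(ps, p)
      }
    }
    list(chrom = chs, pos = ps)
  })
  pooled
}

# draw one genomic site whose reference context matches a 96-class label
sim_site_for_context <- function(ctx, index, exclude_chroms = character(0)) {
  motif <- paste0(substr(ctx, 1, 1), substr(ctx, 3, 3), substr(ctx, 7, 7))
  rc <- revcomp_chr(motif)
  fw <- index[[motif]]
  rv <- index[[rc]]
  n_fw <- if (is.null(fw)) 0L else length(fw$pos)
  n_rv <- if (is.null(rv)) 0L else length(rv$pos)
  if (n_fw + n_rv == 0L) stop("no genomic site matches context ", ctx)
  tries <- 0L
  repeat {
    i <- sample.int(n_fw + n_rv, 1L)
    minus <- i > n_fw
    pick <- if (minus) list(chrom = rv$chrom[i - n_fw], pos = rv$pos[i - n_fw])
      else list(chrom = fw$chrom[i], pos = fw$pos[i])
    if (!pick$chrom %in% exclude_chroms) break
    tries <- tries + 1L
    if (tries > 50L) {   # rejection failing: sample from the filtered set
      chs <- c(fw$chrom, rv$chrom); ps <- c(fw$pos, rv$pos)
      mn <- rep(c(FALSE, TRUE), c(n_fw, n_rv))
      ok <- !chs %in% exclude_chroms
      if (!any(ok)) stop("no genomic site matches context ", ctx)
      j <- sample(which(ok), 1L)
      pick <- list(chrom = chs[j], pos = ps[j]); minus <- mn[j]
      break
    }
  }
  ref <- substr(ctx, 3, 3)   # pyrimidine
  alt <- substr(ctx, 5, 5)
  if (minus) {
    ref <- chartr("CT", "GA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  list(chrom = pick$chrom, pos = pick$pos, ref = ref, alt = alt)
}

sim_depth <- function(n, config) {
  floor_d <- min(150L, max(config$mean_depth - 10L, 1L))
  stats::rnbinom(n, mu = max(config$mean_depth - floor_d, 1),
                 size = config$depth_dispersion) + floor_d
}

sim_reads <- function(true_af, depth, config) {
  if (config$read_noise) stats::rbinom(length(depth), depth, true_af)
  else as.integer(round(true_af * depth))
}

sim_signature_p96 <- function(group, config, catalog) {
  w <- config$signature_mixtures_by_group[[group]]
  if (is.null(w)) w <- config$signature_mixtures_by_group$default
  p <- as.vector(catalog[, names(w), drop = FALSE] %*% (w / sum(w)))
  p / sum(p)
}

#' Simulate a diagnostic ALL cohort with ground truth
#'
#' Generates patient metadata, somatic mutation records at diagnosis,
#' and a truth table (clone assignment, true AF, driver labels,
#' per-patient hazard group), together with the synthetic genome and
#' gene model the mutations live on. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort`: list with `mutations`,
#'   `patients`, `truth` (list `mutation_truth`, `patient_truth`),
#'   `genes`, `genome`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  genes <- sim_gene_model(config$n_passenger_genes)
  genome <- sim_genome(genes)
  index <- sim_position_index(genome)
  catalog <- read_signature_catalog()
  ctx96 <- contexts96()
  # two recurrent hotspot positions per known driver gene
  hotspots <- lapply(stats::setNames(nm = unique(unlist(
    config$driver_genes_by_subtype))), function(g) {
      gi <- match(g, genes$gene)
      sort(sample(seq(genes$start[gi] + 1L, genes$end[gi] - 1L), 2L))
    })

  subtypes <- rep(names(config$n_patients_by_subtype),
                  config$n_patients_by_subtype)
  n_pat <- length(subtypes)
  if (!n_pat) stop("empty cohort")
  pheno <- ifelse(subtypes == "T-ALL", "T", "BCP")
  patients <- data.frame(
    patient_id = sprintf("SIM_%03d", seq_len(n_pat)),
    immunophenotype = pheno,
    subtype = subtypes,
    age_years = round(stats::rgamma(n_pat, shape = 2,
                                    scale = ifelse(pheno == "T",
                                                   10.1, 6.9) / 2), 2),
    sex = sample(c("M", "F"), n_pat, replace = TRUE, prob = c(0.55, 0.45)),
    blast_fraction = round(stats::runif(n_pat, config$blast_range[1],
                                        config$blast_range[2]), 3),
    outcome = NA_character_, time_to_event_years = NA_real_,
    cohort = sample(c("core", "diagnostic_only"), n_pat, replace = TRUE,
                    prob = c(0.83, 0.17)),
    stringsAsFactors = FALSE)

  hyper_ids <- character(0)
  heh_ids <- patients$patient_id[patients$subtype == "HeH"]
  if (config$n_hypermutators > 0 && length(heh_ids))
    hyper_ids <- sample(heh_ids, min(config$n_hypermutators, length(heh_ids)))

  mut_rows <- list(); truth_rows <- list()
  for (i in seq_len(n_pat)) {
    pid <- patients$patient_id[i]
    ph <- pheno[i]
    blast <- patients$blast_fraction[i]
    hyper <- pid %in% hyper_ids
    n_mut <- if (hyper) config$hypermutator_burden else
      stats::rnbinom(1, mu = config$burden_mean_by_phenotype[[ph]],
                     size = config$burden_dispersion)
    # subclone AF levels, spaced so clones remain resolvable
    n_sub <- sample(seq(config$subclone_count_range[1],
                        config$subclone_count_range[2]), 1L)
    grid <- seq(0.04, config$subclonal_af_ceiling * blast,
                by = config$clone_af_separation)
    sub_levels <- sort(grid[sample.int(length(grid),
                                       min(n_sub, length(grid)))])
    # spiked driver mutations
    drivers <- config$driver_genes_by_subtype[[subtypes[i]]]
    spiked <- if (is.null(drivers) || hyper) character(0) else
      drivers[stats::runif(length(drivers)) < config$driver_spike_prob]
    n_mut <- max(n_mut, length(spiked))
    if (!n_mut) next

    p_clonal <- if (hyper) 0.05 else config$clonal_fraction_by_phenotype[[ph]]
    p96 <- sim_signature_p96(subtypes[i], config, catalog)

    used_pos <- character(0)
    for (m in seq_len(n_mut)) {
      is_driver <- m <= length(spiked)
      # drivers on chrX in males stay clonal so subclone AF levels are
      # shared by all members of a subclone
      driver_hemi <- is_driver && patients$sex[i] == "M" &&
        genes$chrom[match(spiked[m], genes$gene)] == "chrX"
      clone <- if (is_driver && (driver_hemi || stats::runif(1) < 0.8)) 0L
        else if (stats::runif(1) < p_clonal) 0L
        else sample.int(length(sub_levels), 1L)
      # draw the genomic site
      if (is_driver) {
        g <- spiked[m]
        gi <- match(g, genes$gene)
        pos <- if (stats::runif(1) < config$driver_hotspot_prob)
          sample(hotspots[[g]], 1L) else
            sample(seq(genes$start[gi] + 1L, genes$end[gi] - 1L), 1L)
        chrom <- genes$chrom[gi]
        ref <- substr(as.character(
          Biostrings::subseq(genome[[chrom]], pos, pos)), 1, 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        effect <- sample(c("nsSNV", "nonsense"), 1L, prob = c(0.85, 0.15))
        vclass <- "SNV"
        impact <- stats::rbeta(1, 4, 1.5)
      } else {
        effect <- sample(
          c("nsSNV", "silent", "noncoding", "nonsense", "splice",
            "frameshift", "nonframeshift_indel"),
          1L, prob = c(0.50, 0.18, 0.17, 0.05, 0.04, 0.03, 0.03))
        vclass <- if (effect == "frameshift")
          sample(c("insertion", "deletion"), 1L)
          else if (effect == "nonframeshift_indel") "deletion" else "SNV"
        # subclonal mutations of males avoid chrX so AF levels stay clean
        excl <- if (patients$sex[i] == "M" && clone != 0L) "chrX"
          else character(0)
        site <- sim_site_for_context(
          ctx96[sample.int(96, 1L, prob = p96)], index, excl)
        chrom <- site$chrom; pos <- site$pos
        if (vclass == "SNV") {
          ref <- site$ref; alt <- site$alt
        } else if (vclass == "insertion") {
          ref <- site$ref
          alt <- paste0(site$ref, sample(c("A", "C", "G", "T"), 1L))
        } else {
          nxt <- substr(as.character(
            Biostrings::subseq(genome[[chrom]], pos + 1L, pos + 1L)), 1, 1)
          ref <- paste0(site$ref, nxt); alt <- site$ref
        }
        g <- genes$gene[genes$chrom == chrom & genes$start <= pos &
                          genes$end >= pos][1]
        impact <- stats::runif(1)
      }
      poskey <- paste(chrom, pos)
      if (poskey %in% used_pos) next   # skip duplicate site in a patient
      used_pos <- c(used_pos, poskey)

      pf <- ploidy_factor(chrom, patients$sex[i])
      base_af <- if (clone == 0L) blast / 2 else sub_levels[clone]
      true_af <- min(base_af * pf, 0.98)
      depth <- sim_depth(1L, config)
      alt_reads <- sim_reads(true_af, depth, config)
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        patient_id = pid, sample_id = paste0(pid, ".diagnosis"),
        timepoint = "diagnosis", chrom = chrom, pos = pos, ref = ref,
        alt = alt, variant_class = vclass, effect = effect, gene = g,
        af = alt_reads / depth, alt_reads = alt_reads, depth = depth,
        called = TRUE, impact_score = round(impact, 4),
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = pid, key = paste(chrom, pos, ref, alt, sep = ":"),
        gene = g, clone = clone, true_af = true_af,
        ploidy_factor = pf, is_driver = is_driver,
        stringsAsFactors = FALSE)
    }
  }
  mutations <- mutation_records(do.call(rbind, mut_rows))
  mutation_truth <- do.call(rbind, truth_rows)

  # outcomes from cause-specific exponential hazards
  pw_pat <- unique(mutations$patient_id[classify_non_silent(mutations) &
                                          mutations$gene %in%
                                          config$pathway_genes])
  pw_flag <- patients$patient_id %in% pw_pat
  h_rel <- config$baseline_relapse_hazard *
    ifelse(pw_flag, config$pathway_hazard_ratio, 1)
  t_rel <- stats::rexp(n_pat, h_rel)
  t_comp <- stats::rexp(n_pat, config$competing_hazard)
  t_min <- pmin(t_rel, t_comp)
  censored <- t_min > config$censor_time_years
  patients$outcome <- ifelse(censored, "CR1",
                        ifelse(t_rel < t_comp, "relapse",
                               sample(COMPETING_EVENTS, n_pat, replace = TRUE,
                                      prob = c(0.5, 0.25, 0.25))))
  patients$time_to_event_years <- round(
    ifelse(censored, config$censor_time_years, t_min), 3)
  patients <- patient_meta(patients)

  patient_truth <- data.frame(
    patient_id = patients$patient_id,
    pathway_mutated = pw_flag,
    relapse_hazard = h_rel,
    hypermutator = patients$patient_id %in% hyper_ids,
    stringsAsFactors = FALSE)

  structure(list(mutations = mutations, patients = patients,
                 truth = list(mutation_truth = mutation_truth,
                              patient_truth = patient_truth),
                 genes = genes, genome = genome, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d patients, %d mutations, %d genes (seed %d)\n",
              nrow(x$patients), nrow(x$mutations), nrow(x$genes),
              x$config$seed))
  invisible(x)
}
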