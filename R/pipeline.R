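#' Default pipeline configuration
#'
#' Pipeline parameters on top of the generator defaults: stage
#' parameters for boundary estimation, signature extraction, driver
#' discovery, the relapse screen and evolution analysis. Any subset can
#' be overridden via a YAML file or a named list handed to
#' [run_pipeline()].
#'
#' @return named list.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    boundary = NA_real_,          # NA = estimate from the data
    k_signatures = 3L,
    nmf_restarts = 50L,
    q_threshold = 0.1,
    min_mutated = 5L,
    screen_subgroup = "BCP-ALL",
    rescue_af_ceiling = 0.02,
    rescue_min_alt_reads = 2L,
    clone_af_tolerance = 0.05,
    isolate_hypermutators = TRUE)
}

load_pipeline_config <- function(config = NULL, seed = NULL) {
  cfg <- pipeline_defaults()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.list(config)) cfg[names(config)] <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2^31)
}

write_stage_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# somaticALL %s config_hash=%s",
                     as.character(utils::packageVersion("somaticALL")),
                     config_hash(cfg)), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "NA"))
  path
}

read_stage_tsv <- function(outdir, name, stage_needed) {
  path <- file.path(outdir, name)
  if (!file.exists(path))
    stop("missing artifact ", name, "; run the '", stage_needed,
         "' stage first", call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, quote = "", check.names = FALSE)
}

signature_groups <- function(patients, isolate_hyper, hyper_ids) {
  subsets <- driver_subgroups(patients)
  assign_one <- function(pid) {
    for (g in c("T-ALL", "HeH", "t(12;21)", "normal"))
      if (pid %in% subsets[[g]]) return(g)
    "BCP-ALL"
  }
  grp <- vapply(patients$patient_id, assign_one, "")
  if (isolate_hyper && length(hyper_ids))
    grp[patients$patient_id %in% hyper_ids] <- "hypermutator"
  stats::setNames(grp, patients$patient_id)
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (generate a synthetic cohort with relapse
#' pairs and write every input table), `clonality` (AF boundary,
#' clonal/subclonal labels, burden and spectrum tables), `signatures`
#' (context matrix, panel correction, NMF, catalogue matching),
#' `drivers` (per-subgroup statistics and consensus list), `survival`
#' (gene and pathway relapse screens), `evolution` (paired
#' diagnosis/relapse calls, clone groups, relapse-associated genes),
#' `report` (plain-text summary tables) and `all`. Each stage reads its
#' inputs from and writes its TSV artifacts to `outdir`, and appends a
#' run record to `manifest.json`.
#'
#' @param subcommand one of the above.
#' @param config optional YAML path or named list overriding
#'   [pipeline_defaults()] entries.
#' @param outdir artifact directory (created if needed).
#' @param seed optional integer overriding `config$seed`.
#' @return invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "clonality",
                                        "signatures", "drivers", "survival",
                                        "evolution", "report"),
                         config = NULL, outdir = "somaticall_out",
                         seed = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- load_pipeline_config(config, seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (subcommand == "all")
    c("simulate", "clonality", "signatures", "drivers", "survival",
      "evolution", "report") else subcommand
  written <- character(0)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message("[somaticALL] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  out <- function(df, name) {
    written <<- c(written, write_stage_tsv(df, file.path(outdir, name), cfg))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      sim_cfg <- sim_config(seed = cfg$seed)
      cohort <- simulate_cohort(sim_cfg)
      if (any(cohort$patients$outcome == "relapse"))
        cohort <- simulate_relapse_pairs(cohort)
      say("simulate: %d patients, %d mutation rows, %d paired patients",
          nrow(cohort$patients), nrow(cohort$mutations),
          length(cohort$pairs))
      out(cohort$mutations, "mutations.tsv")
      out(cohort$patients, "patients.tsv")
      out(cohort$genes, "genes.tsv")
      out(cohort$truth$mutation_truth, "truth_mutations.tsv")
      out(cohort$truth$patient_truth, "truth_patients.tsv")
      if (!is.null(cohort$truth$pair_truth))
        out(cohort$truth$pair_truth, "truth_pairs.tsv")
      fasta <- file.path(outdir, "genome.fasta")
      Biostrings::writeXStringSet(cohort$genome, fasta)
      written <- c(written, fasta)
      # a panel BED covering every second gene, for motif correction
      gsel <- cohort$genes[seq(1, nrow(cohort$genes), by = 2), ]
      bed <- data.frame(chrom = gsel$chrom, start = gsel$start - 1L,
                        end = gsel$end)
      utils::write.table(bed, file.path(outdir, "panel.bed"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      written <- c(written, file.path(outdir, "panel.bed"))
    } else if (stage == "clonality") {
      mut <- read_stage_tsv(outdir, "mutations.tsv", "simulate")
      pat <- read_stage_tsv(outdir, "patients.tsv", "simulate")
      dia <- mut[mut$timepoint == "diagnosis" & mut$called, ]
      sexes <- stats::setNames(pat$sex, pat$patient_id)
      pf <- ploidy_factor(dia$chrom, sexes[dia$patient_id])
      bnd <- if (is.na(cfg$boundary))
        estimate_af_boundary(dia$af[dia$af > 0] / pf[dia$af > 0])
      else cfg$boundary
      cl <- classify_clonality(dia, bnd, sexes)
      say("clonality: boundary %.3f, %d clonal / %d subclonal",
          attr(cl, "boundary"), sum(cl$label == "clonal"),
          sum(cl$label == "subclonal"))
      out(cl, "clonality.tsv")
      counts <- table(factor(dia$patient_id, levels = pat$patient_id))
      grp <- split(as.vector(counts), pat$immunophenotype)
      bt <- compare_burden(list(T = grp$T, BCP = grp$BCP))
      out(bt, "burden_test.tsv")
      snv <- dia[dia$variant_class == "SNV", ]
      out(as.data.frame(substitution_spectrum(
        snv, pat$immunophenotype[match(snv$patient_id, pat$patient_id)])),
        "spectrum.tsv")
    } else if (stage == "signatures") {
      mut <- read_stage_tsv(outdir, "mutations.tsv", "simulate")
      pat <- read_stage_tsv(outdir, "patients.tsv", "simulate")
      tpat <- read_stage_tsv(outdir, "truth_patients.tsv", "simulate")
      fasta <- file.path(outdir, "genome.fasta")
      if (!file.exists(fasta))
        stop("missing artifact genome.fasta; run the 'simulate' stage first",
             call. = FALSE)
      snv <- mut[mut$timepoint == "diagnosis" & mut$called &
                   mut$variant_class == "SNV", ]
      grp <- signature_groups(pat, cfg$isolate_hypermutators,
                              tpat$patient_id[tpat$hypermutator])
      cm <- extract_contexts(mutation_records(snv), fasta,
                             grp[snv$patient_id])
      panel <- kmer_frequencies(fasta, file.path(outdir, "panel.bed"))
      genome <- kmer_frequencies(fasta)
      cmc <- normalize_motifs(cm, panel, genome)
      sigs <- nmf_decompose(cmc, cfg$k_signatures, seed = cfg$seed,
                            n_restarts = cfg$nmf_restarts)
      mt <- match_signatures(sigs, read_signature_catalog())
      say("signatures: %d SNV contexts, k=%d, best matches %s",
          sum(cm), cfg$k_signatures,
          paste(mt$matches$match, collapse = ", "))
      out(data.frame(group = rownames(cm), unclass(cm),
                     check.names = FALSE), "context_matrix.tsv")
      out(data.frame(signature = rownames(sigs$signatures),
                     sigs$signatures, check.names = FALSE),
          "signatures.tsv")
      out(data.frame(group = rownames(sigs$exposures), sigs$exposures,
                     check.names = FALSE), "exposures.tsv")
      out(mt$matches, "signature_matches.tsv")
    } else if (stage == "drivers") {
      mut <- read_stage_tsv(outdir, "mutations.tsv", "simulate")
      pat <- read_stage_tsv(outdir, "patients.tsv", "simulate")
      genes <- read_stage_tsv(outdir, "genes.tsv", "simulate")
      dia <- mutation_records(mut[mut$timepoint == "diagnosis" & mut$called, ])
      calls <- driver_calls(dia, pat, genes, seed = cfg$seed)
      cons <- consensus_drivers(calls, dia, q_threshold = cfg$q_threshold)
      drv <- cons$gene[cons$is_driver]
      say("drivers: %d genes tested, %d consensus drivers",
          length(unique(calls$gene)), length(drv))
      out(calls, "driver_calls.tsv")
      out(cons, "consensus_drivers.tsv")
      out(driver_summary(drv, dia, pat), "driver_summary.tsv")
    } else if (stage == "survival") {
      mut <- read_stage_tsv(outdir, "mutations.tsv", "simulate")
      pat <- read_stage_tsv(outdir, "patients.tsv", "simulate")
      dia <- mut[mut$timepoint == "diagnosis" & mut$called, ]
      pmap <- default_pathway_map()
      sg <- relapse_screen(dia, pat, unit = "gene",
                           min_mutated = cfg$min_mutated,
                           subgroup = cfg$screen_subgroup)
      sp <- relapse_screen(dia, pat, unit = "pathway", pathway_map = pmap,
                           min_mutated = cfg$min_mutated,
                           subgroup = cfg$screen_subgroup)
      say("survival (%s): %d genes, %d pathways tested; top pathway %s p=%.4g",
          cfg$screen_subgroup, nrow(sg), nrow(sp),
          if (nrow(sp)) sp$unit[1] else "none",
          if (nrow(sp)) sp$bonferroni_p[1] else NA)
      out(sg, "relapse_screen_genes.tsv")
      out(sp, "relapse_screen_pathways.tsv")
      relapsed <- pat[pat$immunophenotype == "BCP", ]
      cif <- cumulative_incidence(survival_records(relapsed))
      out(as.data.frame(cif), "cif_relapse_bcp.tsv")
    } else if (stage == "evolution") {
      mut <- read_stage_tsv(outdir, "mutations.tsv", "simulate")
      pat <- read_stage_tsv(outdir, "patients.tsv", "simulate")
      paired_ids <- unique(mut$patient_id[mut$timepoint != "diagnosis"])
      if (!length(paired_ids)) {
        say("evolution: no paired patients; stage not applicable")
        out(data.frame(note = "no paired diagnosis/relapse samples"),
            "evolution_calls.tsv")
        next
      }
      calls <- classify_status(mut[mut$patient_id %in% paired_ids, ])
      calls <- rescue_low_af(calls, af_ceiling = cfg$rescue_af_ceiling,
                             min_alt_reads = cfg$rescue_min_alt_reads)
      calls <- flag_rising(calls)
      clones <- group_clones(calls, af_tolerance = cfg$clone_af_tolerance)
      rg <- relapse_associated_genes(
        calls, mut[mut$timepoint == "diagnosis" & mut$called, ], pat)
      say("evolution: %d paired patients, %d shared / %d lost / %d gained (%d rescued), %d relapse genes",
          length(paired_ids), sum(calls$status == "shared"),
          sum(calls$status == "diagnosis_only"),
          sum(calls$status == "relapse_gained"), sum(calls$rescued),
          sum(rg$flagged))
      out(calls, "evolution_calls.tsv")
      out(clones, "clone_groups.tsv")
      out(rg, "relapse_genes.tsv")
    } else if (stage == "report") {
      rpt <- c("somaticALL run report",
               paste("config hash:", config_hash(cfg)), "")
      ds <- file.path(outdir, "driver_summary.tsv")
      if (file.exists(ds))
        rpt <- c(rpt, "== subtype / driver summary ==",
                 readLines(ds)[-1], "")
      ec <- file.path(outdir, "evolution_calls.tsv")
      if (file.exists(ec)) {
        calls <- utils::read.table(ec, header = TRUE, sep = "\t",
                                   comment.char = "#",
                                   stringsAsFactors = FALSE)
        if ("status" %in% names(calls)) {
          drv_genes <- character(0)
          cd <- file.path(outdir, "consensus_drivers.tsv")
          if (file.exists(cd)) {
            cons <- utils::read.table(cd, header = TRUE, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE)
            drv_genes <- cons$gene[cons$is_driver]
          }
          if (length(drv_genes)) {
            gl <- driver_gain_loss_summary(calls, drv_genes)
            rpt <- c(rpt, "== driver gain/loss at relapse ==",
                     utils::capture.output(print(gl, row.names = FALSE)), "")
          }
        } else {
          rpt <- c(rpt, "== clonal evolution: not applicable ==", "")
        }
      }
      rgp <- file.path(outdir, "relapse_genes.tsv")
      if (file.exists(rgp))
        rpt <- c(rpt, "== relapse-associated genes ==",
                 readLines(rgp)[-1], "")
      writeLines(rpt, file.path(outdir, "report.txt"))
      written <- c(written, file.path(outdir, "report.txt"))
      say("report written")
    }
  }
  manifest <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   subcommand = subcommand, seed = cfg$seed,
                   config = cfg[order(names(cfg))],
                   config_hash = config_hash(cfg), log = log_lines,
                   artifacts = basename(written))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(written)
}

#' Built-in gene-to-pathway map
#'
#' A small KEGG-style many-to-many map covering the simulated panel:
#' Notch, Ras and a few other signalling/chromatin groupings. Genes may
#' belong to several pathways.
#'
#' @return data.frame with columns gene, pathway.
#' @export
default_pathway_map <- function() {
  rbind(
    data.frame(gene = c("NOTCH1", "NOTCH2", "CREBBP", "EP300", "MAML2",
                        "HDAC2", "DTX1"), pathway = "Notch signaling",
               stringsAsFactors = FALSE),
    data.frame(gene = c("KRAS", "NRAS", "PTPN11", "FLT3"),
               pathway = "Ras signaling", stringsAsFactors = FALSE),
    data.frame(gene = c("CREBBP", "EP300", "KMT2D", "WHSC1", "ARID1A",
                        "ATRX", "PHF6", "HDAC2"),
               pathway = "Chromatin modification", stringsAsFactors = FALSE),
    data.frame(gene = c("IL7R", "FLT3", "PTPN11", "SH2B3"),
               pathway = "Cytokine signaling", stringsAsFactors = FALSE),
    data.frame(gene = c("PTEN", "FBXW7", "ETV6", "EBF1"),
               pathway = "Transcriptional regulation",
               stringsAsFactors = FALSE))
}
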