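#' @keywords internal
"_PACKAGE"

#' Recognised timepoint, variant-class and effect labels
#'
#' Mutation tables use a fixed vocabulary: `timepoint` is one of
#' `"diagnosis"`, `"relapse1"`, `"relapse2"`; `variant_class` is one of
#' `"SNV"`, `"insertion"`, `"deletion"`; `effect` is one of the seven
#' consequence classes below, of which the first five are non-silent
#' (protein-altering).
#'
#' @format Character vectors.
#' @name vocab
NULL

#' @rdname vocab
#' @export
TIMEPOINTS <- c("diagnosis", "relapse1", "relapse2")

#' @rdname vocab
#' @export
VARIANT_CLASSES <- c("SNV", "insertion", "deletion")

#' @rdname vocab
#' @export
EFFECT_CLASSES <- c("nsSNV", "nonsense", "frameshift", "nonframeshift_indel",
                    "splice", "silent", "noncoding")

#' @rdname vocab
#' @export
NON_SILENT_EFFECTS <- c("nsSNV", "nonsense", "frameshift",
                        "nonframeshift_indel", "splice")

SUBTYPES <- c("HeH", "t(12;21)", "t(9;22)", "11q23/MLL", "iAMP21", "t(1;19)",
              "dic(9;20)", "gt67chr", "other", "normal", "T-ALL")

OUTCOMES <- c("CR1", "relapse", "DCR1", "SMN", "resistant")

#' @rdname vocab
#' @export
MUTATION_COLUMNS <- c("patient_id", "sample_id", "timepoint", "chrom", "pos",
                      "ref", "alt", "variant_class", "effect", "gene", "af",
                      "alt_reads", "depth", "called")

#' Construct and validate a table of somatic mutation records
#'
#' One row per (variant, sample, timepoint). Coordinates are 1-based,
#' fully closed, VCF-style; indels are expected left-normalized with an
#' anchor base. When `af` is missing and `depth > 0`, it is filled in as
#' `alt_reads / depth`.
#'
#' @param df data.frame with (at least) the columns named in
#'   [MUTATION_COLUMNS]. `gene` may be `NA` for intergenic records; `af`
#'   may be `NA` when no read support was assayed.
#' @return The validated data.frame, with `af` completed, invisibly of
#'   class `data.frame`.
#' @export
mutation_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(MUTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("mutation table lacks columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), MUTATION_COLUMNS)
  df <- as.data.frame(df)[, c(MUTATION_COLUMNS, extra), drop = FALSE]
  df$pos <- as.integer(df$pos)
  df$alt_reads <- as.integer(df$alt_reads)
  df$depth <- as.integer(df$depth)
  df$af <- as.numeric(df$af)
  df$called <- as.logical(df$called)

  check_row <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad))
      stop(sprintf("invalid mutation record (row %d): %s", bad[1], what))
  }
  check_row(df$timepoint %in% TIMEPOINTS, "unknown timepoint label")
  check_row(df$variant_class %in% VARIANT_CLASSES, "unknown variant_class")
  check_row(df$effect %in% EFFECT_CLASSES, "unknown effect class")
  check_row(df$pos >= 1L, "pos must be >= 1")
  check_row(df$alt_reads >= 0L & df$depth >= 0L, "negative read counts")
  check_row(df$alt_reads <= df$depth, "alt_reads exceeds depth")
  check_row(!(df$variant_class == "SNV" & df$ref == df$alt),
            "ref == alt for an SNV")

  fill <- is.na(df$af) & df$depth > 0L
  df$af[fill] <- df$alt_reads[fill] / df$depth[fill]
  with_af <- !is.na(df$af) & df$depth > 0L
  check_row(!with_af | abs(df$af - df$alt_reads / df$depth) <= 0.01 + 1e-12,
            "af inconsistent with alt_reads/depth")
  check_row(is.na(df$af) | (df$af >= 0 & df$af <= 1), "af outside [0, 1]")
  df
}

#' Variant key: one string per genomic change
#'
#' @param df mutation records (or any data.frame with chrom/pos/ref/alt).
#' @return character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Read somatic mutation calls from TSV or VCF
#'
#' The TSV dialect is a header line with the columns in [MUTATION_COLUMNS]
#' (`NA` for missing gene/af). The VCF dialect is VCF 4.x with per-sample
#' `AD` (ref,alt depths) and `DP` FORMAT fields; sample names must follow
#' `<patient_id>.<timepoint>` so that each genotype column maps to one
#' sample at one timepoint. Optional INFO keys `GENE`, `EFFECT` and
#' `CLASS` carry the annotation; records lacking them default to
#' `noncoding`/class inferred from allele lengths.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return validated mutation records (see [mutation_records()]).
#' @export
read_mutations <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    classes <- c(patient_id = "character", sample_id = "character",
                 timepoint = "character", chrom = "character",
                 pos = "integer", ref = "character", alt = "character",
                 variant_class = "character", effect = "character",
                 gene = "character", af = "numeric", alt_reads = "integer",
                 depth = "integer", called = "logical")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = classes,
                            stringsAsFactors = FALSE, na.strings = "NA",
                            comment.char = "#", quote = "")
    return(mutation_records(df))
  }
  read_mutations_vcf(path)
}

read_mutations_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP")
  gt <- vcfR::extract.gt(v, element = "GT")
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_field("GENE")
  effect <- info_field("EFFECT")
  vclass <- info_field("CLASS")

  samples <- colnames(ad)
  parts <- strsplit(samples, ".", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("VCF sample name not of form <patient>.<timepoint>: ", samples[bad][1])
  tp <- vapply(parts, `[[`, "", 2L)
  if (any(!tp %in% TIMEPOINTS))
    stop("unknown timepoint label in VCF sample name: ", tp[!tp %in% TIMEPOINTS][1])

  rows <- list()
  for (j in seq_along(samples)) {
    present <- !is.na(ad[, j])
    if (!any(present)) next
    ad_parts <- strsplit(ad[present, j], ",", fixed = TRUE)
    alt_reads <- as.integer(vapply(ad_parts, `[[`, "", 2L))
    depth <- as.integer(dp[present, j])
    infer_class <- ifelse(nchar(fix$REF[present]) == nchar(fix$ALT[present]),
                          "SNV",
                   ifelse(nchar(fix$REF[present]) < nchar(fix$ALT[present]),
                          "insertion", "deletion"))
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = vapply(parts, `[[`, "", 1L)[j],
      sample_id = samples[j],
      timepoint = tp[j],
      chrom = fix$CHROM[present],
      pos = as.integer(fix$POS[present]),
      ref = fix$REF[present],
      alt = fix$ALT[present],
      variant_class = ifelse(is.na(vclass[present]), infer_class,
                             vclass[present]),
      effect = ifelse(is.na(effect[present]), "noncoding", effect[present]),
      gene = gene[present],
      af = NA_real_,
      alt_reads = alt_reads,
      depth = depth,
      called = !is.na(gt[present, j]) & gt[present, j] != "0/0",
      stringsAsFactors = FALSE)
  }
  mutation_records(do.call(rbind, rows))
}

#' Write mutation records as TSV (the dialect [read_mutations()] reads)
#'
#' @param records mutation records.
#' @param path output file.
#' @export
write_mutations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write mutation records as a minimal VCF 4.2 file
#'
#' One genotype column per `<patient_id>.<timepoint>` sample; AD/DP carry
#' read support and INFO carries GENE/EFFECT/CLASS so that a round trip
#' through [read_mutations()] preserves the annotation.
#'
#' @param records mutation records.
#' @param path output file.
#' @export
write_mutations_vcf <- function(records, path) {
  samples <- unique(paste(records$patient_id, records$timepoint, sep = "."))
  keys <- unique(variant_key(records))
  rec1 <- records[!duplicated(variant_key(records)), , drop = FALSE]
  rownames(rec1) <- variant_key(rec1)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticALL",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rec_sample <- paste(records$patient_id, records$timepoint, sep = ".")
  lines <- vapply(keys, function(k) {
    r <- rec1[k, ]
    info <- sprintf("GENE=%s;EFFECT=%s;CLASS=%s",
                    ifelse(is.na(r$gene), ".", r$gene), r$effect,
                    r$variant_class)
    cells <- vapply(samples, function(s) {
      i <- which(rec_sample == s & variant_key(records) == k)
      if (!length(i)) return("./.:.:.")
      ri <- records[i[1], ]
      sprintf("%s:%d,%d:%d", if (isTRUE(ri$called)) "0/1" else "./.",
              ri$depth - ri$alt_reads, ri$alt_reads, ri$depth)
    }, "")
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", info, "GT:AD:DP",
            cells), collapse = "\t")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Somatic filtering policy
#'
#' Thresholds applied by [filter_somatic()]. Blacklists are data.frames
#' with columns chrom/pos/ref/alt: `germline_blacklist` holds variants
#' seen in matched-remission samples, `population_blacklist` variants
#' from a population panel. Defaults reflect calling-grade records from
#' deep targeted panels; low-AF rescue genotyping deliberately bypasses
#' this policy.
#'
#' @param min_depth,min_alt_reads,min_af numeric thresholds (all >= 0).
#' @param germline_blacklist,population_blacklist data.frames
#'   (chrom, pos, ref, alt) or NULL.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_depth = 20, min_alt_reads = 4, min_af = 0.05,
                          germline_blacklist = NULL,
                          population_blacklist = NULL) {
  stopifnot(min_depth >= 0, min_alt_reads >= 0, min_af >= 0)
  bl_keys <- function(bl) {
    if (is.null(bl) || !nrow(bl)) character(0) else variant_key(bl)
  }
  structure(list(min_depth = min_depth, min_alt_reads = min_alt_reads,
                 min_af = min_af,
                 germline_keys = bl_keys(germline_blacklist),
                 population_keys = bl_keys(population_blacklist)),
            class = "filter_policy")
}

#' Filter mutation records to somatic calling-grade records
#'
#' Records must meet depth, alt-read and AF thresholds and must not sit at
#' a germline- or population-blacklisted site. Each dropped record is
#' tagged with the first failing reason, checked in the order
#' depth, alt_reads, af, germline, population.
#'
#' @param records mutation records.
#' @param policy a [filter_policy()].
#' @return list with elements `kept` (mutation records) and `dropped`
#'   (records plus a `reason` column).
#' @export
filter_somatic <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (!nrow(records)) {
    return(list(kept = records,
                dropped = cbind(records, reason = character(0))))
  }
  keys <- variant_key(records)
  reason <- rep(NA_character_, nrow(records))
  af <- ifelse(is.na(records$af), 0, records$af)
  reason[is.na(reason) & records$depth < policy$min_depth] <- "depth"
  reason[is.na(reason) & records$alt_reads < policy$min_alt_reads] <- "alt_reads"
  reason[is.na(reason) & af < policy$min_af] <- "af"
  reason[is.na(reason) & keys %in% policy$germline_keys] <- "germline"
  reason[is.na(reason) & keys %in% policy$population_keys] <- "population"
  keep <- is.na(reason)
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

#' Is a mutation protein-altering (non-silent)?
#'
#' @param record a mutation record data.frame (one or more rows), or a
#'   character vector of effect classes.
#' @return logical vector: TRUE iff the effect is one of
#'   [NON_SILENT_EFFECTS].
#' @export
classify_non_silent <- function(record) {
  effect <- if (is.character(record)) record else record$effect
  effect %in% NON_SILENT_EFFECTS
}

#' Construct and validate patient metadata
#'
#' @param df data.frame with columns patient_id, immunophenotype
#'   (BCP/T), subtype, age_years, sex (M/F), blast_fraction, outcome,
#'   time_to_event_years, cohort (core/diagnostic_only/extension).
#' @return validated data.frame.
#' @export
patient_meta <- function(df) {
  need <- c("patient_id", "immunophenotype", "subtype", "age_years", "sex",
            "blast_fraction", "outcome", "time_to_event_years", "cohort")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("patient table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)
  stopifnot(all(df$immunophenotype %in% c("BCP", "T")),
            all(df$subtype %in% SUBTYPES),
            all(df$sex %in% c("M", "F")),
            all(df$outcome %in% OUTCOMES),
            all(df$age_years >= 0),
            all(df$blast_fraction >= 0 & df$blast_fraction <= 1),
            all(df$time_to_event_years >= 0),
            all(df$cohort %in% c("core", "diagnostic_only", "extension")),
            !anyDuplicated(df$patient_id))
  t_mismatch <- xor(df$subtype == "T-ALL", df$immunophenotype == "T")
  if (any(t_mismatch))
    stop("subtype T-ALL must coincide with immunophenotype T (patient ",
         df$patient_id[t_mismatch][1], ")")
  df
}

#' Gene model table
#'
#' @param df data.frame with columns gene, chrom, coding_length_bp and
#'   optionally expressed_fpkm.
#' @return validated data.frame.
#' @export
gene_model <- function(df) {
  stopifnot(all(c("gene", "chrom", "coding_length_bp") %in% names(df)),
            all(df$coding_length_bp > 0),
            !anyDuplicated(df$gene))
  if (is.null(df$expressed_fpkm)) df$expressed_fpkm <- NA_real_
  as.data.frame(df)
}
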