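#' Canonical 96 trinucleotide substitution contexts
#'
#' Pyrimidine-centered contexts in fixed lexicographic order: the six
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each crossed with
#' the sixteen 5'/3' flank pairs (A, C, G, T x A, C, G, T). Labels look
#' like `"A[C>A]A"`.
#'
#' @return character vector of length 96.
#' @export
contexts96 <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(classes, function(cl) {
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", cl, "]", r))))
  }))
}

#' The 32 pyrimidine-centered trinucleotide motifs
#'
#' @return character vector: 16 NCN motifs then 16 NTN motifs, flanks in
#'   A, C, G, T order.
#' @export
motifs32 <- function() {
  bases <- c("A", "C", "G", "T")
  c(as.vector(t(outer(bases, bases, function(l, r) paste0(l, "C", r)))),
    as.vector(t(outer(bases, bases, function(l, r) paste0(l, "T", r)))))
}

#' Motif underlying each of the 96 contexts
#' @return named character vector mapping context label to its central
#'   pyrimidine trinucleotide (e.g. `"A[C>A]G"` -> `"ACG"`).
#' @export
context_motifs <- function() {
  ctx <- contexts96()
  stats::setNames(paste0(substr(ctx, 1, 1), substr(ctx, 3, 3),
                         substr(ctx, 7, 7)), ctx)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Collapse a single substitution to its pyrimidine-centered context label
#'
#' @param trinuc reference trinucleotide around the variant (5'-to-3').
#' @param ref,alt reference and alternate base of the SNV; `ref` must be
#'   the central base of `trinuc`.
#' @return context label as in [contexts96()].
#' @keywords internal
collapse_context <- function(trinuc, ref, alt) {
  stopifnot(nchar(trinuc) == 3L)
  if (substr(trinuc, 2, 2) != ref)
    stop("central base of trinucleotide does not match ref allele")
  if (ref %in% c("G", "A")) {
    trinuc <- revcomp_chr(trinuc)
    ref <- chartr("GA", "CT", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  paste0(substr(trinuc, 1, 1), "[", ref, ">", alt, "]", substr(trinuc, 3, 3))
}

fetcher_from_reference <- function(reference) {
  if (is.function(reference)) return(reference)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (!inherits(reference, "DNAStringSet"))
    stop("reference must be a DNAStringSet, FASTA path, or fetcher function")
  nm <- names(reference)
  # strip FASTA description after first whitespace
  names(reference) <- sub("\\s.*$", "", nm)
  function(chrom, pos) {
    if (!chrom %in% names(reference))
      stop("flank retrieval failed at ", chrom, ":", pos,
           " (no such sequence)")
    s <- reference[[chrom]]
    if (pos < 2L || pos > length(s) - 1L)
      stop("flank retrieval failed at ", chrom, ":", pos,
           " (position too close to sequence end)")
    as.character(Biostrings::subseq(s, pos - 1L, pos + 1L))
  }
}

#' Tabulate 96-context counts of SNVs per group
#'
#' Recurrent SNVs (identical chrom/pos/ref/alt seen in more than one
#' patient) are excluded before counting, so that a single mutational
#' event cannot be counted repeatedly. Purine-reference substitutions are
#' reverse-complemented into the pyrimidine-centered classes.
#'
#' @param snvs mutation records, SNVs only.
#' @param reference a `Biostrings::DNAStringSet` (names = chromosomes), a
#'   FASTA path, or a function `(chrom, pos) -> trinucleotide` returning
#'   the reference trinucleotide centered on `pos`.
#' @param groups character vector, one group label per row of `snvs`.
#' @return integer matrix, groups x 96, with a `"context_matrix"` class
#'   attribute; column order as [contexts96()].
#' @export
extract_contexts <- function(snvs, reference, groups) {
  stopifnot(nrow(snvs) == length(groups))
  if (any(snvs$variant_class != "SNV")) stop("extract_contexts expects SNVs only")
  fetch <- fetcher_from_reference(reference)

  key <- variant_key(snvs)
  patients_per_key <- tapply(snvs$patient_id, key,
                             function(p) length(unique(p)))
  recurrent <- names(patients_per_key)[patients_per_key > 1L]
  keep <- !(key %in% recurrent)
  snvs <- snvs[keep, , drop = FALSE]
  groups <- groups[keep]

  ctx_levels <- contexts96()
  out <- matrix(0L, nrow = length(unique(groups)), ncol = 96,
                dimnames = list(unique(groups), ctx_levels))
  if (nrow(snvs)) {
    labels <- character(nrow(snvs))
    for (i in seq_len(nrow(snvs))) {
      tri <- fetch(snvs$chrom[i], snvs$pos[i])
      if (substr(tri, 2, 2) != snvs$ref[i])
        stop(sprintf("reference base mismatch at %s:%d (FASTA %s, record %s)",
                     snvs$chrom[i], snvs$pos[i], substr(tri, 2, 2),
                     snvs$ref[i]))
      labels[i] <- collapse_context(tri, snvs$ref[i], snvs$alt[i])
    }
    tab <- table(factor(groups, levels = rownames(out)),
                 factor(labels, levels = ctx_levels))
    out[] <- as.integer(tab)
  }
  structure(out, class = c("context_matrix", class(out)))
}

#' Trinucleotide motif frequencies of a sequence region
#'
#' Counts all 3-mers of the given sequences (optionally restricted to BED
#' regions), collapses purine-centered motifs onto their reverse
#' complement, and normalizes the 32 pyrimidine-centered motif counts to
#' frequencies summing to one. Windows containing ambiguous bases are
#' skipped.
#'
#' @param fasta a FASTA path or `Biostrings::DNAStringSet`.
#' @param regions optional BED path or data.frame (chrom, start, end;
#'   0-based half-open) restricting the count to those intervals.
#' @return named numeric vector over [motifs32()], summing to 1.
#' @export
kmer_frequencies <- function(fasta, regions = NULL) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(regions)) {
    if (is.character(regions))
      regions <- utils::read.table(regions, sep = "\t",
                                   col.names = c("chrom", "start", "end"),
                                   stringsAsFactors = FALSE)
    if (!nrow(regions)) stop("empty region set")
    parts <- lapply(seq_len(nrow(regions)), function(i) {
      chrom <- regions$chrom[i]
      if (!chrom %in% names(seqs)) stop("region on unknown sequence: ", chrom)
      Biostrings::subseq(seqs[[chrom]], regions$start[i] + 1L, regions$end[i])
    })
    seqs <- Biostrings::DNAStringSet(parts)
  }
  counts64 <- colSums(Biostrings::trinucleotideFrequency(seqs, step = 1))
  motifs <- motifs32()
  out <- stats::setNames(numeric(32), motifs)
  for (m in motifs) out[m] <- counts64[m] + counts64[revcomp_chr(m)]
  total <- sum(out)
  if (total == 0) stop("no unambiguous trinucleotides in the region")
  out / total
}

#' Correct a context matrix for panel vs genome motif composition
#'
#' A targeted panel over- or under-represents some trinucleotide motifs
#' relative to the whole genome; per-context counts are rescaled by
#' `genome_freq / target_freq` of the context's central motif so that
#' downstream signature decomposition reflects genome-scale processes.
#' Total counts are not conserved under this scaling. Swapping the two
#' frequency arguments inverts the correction exactly.
#'
#' @param mat context matrix (groups x 96).
#' @param target motif frequencies of the sequenced target region
#'   ([kmer_frequencies()] output); must be strictly positive.
#' @param genome motif frequencies of the whole genome.
#' @return corrected context matrix (numeric).
#' @export
normalize_motifs <- function(mat, target, genome) {
  motifs <- motifs32()
  stopifnot(all(motifs %in% names(target)), all(motifs %in% names(genome)))
  if (any(target[motifs] <= 0)) stop("target motif frequencies must be > 0")
  ratio <- genome[context_motifs()] / target[context_motifs()]
  out <- sweep(unclass(mat)[, contexts96(), drop = FALSE], 2, ratio, `*`)
  structure(out, class = c("context_matrix", class(out)))
}
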