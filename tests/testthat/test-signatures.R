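test_that("context tabulation collapses strands and drops recurrent SNVs", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTTACGT"))
  #                                       123456789
  # pos 3 = C in context ACG; pos 8 = C in context ACG
  snvs <- make_muts(
    make_mut("P1", pos = 3L, ref = "C", alt = "T", af = 0.3,
             alt_reads = 30L, depth = 100L),
    make_mut("P2", pos = 4L, ref = "G", alt = "A", af = 0.3,
             alt_reads = 30L, depth = 100L),       # revcomp -> A[C>T]G
    make_mut("P1", pos = 8L, ref = "C", alt = "T", af = 0.3,
             alt_reads = 30L, depth = 100L),
    make_mut("P2", pos = 8L, ref = "C", alt = "T", af = 0.3,
             alt_reads = 30L, depth = 100L))       # recurrent: excluded
  cm <- extract_contexts(snvs, ref, groups = c("g", "g", "g", "g"))
  expect_equal(sum(cm), 2)               # recurrent pair dropped
  # both remaining SNVs collapse to A[C>T]G (pos 4 via reverse complement)
  expect_equal(unname(cm["g", "A[C>T]G"]), 2)
  expect_equal(colnames(cm), contexts96())

  # reference-base mismatch is an error naming the coordinate
  bad <- make_muts(make_mut("P1", pos = 3L, ref = "A", alt = "T", af = 0.3,
                            alt_reads = 30L, depth = 100L))
  expect_error(extract_contexts(bad, ref, "g"), "chr1:3")
})

test_that("k-mer frequencies collapse to pyrimidine-centered motifs", {
  # "ACGT": trinucleotides ACG, CGT; CGT -> ACG by reverse complement
  f <- kmer_frequencies(Biostrings::DNAStringSet(c(s = "ACGT")))
  expect_equal(unname(f["ACG"]), 1)
  expect_equal(sum(f), 1)
  expect_error(kmer_frequencies(Biostrings::DNAStringSet(c(s = "NNNNNN"))),
               "no unambiguous")
  # BED covering everything is equivalent to the whole sequence
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")))
  whole <- kmer_frequencies(seqs)
  bed <- data.frame(chrom = "chr1", start = 0L, end = 500L)
  expect_equal(kmer_frequencies(seqs, bed), whole)
  expect_error(kmer_frequencies(seqs, bed[0, ]), "empty region")
})

test_that("motif normalization is identity when panel matches genome and is invertible", {
  set.seed(2)
  cm <- matrix(rpois(2 * 96, 20), 2, 96,
               dimnames = list(c("a", "b"), contexts96()))
  freq <- stats::setNames(rep(1 / 32, 32), motifs32())
  expect_equal(unclass(normalize_motifs(cm, freq, freq)),
               unclass(cm)[, contexts96()], ignore_attr = TRUE)

  # a motif twice as frequent in the panel as in the genome is halved
  target <- freq; target["ACA"] <- target["ACA"] * 2
  target <- target / sum(target)
  out <- normalize_motifs(cm, target, freq)
  ratio <- out[, "A[C>A]A"] / cm[, "A[C>A]A"]
  expect_equal(unname(ratio), rep(freq[["ACA"]] / target[["ACA"]], 2))

  # exact inversion by swapping the frequency arguments
  rand_t <- stats::setNames(runif(32, 0.5, 2), motifs32())
  rand_t <- rand_t / sum(rand_t)
  fwd <- normalize_motifs(cm, rand_t, freq)
  back <- normalize_motifs(fwd, freq, rand_t)
  expect_equal(unclass(back), unclass(cm)[, contexts96()],
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- freq; bad["ACA"] <- 0
  expect_error(normalize_motifs(cm, bad, freq), "> 0")
})

test_that("NMF factorizes exactly at rank 1 and decreases its error monotonically", {
  set.seed(4)
  v <- outer(c(1, 2, 3), runif(96, 0.1, 1))
  colnames(v) <- contexts96()
  s <- nmf_decompose(v, 1, seed = 1, n_restarts = 5)
  expect_lt(s$error, 1e-8)
  expect_true(all(diff(s$error_trace) <= 1e-9))
  expect_equal(unname(rowSums(s$signatures)), 1)
  expect_error(nmf_decompose(v, 0, seed = 1), "k must be")
  expect_error(nmf_decompose(matrix(0, 2, 96), 1, seed = 1), "all-zero")
  # determinism under the same seed
  s2 <- nmf_decompose(v, 1, seed = 1, n_restarts = 5)
  expect_identical(s$signatures, s2$signatures)
})

test_that("rank-3 NMF recovers planted signatures when each dominates a group", {
  catal <- read_signature_catalog()
  set.seed(8)
  E <- matrix(runif(18, 0.05, 0.3), 6, 3)
  E[cbind(1:6, rep(1:3, 2))] <- runif(6, 1.5, 2.5)
  V <- E %*% t(catal)
  counts <- matrix(rpois(length(V), V / sum(V) * 50000), nrow(V))
  colnames(counts) <- rownames(catal)
  sigs <- nmf_decompose(counts, 3, seed = 8, n_restarts = 30)
  mt <- match_signatures(sigs, catal)
  expect_setequal(mt$matches$match, colnames(catal))
  expect_gte(min(mt$matches$cosine), 0.9)
})

test_that("signature matching ranks by cosine and clusters the stacked matrix", {
  catal <- read_signature_catalog()
  found <- t(catal[, c("APOBECLike", "Flat")])
  rownames(found) <- c("X1", "X2")
  mt <- match_signatures(found, catal)
  expect_equal(mt$matches$match, c("APOBECLike", "Flat"))
  expect_equal(mt$matches$cosine, c(1, 1))
  expect_s3_class(mt$hclust, "hclust")

  # orthogonal disjoint-support vectors have cosine zero
  a <- c(1, rep(0, 95)); b <- c(0, 1, rep(0, 94))
  m <- matrix(c(a, b), 2, byrow = TRUE, dimnames = list(NULL, contexts96()))
  refm <- matrix(b, 96, 1, dimnames = list(contexts96(), "other"))
  mt2 <- match_signatures(m, refm)
  expect_equal(unname(mt2$cosine[1, 1]), 0)
  expect_equal(unname(mt2$cosine[2, 1]), 1)

  # APOBEC-like mass on T[C>G]A / T[C>G]T matches the APOBEC entry first
  ap <- stats::setNames(rep(0, 96), contexts96())
  ap[c("T[C>G]A", "T[C>G]T")] <- 0.5
  mt3 <- match_signatures(matrix(ap, 1, dimnames = list("q", contexts96())),
                          catal)
  expect_equal(mt3$matches$match, "APOBECLike")

  # context-order mismatch is refused
  shuffled <- catal[c(2:96, 1), ]
  expect_error(match_signatures(found, shuffled), "context order")
})

test_that("cohort context totals equal the non-recurrent SNV count", {
  co <- cached_cohort()
  snv <- co$mutations[co$mutations$variant_class == "SNV" &
                        co$mutations$timepoint == "diagnosis", ]
  key <- variant_key(snv)
  recurrent <- names(which(tapply(snv$patient_id, key,
                                  function(p) length(unique(p))) > 1))
  cm <- extract_contexts(snv, co$genome, rep("all", nrow(snv)))
  expect_equal(sum(cm), sum(!key %in% recurrent))
})
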