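test_that("AF boundary lands in the valley between two planted components", {
  set.seed(42)
  afs <- c(rbeta(500, 7.5, 42.5),   # subclonal component, mean 0.15
           rbeta(500, 21, 29))      # clonal component, mean 0.42
  b <- estimate_af_boundary(afs)
  expect_s3_class(b, "af_boundary")
  expect_gte(b$boundary, 0.25)
  expect_lte(b$boundary, 0.38)
  expect_lt(b$modes[1], b$boundary)
  expect_gt(b$modes[2], b$boundary)
})

test_that("unimodal and undersized inputs yield an explicit no-boundary state", {
  set.seed(1)
  uni <- estimate_af_boundary(rbeta(600, 45, 55))  # single mode near 0.45
  expect_true(is.na(uni$boundary))
  expect_equal(uni$reason, "unimodal")
  expect_error(estimate_af_boundary(runif(10)), "at least 50")
})

test_that("clonality labels follow the adjusted-AF rule and ploidy factors", {
  sexes <- c(P1 = "M", P2 = "F")
  recs <- make_muts(
    make_mut("P1", pos = 1L, af = 0.45, alt_reads = 45L, depth = 100L),
    make_mut("P1", chrom = "chrX", pos = 2L, af = 0.80, alt_reads = 80L,
             depth = 100L),
    make_mut("P2", chrom = "chrX", pos = 3L, af = 0.10, alt_reads = 10L,
             depth = 100L))
  cl <- classify_clonality(recs, 0.32, sexes)
  expect_equal(cl$label, c("clonal", "clonal", "subclonal"))
  expect_equal(cl$ploidy_factor, c(1, 2, 1))   # chrX female is diploid
  expect_equal(cl$adjusted_af[2], 0.40)

  # monotone in af: raising af never flips clonal -> subclonal
  afs <- seq(0.05, 0.95, by = 0.05)
  recs2 <- mutation_records(do.call(rbind, lapply(seq_along(afs), function(i)
    make_mut("P2", pos = i * 5L, af = afs[i],
             alt_reads = as.integer(afs[i] * 100), depth = 100L))))
  lab <- classify_clonality(recs2, 0.32, sexes)$label
  expect_true(all(diff(lab == "clonal") >= 0))
})

test_that("burden comparison matches exact rank-sum enumeration and symmetry", {
  # exhaustive oracle: all C(6,3)=20 rank assignments of {1,2,3} vs {10,11,12}
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  pooled <- c(x, y)
  w_obs <- sum(rank(pooled)[1:3])
  perms <- combn(6, 3)
  w_all <- apply(perms, 2, function(i) sum(rank(pooled)[i]))
  p_exact <- mean(abs(w_all - mean(w_all)) >= abs(w_obs - mean(w_all)))
  expect_equal(p_exact, 0.1)
  res <- compare_burden(list(a = x, b = y))
  expect_equal(res$p, 0.1)

  same <- compare_burden(list(a = c(5, 6, 7, 8), b = c(5, 6, 7, 8)))
  expect_gte(same$p, 0.99)
  expect_error(compare_burden(list(a = 1:5, b = numeric(0))), "at least 3")
})

test_that("burden difference between phenotypes is detected at study effect sizes", {
  # Monte-Carlo power at the published means under the generator's
  # negative-binomial burden model (dispersion 1.5), n = 100 per group;
  # the rejection rate computed by this oracle is ~0.91 at alpha = 0.01
  set.seed(7)
  hits <- 0
  for (r in 1:200) {
    tg <- rnbinom(100, mu = 6.4, size = 1.5)
    bg <- rnbinom(100, mu = 3.5, size = 1.5)
    if (compare_burden(list(T = tg, BCP = bg))$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.85)
  # at the conventional 0.05 level the difference is detected essentially
  # always
  set.seed(8)
  hits05 <- 0
  for (r in 1:100) {
    tg <- rnbinom(100, mu = 6.4, size = 1.5)
    bg <- rnbinom(100, mu = 3.5, size = 1.5)
    if (compare_burden(list(T = tg, BCP = bg))$p < 0.05) hits05 <- hits05 + 1
  }
  expect_gte(hits05 / 100, 0.95)
})

test_that("clonal-fraction chi-square matches the hand formula", {
  tab <- matrix(c(100, 150, 40, 250), 2)   # [[100,40],[150,250]]
  res <- clonal_fraction_test(tab)
  # oracle: direct sum((O-E)^2/E)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$df, 1)
  # row swap leaves the statistic unchanged
  expect_equal(clonal_fraction_test(tab[2:1, ])$statistic, res$statistic)
  # independence
  even <- clonal_fraction_test(matrix(c(50, 50, 50, 50), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  expect_error(clonal_fraction_test(matrix(c(0, 0, 10, 10), 2)), "margin")
})

test_that("substitution spectrum collapses strands and sums to one", {
  recs <- make_muts(
    make_mut(pos = 1L, ref = "G", alt = "A"),   # -> C>T
    make_mut(pos = 2L, ref = "C", alt = "T"),
    make_mut(pos = 3L, ref = "C", alt = "T"),
    make_mut(pos = 4L, ref = "C", alt = "T"))
  sp <- substitution_spectrum(recs, rep("g1", 4))
  expect_equal(unname(sp["g1", ]), c(0, 0, 1, 0, 0, 0))
  expect_error(substitution_spectrum(
    make_muts(make_mut(variant_class = "insertion", ref = "C", alt = "CA",
                       effect = "frameshift")), "g"), "SNVs only")

  # uniform substitutions -> each class near 1/6
  set.seed(3)
  pyr <- c("C", "T")
  refs <- sample(pyr, 6000, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1), "")
  big <- mutation_records(do.call(rbind, lapply(1:6000, function(i)
    make_mut(pos = i, ref = refs[i], alt = alts[i], af = 0.3,
             alt_reads = 30L, depth = 100L))))
  spu <- substitution_spectrum(big, rep("g", 6000))
  expect_true(all(abs(spu - 1 / 6) < 0.02))
  expect_equal(sum(spu), 1, tolerance = 1e-12)
})

test_that("burden-age correlation behaves at the extremes and under the null", {
  expect_equal(burden_age_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(burden_age_correlation(1:10, -(1:10))$rho, -1)
  expect_error(burden_age_correlation(rep(2, 10), 1:10), "constant")
  set.seed(11)
  small <- vapply(1:200, function(i)
    abs(burden_age_correlation(rnorm(100), rnorm(100))$rho) < 0.2, NA)
  expect_gte(mean(small), 0.95)
})

test_that("cohort clonality labels agree with simulation truth away from the boundary", {
  co <- cached_cohort()
  mut <- co$mutations
  sexes <- stats::setNames(co$patients$sex, co$patients$patient_id)
  hyper <- co$truth$patient_truth$patient_id[co$truth$patient_truth$hypermutator]
  core <- !mut$patient_id %in% hyper
  pf <- ploidy_factor(mut$chrom, sexes[mut$patient_id])
  b <- estimate_af_boundary(mut$af[core & mut$af > 0] / pf[core & mut$af > 0])
  expect_false(is.na(b$boundary))
  cl <- classify_clonality(mut, b, sexes)
  m <- merge(cl, co$truth$mutation_truth, by = c("patient_id", "key"))
  away <- abs(m$adjusted_af - b$boundary) > 0.03
  truth_lab <- ifelse(m$clone == 0, "clonal", "subclonal")
  expect_gte(mean(m$label[away] == truth_lab[away]), 0.95)
})
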