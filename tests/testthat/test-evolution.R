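test_that("status classification partitions mutations by called flags", {
  recs <- make_paired(statuses = c(rep("diagnosis_only", 3), rep("shared", 4),
                                   rep("relapse_gained", 3)))
  calls <- classify_status(recs)
  expect_equal(sum(calls$status == "diagnosis_only"), 3L)
  expect_equal(sum(calls$status == "shared"), 4L)
  expect_equal(sum(calls$status == "relapse_gained"), 3L)
  expect_equal(nrow(calls), 10L)                       # exactly one per key
  expect_true(all(table(calls$key) == 1))
  expect_equal(unique(calls$gained_at[calls$status == "relapse_gained"]),
               "relapse1")

  single <- make_muts(make_mut("LONE", "diagnosis"))
  expect_error(classify_status(single), "single timepoint")
})

test_that("second-relapse-only mutations are classified against the first relapse", {
  rows <- rbind(
    make_mut("P9", "diagnosis", pos = 1L, alt_reads = 400L, depth = 1000L),
    make_mut("P9", "relapse1", pos = 1L, alt_reads = 400L, depth = 1000L),
    make_mut("P9", "relapse2", pos = 1L, alt_reads = 400L, depth = 1000L),
    # gained at second relapse, low-level support at first relapse
    make_mut("P9", "diagnosis", pos = 2L, alt_reads = 0L, depth = 900L,
             called = FALSE),
    make_mut("P9", "relapse1", pos = 2L, alt_reads = 4L, depth = 900L,
             called = FALSE),
    make_mut("P9", "relapse2", pos = 2L, alt_reads = 300L, depth = 900L))
  calls <- classify_status(mutation_records(rows))
  g <- calls[calls$status == "relapse_gained", ]
  expect_equal(g$gained_at, "relapse2")
  resc <- rescue_low_af(calls)
  expect_true(resc$rescued[resc$key == g$key])   # 4 reads at AF 0.0044 < 2%
})

test_that("low-AF rescue honors the AF ceiling and read-support threshold", {
  mk <- function(alt_dia, depth_dia = 600L) mutation_records(rbind(
    make_mut("PR", "diagnosis", pos = 7L, alt_reads = alt_dia,
             depth = depth_dia, called = FALSE),
    make_mut("PR", "relapse1", pos = 7L, alt_reads = 200L, depth = 600L),
    make_mut("PR", "diagnosis", pos = 8L, alt_reads = 250L, depth = 600L),
    make_mut("PR", "relapse1", pos = 8L, alt_reads = 260L, depth = 600L)))
  expect_true(rescue_low_af(classify_status(mk(3L)))$rescued[1])
  expect_false(rescue_low_af(classify_status(mk(0L)))$rescued[1])
  # AF 30/600 = 5% is support, but not "low level"
  expect_false(rescue_low_af(classify_status(mk(30L)))$rescued[1])
  # raising min_alt_reads never increases the rescued count
  r2 <- rescue_low_af(classify_status(mk(3L)), min_alt_reads = 2)
  r4 <- rescue_low_af(classify_status(mk(3L)), min_alt_reads = 4)
  expect_lte(sum(r4$rescued), sum(r2$rescued))
})

test_that("the rising rule doubles AF with an inclusive boundary", {
  mk <- function(af_d, af_r) {
    flag_rising(classify_status(make_paired(
      statuses = "shared", af_dia = af_d, af_rel = af_r)))
  }
  expect_true(mk(0.10, 0.25)$rising)
  expect_true(mk(0.20, 0.40)$rising)     # exactly 2x: inclusive
  expect_false(mk(0.30, 0.30)$rising)
  expect_false(mk(0.30, 0.59)$rising)
})

test_that("clone grouping recovers a planted two-clone structure and is order-invariant", {
  set.seed(71)
  mk_clone <- function(prefix, af_d, af_r, n) {
    do.call(rbind, lapply(1:n, function(i) rbind(
      make_mut("PC", "diagnosis", pos = prefix + i,
               alt_reads = as.integer(round((af_d + rnorm(1, 0, 0.01)) * 2000)),
               depth = 2000L),
      make_mut("PC", "relapse1", pos = prefix + i,
               alt_reads = as.integer(round((af_r + rnorm(1, 0, 0.01)) * 2000)),
               depth = 2000L))))
  }
  recs <- mutation_records(rbind(mk_clone(100L, 0.45, 0.44, 4),
                                 mk_clone(900L, 0.15, 0.30, 3)))
  calls <- flag_rising(classify_status(recs))
  cl <- group_clones(calls, af_tolerance = 0.05)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$n_mutations), c(3L, 4L))
  expect_setequal(cl$fate, c("persisting", "expanding"))

  # permutation invariance of the input row order
  perm <- mutation_records(recs[sample(nrow(recs)), ])
  cl2 <- group_clones(flag_rising(classify_status(perm)), af_tolerance = 0.05)
  expect_equal(cl[order(cl$keys), c("keys", "n_mutations", "fate")],
               cl2[order(cl2$keys), c("keys", "n_mutations", "fate")],
               ignore_attr = TRUE)
})

test_that("an eradicated diagnosis-only clone is labelled eradicated", {
  recs <- mutation_records(rbind(
    make_mut("PE", "diagnosis", pos = 1L, alt_reads = 300L, depth = 1000L),
    make_mut("PE", "relapse1", pos = 1L, alt_reads = 0L, depth = 1000L,
             called = FALSE),
    make_mut("PE", "diagnosis", pos = 2L, alt_reads = 450L, depth = 1000L),
    make_mut("PE", "relapse1", pos = 2L, alt_reads = 440L, depth = 1000L)))
  calls <- flag_rising(rescue_low_af(classify_status(recs)))
  cl <- group_clones(calls)
  expect_equal(cl$fate[grepl("chr1:1:", cl$keys)], "eradicated")
  expect_equal(cl$fate[grepl("chr1:2:", cl$keys)], "persisting")
})

test_that("relapse-gene criteria flag genes and honor the CR1 exclusion", {
  pats <- patient_meta(rbind(
    make_patient("PA", outcome = "relapse"),
    make_patient("PB", outcome = "relapse"),
    make_patient("PC", outcome = "relapse"),
    make_patient("PD", outcome = "CR1"),
    make_patient("PT", immunophenotype = "T", subtype = "T-ALL",
                 outcome = "CR1")))
  paired <- rbind(
    # GENE_A: two non-silent gains in PA -> criterion 1
    make_mut("PA", "diagnosis", pos = 1L, gene = "GENE_A", alt_reads = 0L,
             depth = 500L, called = FALSE),
    make_mut("PA", "relapse1", pos = 1L, gene = "GENE_A", alt_reads = 100L,
             depth = 500L),
    make_mut("PA", "diagnosis", pos = 2L, gene = "GENE_A", alt_reads = 0L,
             depth = 500L, called = FALSE),
    make_mut("PA", "relapse1", pos = 2L, gene = "GENE_A", alt_reads = 100L,
             depth = 500L),
    # GENE_B: one gain; diagnostic carrier PB relapsed -> criterion 2
    make_mut("PA", "diagnosis", pos = 11L, gene = "GENE_B", alt_reads = 0L,
             depth = 500L, called = FALSE),
    make_mut("PA", "relapse1", pos = 11L, gene = "GENE_B", alt_reads = 90L,
             depth = 500L),
    # GENE_C: one gain; diagnostic carriers include CR1 patient PD (same
    # immunophenotype) -> exclusion voids criterion 2
    make_mut("PA", "diagnosis", pos = 21L, gene = "GENE_C", alt_reads = 0L,
             depth = 500L, called = FALSE),
    make_mut("PA", "relapse1", pos = 21L, gene = "GENE_C", alt_reads = 80L,
             depth = 500L),
    # GENE_D: like GENE_C but the CR1 carrier is T-ALL (other phenotype)
    make_mut("PA", "diagnosis", pos = 31L, gene = "GENE_D", alt_reads = 0L,
             depth = 500L, called = FALSE),
    make_mut("PA", "relapse1", pos = 31L, gene = "GENE_D", alt_reads = 80L,
             depth = 500L))
  diag_cohort <- rbind(
    make_mut("PB", "diagnosis", pos = 12L, gene = "GENE_B"),
    make_mut("PC", "diagnosis", pos = 22L, gene = "GENE_C"),
    make_mut("PD", "diagnosis", pos = 23L, gene = "GENE_C"),
    make_mut("PC", "diagnosis", pos = 32L, gene = "GENE_D"),
    make_mut("PT", "diagnosis", pos = 33L, gene = "GENE_D"))
  calls <- classify_status(mutation_records(paired))
  rg <- relapse_associated_genes(calls, mutation_records(diag_cohort), pats)
  rg <- rg[order(rg$gene), ]
  expect_equal(rg$gene, c("GENE_A", "GENE_B", "GENE_C", "GENE_D"))
  expect_equal(rg$criterion1, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rg$criterion2, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(rg$flagged, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("driver gain/loss tallies count non-silent statuses per gene", {
  recs <- make_paired(statuses = c("diagnosis_only", "diagnosis_only",
                                   "shared"))
  calls <- classify_status(recs)
  gl <- driver_gain_loss_summary(calls, "GENE1")
  expect_equal(gl$lost, 2L)
  expect_equal(gl$gained, 0L)
  empty <- driver_gain_loss_summary(calls[0, ], c("KRAS", "NRAS"))
  expect_equal(empty$lost, c(0L, 0L))
  expect_equal(empty$gained, c(0L, 0L))
})

test_that("simulated relapse pairs reproduce their truth labels exactly without noise", {
  co <- cached_pairs_noisefree()
  mut <- co$mutations
  paired <- unique(mut$patient_id[mut$timepoint != "diagnosis"])
  calls <- classify_status(mut[mut$patient_id %in% paired, ])
  calls <- rescue_low_af(calls)
  calls <- flag_rising(calls)
  tr <- co$truth$pair_truth
  m <- merge(calls, tr, by = c("patient_id", "key"), suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$status, m$status.t)
  expect_equal(m$rescued, m$rescued.t)
  expect_equal(m$residual, m$residual.t)
  expect_equal(m$rising, m$rising.t)

  # clone partition matches the generator's clone assignment
  cl <- group_clones(calls)
  norm_part <- function(groups)
    sort(unname(vapply(groups, function(k) paste(sort(k), collapse = ","),
                       "")))
  part_alg <- lapply(split(cl, cl$patient_id),
                     function(d) norm_part(strsplit(d$keys, ",")))
  part_tr <- lapply(split(tr, tr$patient_id),
                    function(d) norm_part(split(d$key, d$clone)))
  ok <- mapply(identical, part_alg[names(part_tr)], part_tr)
  expect_true(all(ok))
})

test_that("planted Ras gain/loss counts are recovered from the pair analysis", {
  cfg <- sim_config(seed = 17, read_noise = FALSE,
                    plant_gain_loss = data.frame(
                      gene = c("KRAS", "NRAS"), lost = c(4L, 3L),
                      gained = c(3L, 3L)))
  co <- simulate_relapse_pairs(simulate_cohort(cfg), cfg)
  mut <- co$mutations
  paired <- unique(mut$patient_id[mut$timepoint != "diagnosis"])
  calls <- classify_status(mut[mut$patient_id %in% paired, ])
  gl <- driver_gain_loss_summary(calls, c("KRAS", "NRAS"))
  tr <- co$truth$pair_truth
  # truth oracle restricted to non-silent mutations (effects live on calls)
  eff <- stats::setNames(calls$effect, paste(calls$patient_id, calls$key))
  tr$non_silent <- classify_non_silent(eff[paste(tr$patient_id, tr$key)])
  for (g in c("KRAS", "NRAS")) {
    expect_equal(gl$lost[gl$gene == g],
                 sum(tr$gene == g & tr$non_silent &
                       tr$status == "diagnosis_only"))
    expect_equal(gl$gained[gl$gene == g],
                 sum(tr$gene == g & tr$non_silent &
                       tr$status == "relapse_gained"))
  }
  expect_gte(sum(gl$lost), 7L)
  expect_gte(sum(gl$gained), 6L)
})
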