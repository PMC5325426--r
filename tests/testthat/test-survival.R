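test_that("cumulative incidence matches hand computation with a competing event", {
  rec <- make_survival(1:4, c("DCR1", "relapse", "relapse", "censored"))
  cif <- cumulative_incidence(rec)
  # Aalen-Johansen by hand: S(1-)=1, DCR1 at t=1 -> S=3/4;
  # relapse at t=2: inc = 3/4 * 1/3 = 1/4; at t=3: inc = 1/2 * 1/2 = 1/4
  expect_equal(cif$cif[cif$time == 2], 0.25)
  expect_equal(cif$cif[cif$time == 3], 0.50)
  expect_equal(cif$n_risk, 4:1)
  expect_true(all(diff(cif$cif) >= 0))

  # four relapses at distinct times: plain product-limit complement
  all_rel <- cumulative_incidence(make_survival(1:4, rep("relapse", 4)))
  expect_equal(all_rel$cif, c(0.25, 0.5, 0.75, 1))
  # all censored
  none <- cumulative_incidence(make_survival(1:4, rep("censored", 4)))
  expect_true(all(none$cif == 0))
  expect_error(cumulative_incidence(make_survival(c(0, 1), rep("relapse", 2))),
               "non-positive")
})

test_that("with no competing events the CIF equals one minus product-limit survival", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    tm <- round(rexp(n, 0.3) + 0.01, 2)
    ev <- sample(c("relapse", "censored"), n, replace = TRUE)
    if (!any(ev == "relapse")) ev[1] <- "relapse"
    rec <- make_survival(tm, ev)
    cif <- cumulative_incidence(rec)
    km <- survival::survfit(
      survival::Surv(tm, ev == "relapse") ~ 1)
    km_at <- stats::approx(km$time, 1 - km$surv, xout = cif$time,
                           method = "constant", yleft = 0, rule = 2)$y
    expect_equal(cif$cif, km_at, tolerance = 1e-10)
  }
})

test_that("Gray's test is null on identical groups and label-permutation invariant", {
  set.seed(41)
  n <- 40
  rec <- make_survival(rexp(n, 0.2) + 0.01,
                       sample(c("relapse", "DCR1", "censored"), n, TRUE))
  dup <- rbind(rec, transform(rec, patient_id = paste0("X", patient_id)))
  same <- gray_test(dup, rep(c("A", "B"), each = n))
  expect_lt(same$statistic, 1e-8)
  expect_equal(same$p, 1, tolerance = 1e-6)

  g <- rep(c("A", "B"), each = n / 2)
  r1 <- gray_test(rec, g)
  r2 <- gray_test(rec, ifelse(g == "A", "B", "A"))   # swap labels
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$df, 1)
  expect_error(gray_test(rec, rep("A", n)), "two groups")
  expect_error(gray_test(make_survival(1:4, rep("DCR1", 4)),
                         c("A", "A", "B", "B")), "no events of interest")
})

test_that("asymptotic p agrees with the exhaustive permutation reference at n=8", {
  g <- rep(c("A", "B"), each = 4)
  toys <- list(
    make_survival(1:8, c("relapse", "relapse", "DCR1", "censored",
                         "relapse", "censored", "DCR1", "censored")),
    make_survival(c(2, 4, 6, 8, 1, 3, 5, 7),
                  c("relapse", "relapse", "relapse", "censored",
                    "DCR1", "censored", "relapse", "censored")))
  for (rec in toys) {
    asym <- gray_test(rec, g)
    perm <- gray_test(rec, g, mode = "permutation")   # enumerates C(8,4)=70
    expect_equal(perm$mode, "exact-permutation")
    expect_lte(abs(asym$p - perm$p), 0.1)
    expect_equal(asym$p < 0.05, perm$p < 0.05)
  }
})

test_that("pathway collapse flags patients once per pathway, non-silent only", {
  pmap <- data.frame(gene = c("CREBBP", "NOTCH1"),
                     pathway = "Notch signaling", stringsAsFactors = FALSE)
  muts <- make_muts(
    make_mut("P1", pos = 1L, gene = "CREBBP", effect = "nsSNV"),
    make_mut("P1", pos = 2L, gene = "NOTCH1", effect = "nsSNV"),
    make_mut("P2", pos = 3L, gene = "CREBBP", effect = "silent"),
    make_mut("P3", pos = 4L, gene = "UNMAPPED", effect = "nsSNV"))
  pc <- pathway_collapse(muts, pmap)
  expect_equal(nrow(pc), 1L)                       # two hits, one flag
  expect_equal(pc$patient_id, "P1")
  expect_equal(attr(pc, "n_unmapped"), 1L)
})

test_that("relapse screen applies the carrier, infant and Bonferroni rules", {
  set.seed(61)
  n <- 60
  pats <- do.call(rbind, lapply(1:n, function(i)
    make_patient(sprintf("P%02d", i),
                 age_years = if (i <= 2) 0.5 else 6,
                 outcome = sample(c("relapse", "CR1", "DCR1"), 1,
                                  prob = c(0.4, 0.5, 0.1)),
                 time_to_event_years = round(runif(1, 0.5, 10), 2))))
  pats <- patient_meta(pats)
  # GENE1 mutated in 10 non-infant patients; GENE2 in 4 (below threshold);
  # GENE3 only in the two infants plus three others (5 carriers, but the
  # infants are removed first, leaving 3 -> not tested)
  muts <- mutation_records(do.call(rbind, c(
    lapply(3:12, function(i) make_mut(sprintf("P%02d", i), pos = i * 7L,
                                      gene = "GENE1")),
    lapply(13:16, function(i) make_mut(sprintf("P%02d", i), pos = 900L + i,
                                       gene = "GENE2")),
    lapply(c(1, 2, 20, 21, 22), function(i)
      make_mut(sprintf("P%02d", i), pos = 1200L + i, gene = "GENE3")))))
  res <- relapse_screen(muts, pats, unit = "gene", min_mutated = 5)
  expect_equal(res$unit, "GENE1")
  expect_equal(res$m, 1L)
  expect_equal(res$bonferroni_p, res$p)            # m = 1
  expect_gte(res$bonferroni_p, res$p)
  expect_error(relapse_screen(muts, pats[pats$age_years < 1, ],
                              unit = "gene"),
               "empty subgroup")
})

test_that("pathway screen detects an elevated relapse hazard", {
  # direct outcome simulation: 300 patients, 60 pathway carriers at HR 3
  pmap <- data.frame(gene = "NOTCH1", pathway = "Notch signaling")
  hits <- 0
  n_rep <- 25
  for (r in 1:n_rep) {
    set.seed(700 + r)
    n <- 300
    carrier <- c(rep(TRUE, 60), rep(FALSE, 240))
    h_rel <- ifelse(carrier, 0.09, 0.03)
    t_rel <- rexp(n, h_rel); t_comp <- rexp(n, 0.015)
    tmin <- pmin(t_rel, t_comp, 10)
    ev <- ifelse(tmin == 10, "CR1", ifelse(t_rel < t_comp, "relapse", "DCR1"))
    pats <- patient_meta(do.call(rbind, lapply(1:n, function(i)
      make_patient(sprintf("P%03d", i), outcome = ev[i],
                   time_to_event_years = round(tmin[i], 4) + 1e-3))))
    muts <- mutation_records(do.call(rbind, lapply(which(carrier), function(i)
      make_mut(sprintf("P%03d", i), pos = 5L + i, gene = "NOTCH1"))))
    res <- relapse_screen(muts, pats, unit = "pathway", pathway_map = pmap,
                          min_mutated = 5)
    if (res$bonferroni_p[1] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})
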