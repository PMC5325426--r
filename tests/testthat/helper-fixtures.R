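# Shared fixture builders for the test suite. All fixtures are built in
# code; nothing is read from disk except package extdata.

make_mut <- function(patient_id = "P1", timepoint = "diagnosis",
                     chrom = "chr1", pos = 100L, ref = "C", alt = "T",
                     variant_class = "SNV", effect = "nsSNV", gene = "GENE1",
                     af = NA_real_, alt_reads = 30L, depth = 100L,
                     called = TRUE, sample_id = NULL) {
  data.frame(patient_id = patient_id,
             sample_id = if (is.null(sample_id))
               paste0(patient_id, ".", timepoint) else sample_id,
             timepoint = timepoint, chrom = chrom, pos = pos, ref = ref,
             alt = alt, variant_class = variant_class, effect = effect,
             gene = gene, af = af, alt_reads = alt_reads, depth = depth,
             called = called, stringsAsFactors = FALSE)
}

make_muts <- function(...) {
  mutation_records(do.call(rbind, list(...)))
}

make_patient <- function(patient_id = "P1", immunophenotype = "BCP",
                         subtype = "HeH", age_years = 5, sex = "F",
                         blast_fraction = 0.9, outcome = "CR1",
                         time_to_event_years = 8, cohort = "core") {
  data.frame(patient_id = patient_id, immunophenotype = immunophenotype,
             subtype = subtype, age_years = age_years, sex = sex,
             blast_fraction = blast_fraction, outcome = outcome,
             time_to_event_years = time_to_event_years, cohort = cohort,
             stringsAsFactors = FALSE)
}

make_survival <- function(times, events, ids = NULL) {
  data.frame(patient_id = if (is.null(ids))
    paste0("S", seq_along(times)) else ids,
    time = times, event = events, stringsAsFactors = FALSE)
}

# a two-timepoint paired patient: statuses controlled per mutation
make_paired <- function(patient_id = "PAIR1",
                        statuses = c("shared", "diagnosis_only",
                                     "relapse_gained"),
                        af_dia = 0.4, af_rel = 0.4) {
  rows <- list()
  for (i in seq_along(statuses)) {
    st <- statuses[i]
    pos <- 1000L + i
    dia_called <- st %in% c("shared", "diagnosis_only")
    rel_called <- st %in% c("shared", "relapse_gained")
    a_d <- if (dia_called) af_dia else 0
    a_r <- if (rel_called) af_rel else 0
    rows[[length(rows) + 1L]] <- make_mut(
      patient_id, "diagnosis", pos = pos, af = NA, alt_reads =
        as.integer(round(a_d * 1000)), depth = 1000L, called = dia_called)
    rows[[length(rows) + 1L]] <- make_mut(
      patient_id, "relapse1", pos = pos, af = NA, alt_reads =
        as.integer(round(a_r * 1000)), depth = 1000L, called = rel_called)
  }
  mutation_records(do.call(rbind, rows))
}

# small cached default cohort shared across test files
sim_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed = 5) {
  key <- paste0("cohort", seed)
  if (is.null(sim_cache[[key]]))
    sim_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  sim_cache[[key]]
}
cached_pairs_noisefree <- function(seed = 11) {
  key <- paste0("pairs", seed)
  if (is.null(sim_cache[[key]])) {
    cfg <- sim_config(seed = seed, read_noise = FALSE)
    sim_cache[[key]] <- simulate_relapse_pairs(simulate_cohort(cfg))
  }
  sim_cache[[key]]
}
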