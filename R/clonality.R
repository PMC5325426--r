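#' Estimate the boundary between the clonal and subclonal AF peaks
#'
#' Somatic allele fractions in a leukemic cohort are typically bimodal:
#' a clonal peak slightly below 0.5 (mutations in all leukemic cells of a
#' sample with blast fraction below one) and a subclonal peak at lower
#' AF. The boundary is located at the minimum of a Gaussian kernel
#' density (bandwidth by Silverman's rule) between the two largest modes
#' found on a fixed grid; the search is restricted to (0.05, 0.5), the
#' biologically meaningful range for diploid heterozygous mutations.
#'
#' @param afs numeric vector of allele fractions in (0, 1); hemizygous
#'   sites should be pre-scaled by their ploidy factor.
#' @param lower,upper search interval for modes and boundary.
#' @param n_grid density grid size.
#' @return object of class `af_boundary`: list with `boundary` (numeric,
#'   or `NA` when the density is unimodal), `modes` (AF of the two modes
#'   used, or all detected modes when unimodal), `method` and
#'   `diagnostics` (the grid density).
#' @export
estimate_af_boundary <- function(afs, lower = 0.05, upper = 0.5,
                                 n_grid = 512L) {
  afs <- afs[!is.na(afs)]
  if (length(afs) < 50)
    stop("need at least 50 AF values to estimate a boundary")
  if (any(afs <= 0 | afs >= 1)) stop("AF values must lie in (0, 1)")
  d <- stats::density(afs, bw = "nrd0", kernel = "gaussian", n = n_grid,
                      from = 0, to = 1)
  in_win <- d$x > lower & d$x < upper
  x <- d$x[in_win]; y <- d$y[in_win]
  is_mode <- which(diff(sign(diff(y))) == -2) + 1L
  # modes at window edges count too (peak truncated by the window)
  if (length(y) > 1 && y[1] > y[2]) is_mode <- c(1L, is_mode)
  if (length(y) > 1 && y[length(y)] > y[length(y) - 1L])
    is_mode <- c(is_mode, length(y))
  # discard numerical wiggles in near-empty density regions
  is_mode <- is_mode[y[is_mode] >= 0.01 * max(y)]
  res <- list(method = "gaussian-kde-valley",
              diagnostics = data.frame(af = x, density = y))
  if (length(is_mode) < 2) {
    res$boundary <- NA_real_
    res$modes <- x[is_mode]
    res$reason <- "unimodal"
    return(structure(res, class = "af_boundary"))
  }
  top2 <- sort(is_mode[order(y[is_mode], decreasing = TRUE)][1:2])
  valley <- seq(top2[1], top2[2])
  res$boundary <- x[valley[which.min(y[valley])]]
  res$modes <- x[top2]
  structure(res, class = "af_boundary")
}

#' @export
print.af_boundary <- function(x, ...) {
  if (is.na(x$boundary))
    cat("af_boundary: no boundary (", x$reason, ")\n", sep = "")
  else
    cat(sprintf("af_boundary: %.3f between modes at %.3f and %.3f\n",
                x$boundary, x$modes[1], x$modes[2]))
  invisible(x)
}

#' Ploidy factor for AF adjustment
#'
#' Heterozygous autosomal mutations in all leukemic cells sit near
#' blast/2, but chrX mutations in males and mitochondrial mutations are
#' effectively hemizygous and sit near the blast fraction itself; their
#' AF is divided by 2 before comparison with the boundary.
#'
#' @param chrom chromosome labels.
#' @param sex per-record sex (`"M"`/`"F"`).
#' @return numeric vector of 1s and 2s.
#' @export
ploidy_factor <- function(chrom, sex) {
  is_x <- chrom %in% c("chrX", "X")
  is_m <- chrom %in% c("chrM", "MT", "chrMT", "M")
  ifelse((is_x & sex == "M") | is_m, 2, 1)
}

#' Classify mutations as clonal or subclonal
#'
#' @param records mutation records with `af` populated.
#' @param boundary an [estimate_af_boundary()] result or a number.
#' @param sex_by_patient named character vector patient_id -> sex.
#' @param exclude_hemizygous drop chrX-male/chrM records instead of
#'   adjusting their AF.
#' @return data.frame: key, patient_id, af, ploidy_factor, adjusted_af,
#'   label (`clonal` iff adjusted AF >= boundary). Records with missing
#'   AF are skipped; their count is in attribute `n_skipped`.
#' @export
classify_clonality <- function(records, boundary, sex_by_patient,
                               exclude_hemizygous = FALSE) {
  if (inherits(boundary, "af_boundary")) boundary <- boundary$boundary
  if (is.na(boundary)) stop("no usable AF boundary")
  skipped <- sum(is.na(records$af))
  if (skipped) warning(skipped, " records without AF skipped")
  records <- records[!is.na(records$af), , drop = FALSE]
  pf <- ploidy_factor(records$chrom, sex_by_patient[records$patient_id])
  if (exclude_hemizygous) {
    records <- records[pf == 1, , drop = FALSE]
    pf <- pf[pf == 1]
  }
  adj <- records$af / pf
  out <- data.frame(key = variant_key(records),
                    patient_id = records$patient_id,
                    af = records$af, ploidy_factor = pf, adjusted_af = adj,
                    label = ifelse(adj >= boundary, "clonal", "subclonal"),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  attr(out, "boundary") <- boundary
  out
}

#' Compare per-patient mutation burdens between groups
#'
#' Two-sided Wilcoxon rank-sum test with mid-ranks for ties; exact when
#' both groups have at most 12 patients and no ties, normal approximation
#' with tie correction otherwise.
#'
#' @param groups named list of two numeric vectors of per-patient counts.
#' @return data.frame: group labels, n, means, statistic W, p.
#' @export
compare_burden <- function(groups) {
  if (length(groups) != 2) stop("compare_burden expects exactly two groups")
  if (any(lengths(groups) < 3)) stop("each group needs at least 3 patients")
  x <- groups[[1]]; y <- groups[[2]]
  exact <- length(x) <= 12 && length(y) <= 12 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
             n1 = length(x), n2 = length(y),
             mean1 = mean(x), mean2 = mean(y),
             statistic = unname(wt$statistic), p = wt$p.value,
             stringsAsFactors = FALSE)
}

#' Chi-square test on a clonal/subclonal by group 2x2 table
#'
#' @param counts 2x2 matrix (rows clonal/subclonal, columns groups).
#' @param correct apply continuity correction (default FALSE).
#' @return data.frame with statistic, df, p.
#' @export
clonal_fraction_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value)
}

#' Six-class substitution spectrum per group
#'
#' SNVs are collapsed to the pyrimidine-reference classes C>A, C>G, C>T,
#' T>A, T>C, T>G; fractions per group sum to one.
#'
#' @param snvs mutation records (SNVs only).
#' @param groups group label per record.
#' @return matrix groups x 6 of fractions.
#' @export
substitution_spectrum <- function(snvs, groups) {
  if (any(snvs$variant_class != "SNV"))
    stop("substitution_spectrum expects SNVs only")
  ref <- snvs$ref; alt <- snvs$alt
  pur <- ref %in% c("G", "A")
  ref[pur] <- chartr("GA", "CT", ref[pur])
  alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  tab <- table(factor(groups, levels = unique(groups)),
               factor(paste0(ref, ">", alt), levels = classes))
  sweep(unclass(tab), 1, rowSums(tab), `/`)
}

#' Spearman correlation between mutation burden and age
#'
#' @param counts,ages paired numeric vectors (n >= 5).
#' @return data.frame with rho and p (asymptotic approximation).
#' @export
burden_age_correlation <- function(counts, ages) {
  stopifnot(length(counts) == length(ages))
  if (length(counts) < 5) stop("need at least 5 paired observations")
  if (stats::sd(counts) == 0 || stats::sd(ages) == 0)
    stop("constant vector: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(counts, ages, method = "spearman", exact = FALSE))
  data.frame(rho = unname(ct$estimate), p = ct$p.value)
}
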