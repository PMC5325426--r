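#' Non-negative matrix factorization of a context matrix
#'
#' Decomposes a groups x 96 count (or corrected count) matrix `V` into
#' `k` mutational signatures: `V ~ E %*% S` with exposures `E`
#' (groups x k) and signatures `S` (k x 96), both non-negative.
#' Multiplicative Frobenius updates are run from `n_restarts` random
#' initializations and the factorization with the lowest reconstruction
#' error is kept; signature rows are normalized to sum to one with the
#' exposure columns rescaled to compensate. The whole procedure is
#' deterministic given `seed`.
#'
#' @param mat non-negative numeric matrix (groups x 96, or any
#'   groups x features).
#' @param k number of signatures (>= 1).
#' @param seed integer RNG seed.
#' @param n_restarts random restarts (default 50).
#' @param max_iter maximum multiplicative updates per restart.
#' @param tol stop when the relative decrease of the error drops below
#'   this.
#' @return object of class `signature_set`: list with `signatures`
#'   (k x features, rows sum to 1), `exposures` (groups x k), `error`
#'   (Frobenius reconstruction error) and `error_trace` of the winning
#'   run.
#' @export
nmf_decompose <- function(mat, k, seed = 1L, n_restarts = 50L,
                          max_iter = 10000L, tol = 1e-6) {
  V <- as.matrix(unclass(mat))
  if (k < 1) stop("k must be >= 1")
  if (any(V < 0)) stop("matrix must be non-negative")
  if (all(V == 0)) stop("all-zero matrix cannot be decomposed")
  m <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  scale0 <- sqrt(mean(V) / k)
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(m * k, 0.1, 1), m, k) * scale0
    H <- matrix(stats::runif(k * n, 0.1, 1), k, n) * scale0
    err_prev <- Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- sqrt(sum((V - W %*% H)^2))
      trace <- c(trace, err)
      if (is.finite(err_prev) &&
          (err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
    if (is.null(best) || err < best$error)
      best <- list(W = W, H = H, error = err, error_trace = trace)
  }
  rs <- rowSums(best$H)
  rs[rs == 0] <- 1
  S <- best$H / rs
  E <- sweep(best$W, 2, rs, `*`)
  rownames(S) <- paste0("S", seq_len(k))
  colnames(S) <- colnames(V)
  dimnames(E) <- list(rownames(V), rownames(S))
  structure(list(signatures = S, exposures = E, error = best$error,
                 error_trace = best$error_trace),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d signatures x %d contexts, %d groups, error %.4g\n",
              nrow(x$signatures), ncol(x$signatures), nrow(x$exposures),
              x$error))
  invisible(x)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match extracted signatures against a reference catalogue
#'
#' Primary output: for each extracted signature, the reference signature
#' with the highest cosine similarity (ties broken by catalogue order).
#' Secondary output: a complete-linkage hierarchical clustering of the
#' row-scaled stacked matrix (extracted plus reference signatures) on
#' Euclidean distance, for dendrogram-style inspection of which
#' extracted signature clusters with which catalogue entry.
#'
#' @param found a `signature_set` (or k x 96 matrix with context
#'   colnames).
#' @param reference catalogue matrix, 96 rows (rownames = contexts) x
#'   named signature columns, as returned by [read_signature_catalog()].
#' @return list with `matches` (data.frame: signature, match, cosine),
#'   `cosine` (full similarity matrix) and `hclust` (the clustering).
#' @export
match_signatures <- function(found, reference) {
  S <- if (inherits(found, "signature_set")) found$signatures else as.matrix(found)
  if (is.null(rownames(S))) rownames(S) <- paste0("S", seq_len(nrow(S)))
  if (!ncol(reference)) stop("reference catalogue is empty")
  if (!setequal(colnames(S), rownames(reference)) ||
      !identical(colnames(S), rownames(reference)))
    stop("context order mismatch between signatures and catalogue")
  cos <- matrix(NA_real_, nrow(S), ncol(reference),
                dimnames = list(rownames(S), colnames(reference)))
  for (i in seq_len(nrow(S)))
    for (j in seq_len(ncol(reference)))
      cos[i, j] <- cosine_sim(S[i, ], reference[, j])
  matches <- data.frame(
    signature = rownames(S),
    match = colnames(reference)[apply(cos, 1, which.max)],
    cosine = apply(cos, 1, max),
    stringsAsFactors = FALSE)
  stacked <- rbind(S, t(reference))
  scaled <- t(scale(t(stacked)))
  scaled[!is.finite(scaled)] <- 0
  hc <- stats::hclust(stats::dist(scaled), method = "complete")
  list(matches = matches, cosine = cos, hclust = hc)
}

#' Read a reference signature catalogue TSV
#'
#' The catalogue format is one `context` column (the 96 labels of
#' [contexts96()]) plus one numeric column per named signature, each
#' summing to one. The package ships a synthetic catalogue
#' (`signature_catalog_synthetic.tsv`) with an aging-like CpG C>T
#' process, an APOBEC-like C>G/C>T-at-TpC process and a flat background;
#' it stands in for externally published catalogues, which are not
#' redistributed here.
#'
#' @param path TSV path; default the shipped synthetic catalogue.
#' @return numeric matrix, 96 x signatures, rownames = contexts.
#' @export
read_signature_catalog <- function(path = system.file(
    "extdata", "signature_catalog_synthetic.tsv", package = "somaticALL")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), contexts96()))
    stop("catalogue context order is not canonical")
  m
}
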