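#' Inverse-correlation summary of a parameter ensemble
#'
#' Computes the sample Pearson correlation matrix `C` of an ensemble of
#' (log10-scale) parameter samples and its inverse `K = C^-1`, the
#' approximate Hessian of the cost surface near the sampled minimum. The
#' eigenstructure of `K` identifies stiff (large eigenvalue, well
#' constrained) and sloppy directions; its diagonal gives the multiple
#' correlation of each parameter with all others and its off-diagonal
#' elements the partial correlations.
#'
#' @param ensemble `n x p` matrix (or data.frame) of parameter samples,
#'   `n > p`, no constant columns.
#' @param max_condition Condition-number threshold beyond which the ensemble
#'   is reported as singular.
#' @return A `correlation_summary`: `C`, `K`, `eigenvalues` (descending),
#'   `eigenvectors` (columns, orthonormal, sign fixed so each vector's
#'   largest-magnitude component is positive), `R` (per-parameter multiple
#'   correlation), `P` (partial correlation matrix), and `n`.
#' @export
correlation_summary <- function(ensemble, max_condition = 1e12) {
  x <- as.matrix(ensemble)
  n <- nrow(x); p <- ncol(x)
  if (n <= p)
    stop("need more samples than parameters (n > p)", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("singular ensemble: constant column(s) ",
         paste(which(sds == 0), collapse = ", "),
         " (remove constant/duplicate parameters)", call. = FALSE)
  C <- stats::cor(x)
  ev_c <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_c) <= 0 || max(ev_c) / min(ev_c) > max_condition)
    stop("singular ensemble: correlation matrix condition number ",
         format(max(ev_c) / max(min(ev_c), .Machine$double.eps), digits = 3),
         " (remove constant/duplicate parameters)", call. = FALSE)
  K <- solve(C)
  K <- (K + t(K)) / 2
  ed <- eigen(K, symmetric = TRUE)
  ord <- order(ed$values, decreasing = TRUE)
  vals <- ed$values[ord]
  vecs <- ed$vectors[, ord, drop = FALSE]
  for (j in seq_len(p)) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  kd <- diag(K)
  if (any(kd < 1 - 1e-8))
    stop("numerical error: diagonal of the inverse correlation matrix ",
         "must be >= 1", call. = FALSE)
  R <- sqrt(1 - 1 / pmax(kd, 1))
  P <- -K / sqrt(outer(kd, kd))
  diag(P) <- 1
  dimnames(P) <- dimnames(K) <- dimnames(C)
  nm <- colnames(x)
  structure(list(C = C, K = K, eigenvalues = vals, eigenvectors = vecs,
                 R = if (is.null(nm)) R else stats::setNames(R, nm),
                 P = P, n = n),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  p <- length(x$R)
  cat("<correlation_summary>", p, "parameters,", x$n, "samples\n")
  cat("  stiffest eigenvalues:",
      paste(sprintf("%.3g", utils::head(x$eigenvalues, 3)), collapse = ", "),
      "\n")
  cat("  multiple R range    : [",
      sprintf("%.3f", min(x$R)), ",", sprintf("%.3f", max(x$R)), "]\n")
  invisible(x)
}

#' Stiffness spectrum (PCA of the approximate Hessian)
#'
#' Eigendecomposition of the inverse correlation matrix: eigenvalues in
#' descending order (stiffest first), orthonormal eigenvectors as columns.
#'
#' @param summary A [correlation_summary()].
#' @return List with `values` and `vectors`.
#' @export
stiffness_spectrum <- function(summary) {
  stopifnot(inherits(summary, "correlation_summary"))
  list(values = summary$eigenvalues, vectors = summary$eigenvectors)
}

#' Multiple correlation coefficients
#'
#' `R_i = sqrt(1 - 1 / K_ii)`: the correlation between parameter `i` and the
#' best linear combination of all other parameters.
#'
#' @param summary A [correlation_summary()].
#' @return Vector of `R_i` in `[0, 1)`.
#' @export
multiple_correlation <- function(summary) {
  stopifnot(inherits(summary, "correlation_summary"))
  summary$R
}

#' Partial correlation matrix
#'
#' `P_ij = -K_ij / sqrt(K_ii K_jj)` for `i != j` (unit diagonal): the
#' correlation between two parameters after adjusting for all others.
#'
#' @param summary A [correlation_summary()].
#' @return Symmetric matrix with unit diagonal.
#' @export
partial_correlation <- function(summary) {
  stopifnot(inherits(summary, "correlation_summary"))
  summary$P
}

#' Classify significant pairwise partial-correlation changes
#'
#' Contrasts the partial correlations of two ensembles pair by pair with a
#' two-sample Fisher z test (controlling for the `p - 2` remaining
#' parameters), Benjamini-Hochberg corrected across all pairs, combined with
#' an absolute-difference filter. Significant pairs are categorized as
#' `lose` (weaker partial correlation in B), `gain` (stronger in B) or
#' `flip` (significant sign reversal, both magnitudes individually
#' significant).
#'
#' @param A,B [correlation_summary()] objects with identical parameter
#'   indexing (A is the reference ensemble, e.g. survivors).
#' @param n_A,n_B Sample sizes used in the tests; pass autocorrelation-
#'   adjusted effective sizes for MCMC ensembles (see
#'   [effective_sample_size()]). Defaults: the ensemble row counts.
#' @param alpha Significance level after correction (default 0.05).
#' @param min_delta Minimal absolute difference of partial correlations
#'   (default 0.1).
#' @return Data.frame of significant pairs: `p1`, `p2` (indices), `name1`,
#'   `name2`, `r_A`, `r_B`, `difference` (`r_A - r_B`), `p_adj`, `class`;
#'   empty if no pair qualifies.
#' @export
classify_pair_changes <- function(A, B, n_A = A$n, n_B = B$n, alpha = 0.05,
                                  min_delta = 0.1) {
  stopifnot(inherits(A, "correlation_summary"),
            inherits(B, "correlation_summary"))
  p <- length(A$R)
  if (length(B$R) != p)
    stop("ensembles have different parameter dimensions", call. = FALSE)
  # Fisher z standard error for a partial correlation controlling p-2
  # variables: 1 / sqrt(n - (p - 2) - 3)
  df_A <- n_A - (p - 2) - 3
  df_B <- n_B - (p - 2) - 3
  if (df_A <= 0 || df_B <= 0)
    stop("effective sample size too small for the Fisher z test",
         call. = FALSE)
  idx <- which(upper.tri(A$P), arr.ind = TRUE)
  rA <- A$P[idx]; rB <- B$P[idx]
  rA <- pmin(pmax(rA, -0.999999), 0.999999)
  rB <- pmin(pmax(rB, -0.999999), 0.999999)
  zA <- atanh(rA); zB <- atanh(rB)
  se <- sqrt(1 / df_A + 1 / df_B)
  z <- (zA - zB) / se
  pval <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(pval, method = "BH")
  keep <- padj <= alpha & abs(rA - rB) >= min_delta
  if (!any(keep)) {
    return(data.frame(p1 = integer(0), p2 = integer(0),
                      name1 = character(0), name2 = character(0),
                      r_A = numeric(0), r_B = numeric(0),
                      difference = numeric(0), p_adj = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  crit <- stats::qnorm(1 - alpha / 2)
  sigA <- abs(zA) * sqrt(df_A) > crit
  sigB <- abs(zB) * sqrt(df_B) > crit
  cls <- ifelse(sign(rA) != sign(rB) & sigA & sigB, "flip",
                ifelse(abs(rB) < abs(rA), "lose", "gain"))
  nm <- names(A$R)
  if (is.null(nm)) nm <- paste0("p", seq_len(p))
  out <- data.frame(p1 = idx[keep, 1], p2 = idx[keep, 2],
                    name1 = nm[idx[keep, 1]], name2 = nm[idx[keep, 2]],
                    r_A = rA[keep], r_B = rB[keep],
                    difference = rA[keep] - rB[keep], p_adj = padj[keep],
                    class = cls[keep], stringsAsFactors = FALSE)
  out[order(-abs(out$difference)), ]
}

#' Subsample a pooled ensemble
#'
#' Random subsample of rows (without replacement when possible), as used to
#' draw analysis ensembles of ten thousand parameter sets from the pooled
#' chains.
#'
#' @param ensemble Sample matrix.
#' @param n Target number of rows.
#' @param seed Integer seed.
#' @return Matrix with `min(n, nrow)` rows (sampled with replacement only if
#'   the ensemble is smaller than `n`).
#' @export
subsample_ensemble <- function(ensemble, n = 10000, seed = 1) {
  x <- as.matrix(ensemble)
  set.seed(seed)
  idx <- sample.int(nrow(x), n, replace = n > nrow(x))
  x[idx, , drop = FALSE]
}

#' Write analysis artifacts as CSV
#'
#' Emits the eigen-spectrum, multiple-correlation vector and partial
#' correlation matrix of a summary, and optionally the pair-change table
#' (columns mirroring `(P1, P2, r_A, r_B, difference, class)`).
#'
#' @param summary A [correlation_summary()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param pair_changes Optional [classify_pair_changes()] result.
#' @return Invisibly, the written paths.
#' @export
write_analysis_artifacts <- function(summary, dir, prefix = "ensemble",
                                     pair_changes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_spectrum.csv"))
  utils::write.csv(data.frame(component = seq_along(summary$eigenvalues),
                              eigenvalue = summary$eigenvalues),
                   p1, row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_multiple_r.csv"))
  utils::write.csv(data.frame(parameter = names(summary$R),
                              multiple_r = unname(summary$R)),
                   p2, row.names = FALSE)
  p3 <- file.path(dir, paste0(prefix, "_partial_corr.csv"))
  utils::write.csv(as.data.frame(summary$P), p3, row.names = TRUE)
  paths <- c(p1, p2, p3)
  if (!is.null(pair_changes)) {
    p4 <- file.path(dir, paste0(prefix, "_pair_changes.csv"))
    utils::write.csv(pair_changes, p4, row.names = FALSE)
    paths <- c(paths, p4)
  }
  invisible(paths)
}
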