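# Covariance model of an aligned Calpha trajectory and its ranked
# orthonormal collective modes (essential dynamics).

#' Calpha covariance model of an aligned trajectory
#'
#' Population covariance (1/N normalisation) of the 3M flattened coordinates
#' about their mean. Coordinates are flattened atom-major:
#' (x1, y1, z1, x2, ...). The trajectory must already be free of rigid-body
#' motion (see [align_trajectory()]); otherwise overall tumbling dominates
#' the spectrum.
#'
#' @param traj An aligned `gm_trajectory` with at least 2 frames.
#' @return A `gm_covariance`: list with `mean` (M x 3), `matrix` (3M x 3M,
#'   Angstrom^2), `selection`, `n_frames`.
#' @export
covariance_model <- function(traj) {
  n <- n_frames(traj)
  if (n < 2L) stopf("covariance needs at least 2 frames")
  M <- traj$selection$M
  flat <- matrix(aperm(traj$coords, c(3, 2, 1)), nrow = 3L * M, ncol = n)
  if (!all(is.finite(flat))) {
    bad <- which(!apply(is.finite(flat), 2, all))[1]
    stopf("non-finite coordinates in frame %d", bad)
  }
  mu <- rowMeans(flat)
  dev <- flat - mu
  cmat <- tcrossprod(dev) / n
  cmat <- (cmat + t(cmat)) / 2         # enforce exact symmetry
  structure(list(mean = unflatten_coords(mu), matrix = cmat,
                 selection = traj$selection, n_frames = n),
            class = "gm_covariance")
}

#' @export
print.gm_covariance <- function(x, ...) {
  cat(sprintf("<gm_covariance> 3M = %d, %d frames, trace %.4g A^2\n",
              nrow(x$matrix), x$n_frames, sum(diag(x$matrix))))
  invisible(x)
}

#' Top collective modes of a covariance model
#'
#' Eigendecomposition of the covariance matrix; the `k_max` eigenvectors with
#' the largest eigenvalues are returned, in descending eigenvalue order.
#' Small negative eigenvalues (numerical) are clipped at zero with a message.
#' Eigenvector signs are arbitrary; all downstream statistics are
#' sign-invariant.
#'
#' @param cov A `gm_covariance`.
#' @param k_max Number of modes to keep (default 20). If the matrix rank is
#'   smaller, fewer modes are returned with a warning.
#' @param provenance Optional segment id string carried along for reporting.
#' @return A `gm_modes`: list with `values` (eigenvalues, Angstrom^2),
#'   `vectors` (3M x k, orthonormal columns), `k_max`, `all_values` (full
#'   spectrum, for variance fractions), `provenance`.
#' @export
eigenmodes <- function(cov, k_max = 20L, provenance = NULL) {
  if (!is_number(k_max) || k_max < 1) stopf("k_max must be a positive integer")
  k_max <- as.integer(k_max)
  e <- eigen(cov$matrix, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-8 * max(sum(vals), 1)))
    warnf("covariance has substantially negative eigenvalues; clipping")
  tol <- max(vals) * 1e-12
  rank <- sum(vals > tol)
  k <- k_max
  if (rank < k_max) {
    warnf("covariance rank %d < k_max %d; returning %d modes", rank, k_max, rank)
    k <- max(rank, 1L)
  }
  structure(list(values = pmax(vals[seq_len(k)], 0),
                 vectors = e$vectors[, seq_len(k), drop = FALSE],
                 k_max = k, all_values = pmax(vals, 0),
                 provenance = provenance),
            class = "gm_modes")
}

#' @export
print.gm_modes <- function(x, ...) {
  cat(sprintf("<gm_modes> %d modes, lambda_1 = %.4g A^2%s\n", x$k_max,
              x$values[1],
              if (is.null(x$provenance)) "" else paste0(" [", x$provenance, "]")))
  invisible(x)
}

#' Fraction of total motion captured by the top k modes
#'
#' `sum(lambda_1..k) / trace(C)`.
#'
#' @param modes A `gm_modes`.
#' @param cov The `gm_covariance` the modes came from.
#' @param k Number of leading modes (k <= k_max).
#' @return Fraction in `[0, 1]`.
#' @export
variance_fraction <- function(modes, cov, k) {
  if (!is_number(k) || k < 1 || k > modes$k_max)
    stopf("k must be in 1..k_max (= %d)", modes$k_max)
  tr <- sum(diag(cov$matrix))
  if (tr <= 0) stopf("zero-trace covariance: degenerate trajectory")
  min(sum(modes$values[seq_len(k)]) / tr, 1)
}

#' Smallest k whose leading modes reach a target variance fraction
#'
#' Mirrors the practice of analysing the top modes that account for the bulk
#' (e.g. >= 75%) of the observed motion.
#'
#' @param modes A `gm_modes`.
#' @param cov The matching `gm_covariance`.
#' @param target Variance fraction to reach (default 0.75).
#' @return Integer k (capped at `k_max` with a warning if the target is not
#'   reachable within the kept modes).
#' @export
n_modes_for_variance <- function(modes, cov, target = 0.75) {
  tr <- sum(diag(cov$matrix))
  if (tr <= 0) stopf("zero-trace covariance: degenerate trajectory")
  cum <- cumsum(modes$values) / tr
  k <- which(cum >= target)[1]
  if (is.na(k)) {
    warnf("top %d modes reach only %.1f%% of variance (target %.0f%%)",
          modes$k_max, 100 * max(cum), 100 * target)
    k <- modes$k_max
  }
  as.integer(k)
}

#' Subspace overlap between two orthonormal mode sets
#'
#' Mean squared singular value of `t(U) %*% V`: 1 for identical subspaces,
#' ~k/3M for random ones. Used to compare recovered with planted modes
#' without relying on individual eigenvector identifiability.
#'
#' @param u,v Matrices with orthonormal columns (same row dimension).
#' @export
subspace_overlap <- function(u, v) {
  s <- svd(crossprod(as.matrix(u), as.matrix(v)))$d
  mean(s^2)
}
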