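# Segmenting trajectories into (subunit x time-block) units and comparing
# per-segment opening counts between conditions with an exact
# Wilcoxon-Mann-Whitney test that handles ties.

#' Plan the division of a trajectory into analysis segments
#'
#' The first `discard_ns` of the trajectory is discarded (equilibration),
#' the remaining frames are split into `n_blocks` contiguous blocks as equal
#' as possible (remainder frames go to the final blocks), and each block is
#' crossed with each subunit.
#'
#' @param traj A `gm_trajectory`.
#' @param discard_ns Initial interval to drop, in ns (default 50).
#' @param n_blocks Number of time blocks (default 3).
#' @return A `gm_segment_plan`: list with `blocks` (list of frame-index
#'   vectors), `subunits` (labels), `discard_ns`, `n_blocks`.
#' @export
segment_plan <- function(traj, discard_ns = 50, n_blocks = 3L) {
  if (n_blocks < 1L) stopf("n_blocks must be >= 1")
  keep <- which(traj$times >= discard_ns)
  if (length(keep) == 0L)
    stopf("discard interval (%g ns) covers the whole trajectory", discard_ns)
  if (length(keep) < n_blocks)
    stopf("only %d post-discard frames for %d blocks", length(keep), n_blocks)
  n <- length(keep)
  base <- n %/% n_blocks
  rem <- n %% n_blocks
  sizes <- rep(base, n_blocks)
  if (rem > 0)   # remainder assigned to the final blocks
    sizes[seq.int(n_blocks - rem + 1L, n_blocks)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- lapply(seq_len(n_blocks), function(b) keep[starts[b]:ends[b]])
  structure(list(blocks = blocks, subunits = unique(traj$subunits),
                 discard_ns = discard_ns, n_blocks = n_blocks),
            class = "gm_segment_plan")
}

#' Split a trajectory into per-(subunit, block) segment trajectories
#'
#' @param traj A `gm_trajectory`.
#' @param plan A `gm_segment_plan` (default: built with the standard
#'   parameters).
#' @return Named list of `gm_trajectory` segments, names `"<subunit>.<block>"`,
#'   ordered subunit-major.
#' @export
split_segments <- function(traj, plan = segment_plan(traj)) {
  out <- list()
  for (su in plan$subunits) {
    atom_idx <- which(traj$subunits == su)
    for (b in seq_along(plan$blocks)) {
      out[[paste0(su, ".", b)]] <-
        subset_trajectory(traj, frames = plan$blocks[[b]], atoms = atom_idx)
    }
  }
  out
}

#' Exact Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact p-values are computed from the permutation distribution of the
#' rank sum over all `choose(n+m, n)` group assignments of the pooled
#' mid-ranks, conditional on the observed tie pattern (evaluated by the
#' exact convolution algorithm, which enumerates that distribution without
#' materialising every assignment). For `n + m > 30` a normal approximation
#' with mid-ranks and tie-corrected variance is used and flagged.
#'
#' The two-sided p-value is twice the smaller one-sided tail, capped at 1.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger),
#'   or `"less"`.
#' @return A `gm_wmw`: list with `u` (Mann-Whitney U for sample `a`), `p`
#'   (for the requested alternative), `p_less`, `p_greater`, `p_two_sided`,
#'   `n`, `m`, `ties` (logical), `exact` (logical), `alternative`.
#' @export
wmw_exact <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stopf("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stopf("samples must not contain NA")
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)                    # mid-ranks under ties
  w_obs <- sum(r[seq_len(n)])          # rank sum of sample a
  u <- w_obs - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (n + m <= 30L) {
    dist <- ranksum_distribution(r, n)  # exact, conditional on tie pattern
    eps <- 1e-9
    p_greater <- sum(dist$prob[dist$sum >= w_obs - eps])
    p_less <- sum(dist$prob[dist$sum <= w_obs + eps])
    exact <- TRUE
  } else {
    mu <- n * (n + m + 1) / 2
    tie_tab <- table(pooled)
    nn <- n + m
    sig2 <- n * m / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sig2 <= 0) {
      p_greater <- p_less <- 1
    } else {
      z <- (w_obs - mu) / sqrt(sig2)
      p_greater <- stats::pnorm(z, lower.tail = FALSE)
      p_less <- stats::pnorm(z)
    }
    exact <- FALSE
  }
  p_two <- min(1, 2 * min(p_less, p_greater))
  p <- switch(alternative, two.sided = p_two, greater = p_greater,
              less = p_less)
  structure(list(u = u, p = p, p_less = p_less, p_greater = p_greater,
                 p_two_sided = p_two, n = n, m = m, ties = ties,
                 exact = exact, alternative = alternative),
            class = "gm_wmw")
}

#' @export
print.gm_wmw <- function(x, ...) {
  cat(sprintf("<gm_wmw> U = %g (n=%d, m=%d), p[%s] = %.4g%s%s\n",
              x$u, x$n, x$m, x$alternative, x$p,
              if (x$ties) ", ties" else "",
              if (x$exact) ", exact" else ", normal approx"))
  invisible(x)
}

# Exact permutation distribution of the rank sum of a size-n subset of the
# mid-ranks r. Doubled mid-ranks are integers, so the distribution is built
# by integer convolution: f[k, s] = number of k-subsets with doubled sum s.
ranksum_distribution <- function(r, n) {
  d <- as.integer(round(2 * r))
  total <- sum(d)
  f <- matrix(0, nrow = n + 1L, ncol = total + 1L)  # col s+1 <-> sum s
  f[1L, 1L] <- 1
  for (val in d) {
    kmax <- n
    for (k in seq.int(kmax, 1L)) {
      src <- f[k, ]
      if (val > 0) {
        shifted <- c(rep(0, val), src[seq_len(length(src) - val)])
      } else shifted <- src
      f[k + 1L, ] <- f[k + 1L, ] + shifted
    }
  }
  counts <- f[n + 1L, ]
  nz <- which(counts > 0)
  data.frame(sum = (nz - 1L) / 2, prob = counts[nz] / sum(counts[nz]))
}

#' Compare per-segment opening counts between two conditions
#'
#' Runs [wmw_exact()] per gate pair on the two count vectors and reports a
#' five-number summary (minimum, lower hinge, median, upper hinge, maximum)
#' per condition, mirroring a box-and-whisker display.
#'
#' @param counts_a,counts_b Segments x pairs integer matrices (as from
#'   [segment_count_table()]) with identical column names and >= 2 rows each.
#' @param alternative Passed to [wmw_exact()].
#' @return A `gm_comparison`: list with `table` (data frame: pair, U, p_less,
#'   p_greater, p_two_sided, n, m) and `summary` (data frame of five-number
#'   summaries per condition per pair).
#' @export
compare_conditions <- function(counts_a, counts_b,
                               alternative = "two.sided") {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (!identical(colnames(counts_a), colnames(counts_b)))
    stopf("conditions disagree on gate pairs")
  if (nrow(counts_a) < 2L || nrow(counts_b) < 2L)
    stopf("need >= 2 segments per condition")
  pairs <- colnames(counts_a)
  rows <- lapply(pairs, function(p) {
    t <- wmw_exact(counts_a[, p], counts_b[, p], alternative = alternative)
    data.frame(pair = p, u = t$u, p_less = t$p_less, p_greater = t$p_greater,
               p_two_sided = t$p_two_sided, n = t$n, m = t$m,
               exact = t$exact, stringsAsFactors = FALSE)
  })
  fv <- lapply(pairs, function(p) {
    fa <- stats::fivenum(counts_a[, p]); fb <- stats::fivenum(counts_b[, p])
    data.frame(pair = p, condition = c("A", "B"),
               min = c(fa[1], fb[1]), q25 = c(fa[2], fb[2]),
               median = c(fa[3], fb[3]), q75 = c(fa[4], fb[4]),
               max = c(fa[5], fb[5]), stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), summary = do.call(rbind, fv)),
            class = "gm_comparison")
}

#' @export
print.gm_comparison <- function(x, ...) {
  cat("<gm_comparison>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
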