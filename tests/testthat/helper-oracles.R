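# Independent oracles and small in-code fixtures shared across tests.

# Complete-enumeration Wilcoxon-Mann-Whitney oracle: walks every
# choose(n+m, n) assignment of the pooled mid-ranks. Definitionally exact;
# only usable for small n + m.
oracle_wmw_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  eps <- 1e-9
  p_greater <- mean(sums >= w_obs - eps)
  p_less <- mean(sums <= w_obs + eps)
  list(p_less = p_less, p_greater = p_greater,
       p_two_sided = min(1, 2 * min(p_less, p_greater)))
}

# Brute-force minimum RMSD over rotations: coarse grid over Euler angles
# followed by Nelder-Mead on the angles. Centres both sets first (the
# optimal translation aligns centroids). Independent of the Kabsch path.
oracle_min_rmsd <- function(x, y, coarse = 10) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(ang) sqrt(mean(rowSums((xc %*% rot_euler(ang) - yc)^2)))
  g <- seq(0, 2 * pi, length.out = coarse + 1L)[-1]
  g2 <- seq(-pi / 2, pi / 2, length.out = coarse)
  best <- c(0, 0, 0); best_v <- f(best)
  for (a1 in g) for (a2 in g2) for (a3 in g) {
    v <- f(c(a1, a2, a3))
    if (v < best_v) { best <- c(a1, a2, a3); best_v <- v }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}

# Analytic covariance of a planted model: sum_k s_k^2 B_k B_k' + sigma^2 I
planted_covariance <- function(model, atom_idx = NULL) {
  B <- model$modes
  s <- model$amplitudes
  if (!is.null(atom_idx)) {
    rows <- as.vector(vapply(atom_idx, function(i) 3L * (i - 1L) + 1:3,
                             integer(3)))
    B <- B[rows, , drop = FALSE]
  }
  B %*% (t(B) * s^2) + diag(model$sigma^2, nrow(B))
}

# tiny PDB fixture: two CA atoms 8.8 A apart along z
toy_pdb_two_atoms <- function() {
  paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       0.000   0.000   8.800  1.00  0.00           C",
    sep = "\n")
}

# n-residue single-chain CA trace along z
toy_chain <- function(n, chain = "A") {
  structure_from_coords(cbind(0, 0, 3.8 * seq_len(n)), chain = chain)
}

# random unit 3M vector
random_unit_mode <- function(M) {
  v <- stats::rnorm(3 * M)
  v / sqrt(sum(v^2))
}

# hollow cylinder of atoms: rings of `per_ring` atoms at in-plane radius R,
# stacked along z
cylinder_structure <- function(R = 5, vdw = 1.7, per_ring = 24L,
                               z = seq(-10, 10, by = 0.5)) {
  th <- seq(0, 2 * pi, length.out = per_ring + 1L)[-1]
  xyz <- do.call(rbind, lapply(z, function(zz)
    cbind(R * cos(th), R * sin(th), zz)))
  s <- structure_from_coords(xyz, chain = "A")
  s$atoms$radius <- vdw
  s
}

# standard small study configuration used by pipeline-level tests
study_config <- function(model, ...) {
  analysis_config(pairs = list(model$gate_pairs$target,
                               model$gate_pairs$control),
                  mode_select = "variance", ...)
}
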