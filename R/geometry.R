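# Rigid-body superposition (Kabsch), RMSD, labeled distances, and trajectory
# alignment. Proper rotations only: chirality is never inverted.

#' Least-squares rigid superposition of two coordinate sets
#'
#' Kabsch algorithm via SVD of the cross-covariance; a reflection, if it is
#' the unconstrained optimum, is corrected to the best proper rotation by
#' flipping the sign of the smallest singular direction.
#'
#' @param mobile,reference M x 3 coordinate matrices with matched rows
#'   (M >= 3, finite).
#' @return A `gm_superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom, over all supplied atoms after
#'   the transform), and `n_atoms`. The fit of `x` is `x %*% rotation +`
#'   `translation` (rows are atoms); see [apply_superposition()].
#' @export
superpose <- function(mobile, reference) {
  x <- as.matrix(mobile); y <- as.matrix(reference)
  if (nrow(x) != nrow(y) || ncol(x) != 3L || ncol(y) != 3L)
    stopf("superpose needs two M x 3 matrices with equal M")
  if (nrow(x) < 3L) stopf("superpose needs at least 3 atoms")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("superpose: non-finite coordinates")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  h <- crossprod(xc, yc)                 # 3x3 cross-covariance
  sv <- svd(h)
  # collinear/degenerate sets leave the in-plane rotation unidentifiable
  if (sv$d[2] <= max(sv$d) * 1e-10)
    stopf("superpose: ill-conditioned (collinear or degenerate) coordinates")
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- as.numeric(cy - cx %*% rot)
  fit <- x %*% rot + matrix(trans, nrow(x), 3, byrow = TRUE)
  structure(list(rotation = rot, translation = trans,
                 rmsd = rmsd_coords(fit, y), n_atoms = nrow(x)),
            class = "gm_superposition")
}

#' @export
print.gm_superposition <- function(x, ...) {
  cat(sprintf("<gm_superposition> %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a fitted superposition to coordinates
#' @param sp A `gm_superposition`.
#' @param x M x 3 matrix.
#' @export
apply_superposition <- function(sp, x) {
  as.matrix(x) %*% sp$rotation + matrix(sp$translation, nrow(x), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two matched coordinate sets (no fitting)
#' @param x,y M x 3 matrices.
#' @export
rmsd_coords <- function(x, y) {
  d <- as.matrix(x) - as.matrix(y)
  sqrt(mean(rowSums(d^2)))
}

#' Pair the common atoms of two structures by (chain, residue, atom name)
#'
#' Used for same-sequence or near-identical structure comparisons; no sequence
#' alignment is attempted.
#'
#' @param s1,s2 `gm_structure` objects.
#' @param atoms Atom names to pair (default `"CA"`).
#' @return List with selections `sel1`, `sel2` (equal `M`) and `n` pairs.
#' @export
paired_selection <- function(s1, s2, atoms = "CA") {
  a1 <- select_atoms(s1, atoms = atoms)
  a2 <- select_atoms(s2, atoms = atoms)
  k1 <- paste(a1$chain, a1$resno, a1$insert, a1$atom)
  k2 <- paste(a2$chain, a2$resno, a2$insert, a2$atom)
  common <- intersect(k1, k2)
  if (length(common) < 3L) stopf("fewer than 3 shared atoms to pair")
  take <- function(sel, keep) {
    structure(list(index = sel$index[keep], chain = sel$chain[keep],
                   resno = sel$resno[keep], insert = sel$insert[keep],
                   atom = sel$atom[keep], resid = sel$resid[keep],
                   M = sum(keep)), class = "gm_selection")
  }
  list(sel1 = take(a1, k1 %in% common), sel2 = take(a2, k2 %in% common),
       n = length(common))
}

#' Distance between two named atoms of a structure
#'
#' @param structure A `gm_structure`.
#' @param a,b Atom site specs: `list(chain=, resno=, atom=)` (atom defaults to
#'   `"CA"`), or a character `"A:419:CA"`.
#' @return Euclidean distance in Angstrom.
#' @export
pair_distance <- function(structure, a, b) {
  pa <- locate_site(structure, a)
  pb <- locate_site(structure, b)
  sqrt(sum((pa - pb)^2))
}

parse_site <- function(s) {
  if (is.character(s)) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    s <- list(chain = parts[1], resno = as.integer(parts[2]),
              atom = if (length(parts) >= 3) parts[3] else "CA")
  }
  if (is.null(s$atom)) s$atom <- "CA"
  s
}

locate_site <- function(structure, site) {
  site <- parse_site(site)
  a <- structure$atoms
  hit <- which(a$chain == site$chain & a$resno == site$resno &
                 a$name == site$atom)
  if (length(hit) != 1L)
    stopf("atom %s:%s:%s %s in structure", site$chain, site$resno, site$atom,
          if (length(hit) == 0L) "not found" else "is ambiguous")
  as.numeric(a[hit, c("x", "y", "z")])
}

#' Remove rigid-body motion from a trajectory
#'
#' Every frame is replaced by its least-squares superposed image. With
#' `reference = "mean"` the reference is iterated: frames are aligned to the
#' running mean until the mean moves by less than `tol` (RMSD) or `max_iter`
#' passes, which makes the result independent of which frame happens to come
#' first.
#'
#' @param traj A `gm_trajectory`.
#' @param reference `"mean"` (default) or an M x 3 coordinate matrix.
#' @param tol Convergence tolerance on the mean shift (Angstrom).
#' @param max_iter Maximum mean-refinement passes.
#' @return The aligned `gm_trajectory`.
#' @export
align_trajectory <- function(traj, reference = "mean", tol = 1e-6,
                             max_iter = 20L) {
  co <- traj$coords
  n <- dim(co)[1]
  if (identical(reference, "mean")) {
    ref <- co[1, , , drop = TRUE]
    for (it in seq_len(max_iter)) {
      co <- align_frames(co, ref)
      new_ref <- apply(co, c(2, 3), mean)
      shift <- rmsd_coords(new_ref, ref)
      ref <- new_ref
      if (shift < tol) break
    }
  } else {
    ref <- as.matrix(reference)
    if (nrow(ref) != dim(co)[2]) stopf("reference has wrong atom count")
    co <- align_frames(co, ref)
  }
  trajectory_from_coords(co, traj$selection, times = traj$times,
                         subunits = traj$subunits)
}

# lean per-frame Kabsch used in the alignment hot loop (no object building)
align_frames <- function(co, ref) {
  cy <- colMeans(ref)
  yc <- ref - matrix(cy, nrow(ref), 3, byrow = TRUE)
  M <- dim(co)[2]
  ones <- rep(1, M)
  for (i in seq_len(dim(co)[1])) {
    x <- co[i, , ]
    cx <- colMeans(x)
    xc <- x - tcrossprod(ones, cx)
    sv <- svd(crossprod(xc, yc))
    d <- sign(det(tcrossprod(sv$u, sv$v)))
    rot <- sv$u %*% (t(sv$v) * c(1, 1, d))
    co[i, , ] <- xc %*% rot + tcrossprod(ones, cy)
  }
  co
}
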