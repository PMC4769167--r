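# Pore radius profile along the membrane normal: largest sphere centred in
# each slice plane that touches no atom, found by a deterministic grid search
# with local refinement that follows the pathway from slice to slice.

#' Van der Waals radius tables
#'
#' `"hole"` mirrors the simple radius set commonly used for pore profiling
#' (C 1.85, N 1.75, O 1.65, S 2.00, H 1.00, P 2.10); `"bondi"` is the Bondi
#' set. Both cover every protein element.
#'
#' @param table `"hole"` (default) or `"bondi"`.
#' @return Named numeric vector, element -> radius (Angstrom).
#' @export
vdw_radii <- function(table = c("hole", "bondi")) {
  table <- match.arg(table)
  switch(table,
    hole = c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, H = 1.00, P = 2.10,
             CL = 1.81, FE = 1.70, ZN = 1.39, NA. = 2.27, MG = 1.73),
    bondi = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
              CL = 1.75, FE = 1.70, ZN = 1.39, NA. = 2.27, MG = 1.73))
}

#' Attach van der Waals radii to a structure
#'
#' @param structure A `gm_structure`.
#' @param table Radius table name (see [vdw_radii()]) or a named vector.
#' @param default Radius for elements missing from the table.
#' @return The structure with a `radius` column on `atoms`.
#' @export
assign_radii <- function(structure, table = "hole", default = 1.85) {
  tab <- if (is.character(table) && length(table) == 1L) vdw_radii(table)
         else table
  el <- structure$atoms$element
  el[el == "NA"] <- "NA."            # sodium vs missing-value guard
  r <- unname(tab[el])
  r[is.na(r)] <- default
  structure$atoms$radius <- r
  structure
}

#' Pore radius profile along an axis
#'
#' At each position z along `axis` (measured from `origin`), the pore radius
#' is the largest `min_i(|c - a_i| - vdw_i)` over candidate sphere centres
#' `c` in the slice plane. The search starts from the previous slice's
#' centre (first slice: the supplied origin), explores a deterministic grid
#' within `max_center_step` of it, and refines the best grid point by
#' Nelder-Mead. This connectivity constraint makes the profile follow a
#' single pathway instead of jumping between unconnected cavities. The
#' radius may be negative (blocked pore) and is capped at `cap`.
#'
#' @param structure A `gm_structure` with radii (see [assign_radii()]).
#' @param axis Unit 3-vector, the membrane normal (default z).
#' @param origin Point on the axis where z = 0 (e.g. the central Cl- site).
#' @param z_range Length-2 numeric, z interval to profile (Angstrom).
#' @param step Slice spacing (Angstrom, default 0.5).
#' @param cap Maximum reported radius (default 15).
#' @param max_center_step In-plane search window around the previous centre
#'   (Angstrom, default 2).
#' @return A `gm_pore_profile`: data frame with columns `z`, `radius`, and
#'   centre coordinates `cx`, `cy`, `cz`; attributes `axis`, `origin`, `cap`.
#' @export
pore_profile <- function(structure, axis = c(0, 0, 1), origin,
                         z_range, step = 0.5, cap = 15,
                         max_center_step = 2) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6) stopf("axis must be unit length")
  if (is.null(structure$atoms$radius))
    stopf("structure has no radii; call assign_radii() first")
  a <- as.matrix(structure$atoms[, c("x", "y", "z")])
  vdw <- structure$atoms$radius
  # orthonormal in-plane basis
  e1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  zs <- seq(z_range[1], z_range[2], by = step)
  az <- as.numeric((a - matrix(origin, nrow(a), 3, byrow = TRUE)) %*% axis)
  uv_prev <- c(0, 0)                    # in-plane offset of previous centre
  out <- data.frame(z = zs, radius = NA_real_,
                    cx = NA_real_, cy = NA_real_, cz = NA_real_)
  for (i in seq_along(zs)) {
    z <- zs[i]
    near <- which(abs(az - z) <= cap + max(vdw))
    if (length(near) == 0L) {
      warnf("no atoms near slice z = %.2f; radius capped", z)
      cen <- origin + z * axis + uv_prev[1] * e1 + uv_prev[2] * e2
      out[i, c("radius", "cx", "cy", "cz")] <- c(cap, cen)
      next
    }
    an <- a[near, , drop = FALSE]; vn <- vdw[near]
    fobj <- function(uv) {
      cen <- origin + z * axis + uv[1] * e1 + uv[2] * e2
      d <- sqrt(rowSums((an - matrix(cen, nrow(an), 3, byrow = TRUE))^2))
      min(d - vn)
    }
    # deterministic grid around the previous centre, then local refinement
    g <- seq(-max_center_step, max_center_step, by = 0.25)
    grid <- expand.grid(u = uv_prev[1] + g, v = uv_prev[2] + g)
    vals <- apply(grid, 1, fobj)
    best <- as.numeric(grid[which.max(vals), ])
    opt <- stats::optim(best, function(uv) {
      if (max(abs(uv - uv_prev)) > max_center_step) return(1e6)
      -fobj(uv)
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-10, maxit = 400))
    uv_prev <- opt$par
    cen <- origin + z * axis + uv_prev[1] * e1 + uv_prev[2] * e2
    out[i, c("radius", "cx", "cy", "cz")] <- c(min(-opt$value, cap), cen)
  }
  structure(out, class = c("gm_pore_profile", "data.frame"),
            axis = axis, origin = origin, cap = cap)
}

#' Locate the bottleneck of a pore profile
#'
#' Global minimum radius within a z-region; ties broken towards smaller z.
#'
#' @param profile A `gm_pore_profile`.
#' @param region Length-2 numeric `(z_lo, z_hi)`; default: the full profile.
#' @return List with `z` and `radius` of the bottleneck.
#' @export
bottleneck <- function(profile, region = range(profile$z)) {
  keep <- profile$z >= region[1] & profile$z <= region[2]
  if (!any(keep)) stopf("region does not overlap the profile")
  sub <- profile[keep, , drop = FALSE]
  i <- which.min(sub$radius)           # which.min takes the first (smaller z)
  list(z = sub$z[i], radius = sub$radius[i])
}

#' Two-fold symmetry axis of a homodimer
#'
#' Superposes one subunit onto the other (pairing by residue number and atom
#' name) and returns the rotation axis, i.e. the eigenvector of the fitted
#' rotation with eigenvalue +1. For a C2 dimer this is the molecular two-fold,
#' which for a membrane protein dimer approximates the membrane normal.
#'
#' @param structure A `gm_structure` with (at least) two chains.
#' @param chains Length-2 chain ids (default: the first two).
#' @param atoms Atom names used for pairing (default CA).
#' @return Unit 3-vector (sign convention: positive z component).
#' @export
twofold_axis <- function(structure, chains = NULL, atoms = "CA") {
  if (is.null(chains)) chains <- unique(structure$atoms$chain)[1:2]
  a <- select_atoms(structure, chains = chains[1], atoms = atoms)
  b <- select_atoms(structure, chains = chains[2], atoms = atoms)
  common <- intersect(a$resno, b$resno)
  if (length(common) < 3L) stopf("subunits share fewer than 3 residues")
  xa <- coords(structure, a)[match(common, a$resno), , drop = FALSE]
  xb <- coords(structure, b)[match(common, b$resno), , drop = FALSE]
  rot <- superpose(xa, xb)$rotation
  e <- eigen(rot)
  k <- which.min(abs(e$values - 1))
  ax <- Re(e$vectors[, k])
  ax <- ax / sqrt(sum(ax^2))
  if (ax[3] < 0) ax <- -ax
  ax
}

#' Pick the central anion site of a structure as profile origin
#'
#' Returns the coordinates of the bound Cl- HETATM closest to the mean of
#' the coordinating residues (if given), or the Cl- nearest the structure
#' centroid.
#'
#' @param structure A `gm_structure`.
#' @param near Optional site spec list/strings (as in [pair_distance()])
#'   whose mean position anchors the search.
#' @export
central_anion_site <- function(structure, near = NULL) {
  a <- structure$atoms
  cl <- which(a$het & a$element == "CL")
  if (length(cl) == 0L) stopf("no Cl- HETATM in structure")
  target <- if (is.null(near)) colMeans(a[, c("x", "y", "z")])
            else colMeans(do.call(rbind, lapply(near, function(s)
              locate_site(structure, s))))
  d <- sqrt(rowSums(sweep(as.matrix(a[cl, c("x", "y", "z")]), 2,
                          as.numeric(target))^2))
  as.numeric(a[cl[which.min(d)], c("x", "y", "z")])
}
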