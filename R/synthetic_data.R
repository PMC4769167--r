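# Synthetic homodimer generator with planted orthonormal collective modes.
# Frames fluctuate along the planted modes with Gaussian amplitudes plus
# isotropic noise and optional rigid-body jitter, so every stage of the
# pipeline can be validated against a known generative model.

#' Build a C2-symmetric two-subunit Calpha template
#'
#' Each pseudo-subunit is a bundle of parallel ideal helices (rise 1.5 A,
#' radius 2.3 A, 100 degrees/residue) with consecutive residue numbering per
#' chain; chain B is the exact 180-degree rotation of chain A about the
#' dimer two-fold (z) axis. Subunit centroids sit exactly `dimer_sep` apart.
#' A small seeded perturbation is applied to chain A before mirroring so the
#' construction has no accidental exact degeneracies.
#'
#' @param n_per_subunit Atoms (residues) per subunit; must be >= 4 and is
#'   split evenly over `n_helices`.
#' @param n_helices Helices per subunit (default 2).
#' @param helix_sep Distance between helix axes within a subunit (A, default 8).
#' @param dimer_sep Distance between subunit centroids (A, default 24).
#' @param jitter_sd Magnitude of the symmetry-breaking perturbation (A).
#' @param seed RNG seed (construction is deterministic per seed).
#' @return A `gm_structure` with chains A and B.
#' @export
make_dimer_template <- function(n_per_subunit = 50L, n_helices = 2L,
                                helix_sep = 8, dimer_sep = 24,
                                jitter_sd = 0.15, seed = 1L) {
  if (n_per_subunit < 4L) stopf("need at least 4 atoms per subunit")
  per_helix <- n_per_subunit %/% n_helices
  counts <- rep(per_helix, n_helices)
  counts[n_helices] <- n_per_subunit - per_helix * (n_helices - 1L)
  rise <- 1.5; rad <- 2.3; turn <- 100 * pi / 180
  xs <- (seq_len(n_helices) - (n_helices + 1) / 2) * helix_sep
  xyz <- do.call(rbind, lapply(seq_len(n_helices), function(h) {
    i <- seq_len(counts[h]) - 1L
    cbind(xs[h] + rad * cos(i * turn), rad * sin(i * turn), rise * i)
  }))
  xyz <- with_seed(seed, xyz + matrix(stats::rnorm(length(xyz), sd = jitter_sd),
                                      nrow(xyz), 3))
  xyz <- sweep(xyz, 2, colMeans(xyz))            # centre subunit exactly
  a_coords <- sweep(xyz, 2, c(-dimer_sep / 2, 0, 0), `+`)
  rot180 <- diag(c(-1, -1, 1))                   # C2 about z
  b_coords <- a_coords %*% rot180
  structure_from_coords(rbind(a_coords, b_coords),
                        chain = rep(c("A", "B"), each = n_per_subunit),
                        title = "synthetic dimer template")
}

# --- mode construction helpers -------------------------------------------

# 6 orthonormal rigid-body displacement fields (3 translations, 3 rotations)
# for atoms restricted to `atom_idx` of the template coordinates
rigid_generators <- function(xyz, atom_idx = seq_len(nrow(xyz))) {
  M_all <- nrow(xyz)
  sub <- xyz[atom_idx, , drop = FALSE]
  cen <- colMeans(sub)
  xc <- sweep(sub, 2, cen)
  fields <- list(
    cbind(1, 0, 0), cbind(0, 1, 0), cbind(0, 0, 1),
    cbind(0, -xc[, 3], xc[, 2]),        # rotation about x
    cbind(xc[, 3], 0, -xc[, 1]),        # about y
    cbind(-xc[, 2], xc[, 1], 0))        # about z
  g <- vapply(fields, function(f) {
    full <- matrix(0, M_all, 3)
    full[atom_idx, ] <- if (nrow(f) == 1L) matrix(f, length(atom_idx), 3,
                                                  byrow = TRUE) else f
    flatten_coords(full)
  }, numeric(3L * M_all))
  qr.Q(qr(g))[, seq_len(qr(g)$rank), drop = FALSE]
}

# coordinate basis vectors that pin selected atoms to zero displacement
pin_vectors <- function(M_all, atom_idx) {
  cols <- as.vector(vapply(atom_idx, function(i) 3L * (i - 1L) + 1:3,
                           integer(3)))
  diag(3L * M_all)[, cols, drop = FALSE]
}

# project columns of u orthogonal to the span of the constraint basis cb
project_out <- function(u, cb) {
  if (is.null(cb) || ncol(cb) == 0L) return(u)
  q <- qr.Q(qr(cb))
  u - q %*% crossprod(q, u)
}

# normalise a projected field, refusing degenerate residuals (too many
# constraints for the subunit size)
normalise_residual <- function(u, what) {
  nrm <- sqrt(sum(u^2))
  if (nrm < 1e-6)
    stopf("%s vanishes under the rigid/pinning constraints; increase the subunit size",
          what)
  u / nrm
}

# smooth low-order polynomial displacement fields on a subunit
smooth_fields <- function(xyz, atom_idx, n, seed) {
  sub <- xyz[atom_idx, , drop = FALSE]
  sc <- scale(sub)
  basis <- cbind(1, sc, sc^2, sc[, 1] * sc[, 2], sc[, 1] * sc[, 3],
                 sc[, 2] * sc[, 3])
  nb <- ncol(basis)
  with_seed(seed, {
    vapply(seq_len(n), function(k) {
      co <- matrix(stats::rnorm(3 * nb), nb, 3)
      full <- matrix(0, nrow(xyz), 3)
      full[atom_idx, ] <- basis %*% co
      flatten_coords(full)
    }, numeric(3L * nrow(xyz)))
  })
}

#' Plant a gate-opening collective mode
#'
#' Constructs a unit 3M displacement mode, localized on a residue support
#' window, whose positive-direction deformation strictly increases the gate
#' pair distance. The mode is the sum of a smooth collective carrier (exactly
#' zero at the pair and protected atoms) and a small opening component that
#' pulls the two pair atoms apart along their connecting axis, with tapered
#' displacement of sequence neighbours inside the support window. The result
#' is projected exactly orthogonal to rigid-body motion, to the coordinates
#' of `protect`ed atoms, and to `prev_modes`, then normalised.
#'
#' @param template A `gm_structure` (the dimer template).
#' @param pair A `gm_gate_pair` with a chain (both sites on one subunit).
#' @param support Residue-number vector of the support window; must contain
#'   both pair residues (default: pair residues +/- 3).
#' @param protect Optional list of site specs (see [pair_distance()]) pinned
#'   to zero displacement, e.g. a control pair.
#' @param opening_share Fraction of the mode's squared norm carried by the
#'   opening component (default 0.01; see the methods vignette for how this
#'   sets the pure-mode delta-r at the study deformation).
#' @param prev_modes Optional 3M x k matrix of previously planted modes to
#'   orthogonalise against.
#' @param seed Seed for the carrier field.
#' @return Unit numeric vector of length 3M (M = total template atoms).
#' @export
plant_gate_mode <- function(template, pair, support = NULL, protect = NULL,
                            opening_share = 0.01, prev_modes = NULL,
                            seed = 1L) {
  xyz <- coords(template)
  at <- template$atoms
  chain <- if (is.null(pair$chain)) "A" else pair$chain[1]
  if (is.null(support)) support <- c(pair$res_a + (-3:3), pair$res_b + (-3:3))
  if (!(pair$res_a %in% support) || !(pair$res_b %in% support))
    stopf("support window excludes the gate pair residues")
  chain_idx <- which(at$chain == chain)
  ia <- which(at$chain == chain & at$resno == pair$res_a & at$name == pair$atom)
  ib <- which(at$chain == chain & at$resno == pair$res_b & at$name == pair$atom)
  if (length(ia) != 1L || length(ib) != 1L)
    stopf("gate pair %s not resolvable in template chain %s", pair$label, chain)
  axis <- xyz[ib, ] - xyz[ia, ]
  axis <- axis / sqrt(sum(axis^2))
  # opening pattern: anchors move apart along the axis, sequence neighbours
  # inside the window follow with geometric taper
  p <- matrix(0, nrow(xyz), 3)
  add_side <- function(p, anchor_res, dir) {
    for (res in intersect(support, at$resno[chain_idx])) {
      d_a <- abs(res - pair$res_a); d_b <- abs(res - pair$res_b)
      near <- min(d_a, d_b)
      anchored_to_a <- d_a <= d_b
      if ((anchored_to_a && anchor_res == pair$res_a) ||
          (!anchored_to_a && anchor_res == pair$res_b)) {
        i <- which(at$chain == chain & at$resno == res & at$name == pair$atom)
        if (length(i) == 1L) p[i, ] <- dir * 0.5^near
      }
    }
    p
  }
  p <- add_side(p, pair$res_a, -axis)
  p <- add_side(p, pair$res_b, +axis)
  pv <- flatten_coords(p)
  # constraints: rigid motion of the subunit + pinned (protected) atoms
  prot_idx <- unlist(lapply(protect, function(s) {
    s <- parse_site(s)
    which(at$chain == s$chain & at$resno == s$resno & at$name == s$atom)
  }))
  cb <- cbind(rigid_generators(xyz, chain_idx),
              if (length(prot_idx)) pin_vectors(nrow(xyz), prot_idx))
  pv <- normalise_residual(project_out(pv, cb), "opening pattern")
  # carrier: smooth field on the subunit, pinned at pair + support + protected
  support_idx <- which(at$chain == chain & at$resno %in% support &
                         at$name == pair$atom)
  cb_car <- cbind(cb, pin_vectors(nrow(xyz), unique(c(support_idx, ia, ib))))
  carrier <- normalise_residual(
    project_out(smooth_fields(xyz, chain_idx, 1L, seed = seed), cb_car),
    "carrier field")
  u <- sqrt(1 - opening_share) * carrier + sqrt(opening_share) * pv
  if (!is.null(prev_modes)) u <- u - prev_modes %*% crossprod(prev_modes, u)
  u <- as.numeric(normalise_residual(u, "gate mode"))
  # defining property: +A deformation must open the pair
  spec1 <- deformation_spec(nrow(xyz), target_rmsd = 1)
  sel_all <- select_atoms(template)
  if (delta_r(xyz, deform(xyz, u, spec1, 1), pair, sel_all) <= 0)
    u <- -u
  u
}

#' Planted collective-mode model of a homodimer
#'
#' @param template `gm_structure`, the reference conformation.
#' @param modes 3M x K matrix of orthonormal planted modes `B_k`.
#' @param amplitudes Mode amplitudes `s_k` in Angstrom (length K, > 0),
#'   optionally named.
#' @param sigma Isotropic coordinate noise SD (A, >= 0, default 0.1).
#' @param jitter List with `max_rot_deg` and `max_trans` for per-frame
#'   rigid-body jitter (either 0 disables that part).
#' @param gate_pairs Named list of `gm_gate_pair` (e.g. `target`, `control`).
#' @param seed Default seed for [sample_trajectory()].
#' @return A `gm_planted_model`.
#' @export
planted_model <- function(template, modes, amplitudes, sigma = 0.1,
                          jitter = list(max_rot_deg = 3, max_trans = 1),
                          gate_pairs = list(), seed = 1L) {
  modes <- as.matrix(modes)
  if (length(amplitudes) != ncol(modes))
    stopf("need one amplitude per mode")
  if (any(amplitudes <= 0)) stopf("amplitudes must be positive")
  if (sigma < 0) stopf("sigma must be >= 0")
  gram <- crossprod(modes)
  if (max(abs(gram - diag(ncol(modes)))) > 1e-9)
    stopf("planted modes are not orthonormal")
  structure(list(template = template, modes = modes,
                 amplitudes = amplitudes, sigma = sigma, jitter = jitter,
                 gate_pairs = gate_pairs, seed = seed),
            class = "gm_planted_model")
}

#' Standard synthetic study model
#'
#' A two-helix-bundle homodimer (50 atoms per subunit) carrying, per subunit,
#' one gate-opening mode (amplitude 3 A, the dominant motion) and four smooth
#' background modes (2.5, 2, 1.5, 1 A), with 0.1 A isotropic noise and mild
#' rigid-body jitter. The target gate pair spans the two helices mid-bundle;
#' a control pair sits at the helix N-termini and is pinned to zero in every
#' planted mode. Mode labels are `gate.A`, `bg1.A`, ..., `bg4.B`.
#'
#' @param n_per_subunit Atoms per subunit (default 50).
#' @param amplitudes Per-subunit amplitudes, gate first (default
#'   `c(3, 2.5, 2, 1.5, 1)`).
#' @param sigma Noise SD (default 0.1 A).
#' @param jitter Rigid-body jitter spec (see [planted_model()]).
#' @param seed Construction + default sampling seed.
#' @return A `gm_planted_model` with `gate_pairs$target` and
#'   `gate_pairs$control`.
#' @export
default_planted_model <- function(n_per_subunit = 50L,
                                  amplitudes = c(3, 2.5, 2, 1.5, 1),
                                  sigma = 0.1,
                                  jitter = list(max_rot_deg = 3, max_trans = 1),
                                  seed = 1L) {
  template <- make_dimer_template(n_per_subunit, seed = seed)
  half <- n_per_subunit %/% 2L
  target_res <- c(floor(half / 2), half + floor(half / 2))   # mid-bundle rung
  control_res <- c(3L, half + 3L)                            # near N-termini
  n_bg <- length(amplitudes) - 1L
  labels <- c("gate", paste0("bg", seq_len(n_bg)))
  all_modes <- NULL
  amps <- numeric(0)
  for (ch in c("A", "B")) {
    pair <- gate_pair(target_res[1], target_res[2],
                      label = "target", chain = ch)
    protect <- list(list(chain = ch, resno = control_res[1], atom = "CA"),
                    list(chain = ch, resno = control_res[2], atom = "CA"))
    gate <- plant_gate_mode(template, pair, protect = protect,
                            prev_modes = all_modes,
                            seed = seed + match(ch, c("A", "B")))
    all_modes <- cbind(all_modes, gate)
    # background: smooth fields, rigid-free, pinned at both measured pairs
    at <- template$atoms
    chain_idx <- which(at$chain == ch)
    pin_idx <- which(at$chain == ch &
                       at$resno %in% c(target_res, control_res) &
                       at$name == "CA")
    cb <- cbind(rigid_generators(coords(template), chain_idx),
                pin_vectors(nrow(at), pin_idx), all_modes)
    raw <- project_out(smooth_fields(coords(template), chain_idx, n_bg,
                                     seed = seed + 10L + match(ch, c("A", "B"))),
                       cb)
    if (min(svd(raw)$d) < 1e-6)
      stopf("background modes are degenerate; increase n_per_subunit")
    bg <- qr.Q(qr(raw))[, seq_len(n_bg), drop = FALSE]
    all_modes <- cbind(all_modes, bg)
    amps <- c(amps, amplitudes)
  }
  colnames(all_modes) <- paste(rep(labels, 2), rep(c("A", "B"), each = n_bg + 1L),
                               sep = ".")
  names(amps) <- colnames(all_modes)
  planted_model(template, all_modes, amps, sigma = sigma, jitter = jitter,
                gate_pairs = list(
                  target = gate_pair(target_res[1], target_res[2],
                                     label = "target"),
                  control = gate_pair(control_res[1], control_res[2],
                                      label = "control")),
                seed = seed)
}

#' Dampen a planted mode
#'
#' Scales the amplitude of the selected mode(s) by `factor`, emulating a
#' motion restricted by, e.g., an inter-subunit cross-link. Everything else
#' (modes, noise, seed handling) is untouched.
#'
#' @param model A `gm_planted_model`.
#' @param mode Mode index/indices, or a label prefix such as `"gate"`
#'   (matches the mode in both subunits).
#' @param factor Scaling in `(0, 1]`.
#' @export
dampen <- function(model, mode = "gate", factor) {
  if (!is_number(factor) || factor <= 0 || factor > 1)
    stopf("factor must be in (0, 1]")
  idx <- if (is.character(mode)) {
    grep(paste0("^", mode), names(model$amplitudes))
  } else as.integer(mode)
  if (length(idx) == 0L || any(idx < 1L | idx > length(model$amplitudes)))
    stopf("no such planted mode: %s", paste(mode, collapse = ","))
  model$amplitudes[idx] <- model$amplitudes[idx] * factor
  model
}

#' Sample a trajectory from a planted model
#'
#' Frame n is `template + sum_k s_k z_nk B_k + noise`, with `z_nk` standard
#' normal and isotropic Gaussian coordinate noise, followed by optional
#' rigid-body jitter (random rotation about the centroid up to
#' `max_rot_deg`, random translation up to `max_trans` per axis). Fully
#' reproducible for a given seed.
#'
#' @param model A `gm_planted_model`.
#' @param n_frames Number of frames (>= 2).
#' @param frame_dt_ns Frame spacing in ns (default 1).
#' @param seed RNG seed (default: the model's seed).
#' @return A `gm_trajectory` over the template's CA atoms.
#' @export
sample_trajectory <- function(model, n_frames, frame_dt_ns = 1,
                              seed = NULL) {
  if (n_frames < 2L) stopf("need at least 2 frames")
  if (is.null(seed)) seed <- model$seed
  x0 <- flatten_coords(coords(model$template))
  M <- length(x0) / 3L
  K <- ncol(model$modes)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_frames * K), n_frames, K)
    disp <- z %*% (t(model$modes) * model$amplitudes)  # n x 3M
    if (model$sigma > 0)
      disp <- disp + matrix(stats::rnorm(n_frames * 3L * M,
                                         sd = model$sigma), n_frames)
    co <- array(0, dim = c(n_frames, M, 3L))
    max_rot <- model$jitter$max_rot_deg %||% 0
    max_trans <- model$jitter$max_trans %||% 0
    for (i in seq_len(n_frames)) {
      fr <- unflatten_coords(x0 + disp[i, ])
      if (max_rot > 0 || max_trans > 0) {
        ang <- stats::runif(1, 0, max_rot) * pi / 180
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        R <- rotation_matrix(ax, ang)
        cen <- colMeans(fr)
        fr <- sweep(fr, 2, cen) %*% R +
          matrix(cen + stats::runif(3, -max_trans, max_trans), M, 3,
                 byrow = TRUE)
      }
      co[i, , ] <- fr
    }
    sel <- select_atoms(model$template)
    trajectory_from_coords(co, sel, times = frame_dt_ns)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rotation_matrix <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle); t_ <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(t_ * x * x + c_, t_ * x * y - s_ * z, t_ * x * z + s_ * y,
           t_ * x * y + s_ * z, t_ * y * y + c_, t_ * y * z - s_ * x,
           t_ * x * z - s_ * y, t_ * y * z + s_ * x, t_ * z * z + c_),
         3, 3, byrow = TRUE)
}
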