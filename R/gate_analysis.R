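# Mode deformation of a reference structure to a fixed RMSD and counting of
# modes that widen gate residue pairs beyond a distance-change threshold.

#' Define a gate residue pair
#'
#' Both sites are Calpha atoms identified by (chain-relative) residue number;
#' when the analysed selection covers one subunit, the chain can be left NULL
#' and the pair resolves within that subunit.
#'
#' @param res_a,res_b Residue numbers of the two sites.
#' @param label Pair label (default `"a-b"`).
#' @param chain Optional chain id restricting the lookup.
#' @param atom Atom name (default `"CA"`).
#' @return A `gm_gate_pair`.
#' @export
gate_pair <- function(res_a, res_b, label = NULL, chain = NULL, atom = "CA") {
  if (identical(res_a, res_b) && (is.null(chain) || length(chain) < 2L))
    stopf("gate pair sites must differ")
  if (is.null(label)) label <- paste0(res_a, "-", res_b)
  structure(list(res_a = res_a, res_b = res_b, label = label,
                 chain = chain, atom = atom), class = "gm_gate_pair")
}

# pair -> indices into a selection; errors if unresolvable
resolve_pair <- function(pair, selection) {
  find1 <- function(resno, which_chain) {
    mask <- selection$resno == resno & selection$atom == pair$atom
    if (!is.null(which_chain)) mask <- mask & selection$chain == which_chain
    hit <- which(mask)
    if (length(hit) != 1L)
      stopf("gate pair %s: residue %s %s in selection", pair$label, resno,
            if (length(hit) == 0L) "not found" else "ambiguous (give chain)")
    hit
  }
  chains <- pair$chain
  c(find1(pair$res_a, if (is.null(chains)) NULL else chains[1]),
    find1(pair$res_b, if (is.null(chains)) NULL else chains[length(chains)]))
}

#' Deformation amplitude spec for mode displacement at fixed RMSD
#'
#' Displacing M atoms along a unit 3M-vector by amplitude A produces an RMSD
#' of exactly A / sqrt(M) from the reference, so A = target_rmsd * sqrt(M).
#'
#' @param M Number of atoms in the deformed selection.
#' @param target_rmsd Target RMSD of the deformed structure (Angstrom,
#'   default 3.5).
#' @param sign_policy How the +/- directions enter the opening count:
#'   `"both"` (a mode opens a pair if either direction does; default),
#'   `"plus"`, or `"minus"`.
#' @return A `gm_deformation_spec` with fields `M`, `target_rmsd`, `A`,
#'   `sign_policy`.
#' @export
deformation_spec <- function(M, target_rmsd = 3.5,
                             sign_policy = c("both", "plus", "minus")) {
  if (!is_number(target_rmsd) || target_rmsd <= 0)
    stopf("target_rmsd must be positive")
  if (!is_number(M) || M < 1) stopf("M must be a positive integer")
  structure(list(M = as.integer(M), target_rmsd = target_rmsd,
                 A = target_rmsd * sqrt(M),
                 sign_policy = match.arg(sign_policy)),
            class = "gm_deformation_spec")
}

#' Deform a reference coordinate set along one collective mode
#'
#' `X' = X0 + sign * A * R_k` with the mode reshaped to M x 3. No
#' re-superposition is applied: the displacement itself is the deformation,
#' so `RMSD(X0, X') == target_rmsd` exactly for a unit mode.
#'
#' @param x0 M x 3 reference coordinates.
#' @param mode Unit vector of length 3M (atom-major flattening).
#' @param spec A `gm_deformation_spec` with matching `M`.
#' @param sign `+1` or `-1`.
#' @return Deformed M x 3 coordinates.
#' @export
deform <- function(x0, mode, spec, sign = 1) {
  x0 <- as.matrix(x0)
  if (nrow(x0) != spec$M) stopf("x0 has %d atoms, spec expects %d",
                                nrow(x0), spec$M)
  if (length(mode) != 3L * spec$M)
    stopf("mode has length %d, expected 3M = %d", length(mode), 3L * spec$M)
  nrm <- sqrt(sum(mode^2))
  if (abs(nrm - 1) > 1e-9) stopf("mode is not unit length (|R| = %.6g)", nrm)
  if (!sign %in% c(-1, 1)) stopf("sign must be +1 or -1")
  x0 + sign * spec$A * unflatten_coords(mode)
}

#' Gate distance change caused by a deformation
#'
#' `delta_r = |x'_i - x'_j| - |x_i - x_j|`; positive values mean the pair
#' opens, negative values mean it closes.
#'
#' @param x0 Reference M x 3 coordinates.
#' @param x1 Deformed M x 3 coordinates.
#' @param pair A `gm_gate_pair`.
#' @param selection The `gm_selection` labelling the rows of `x0`/`x1`.
#' @return Signed length change in Angstrom.
#' @export
delta_r <- function(x0, x1, pair, selection) {
  ij <- resolve_pair(pair, selection)
  d0 <- sqrt(sum((x0[ij[1], ] - x0[ij[2], ])^2))
  d1 <- sqrt(sum((x1[ij[1], ] - x1[ij[2], ])^2))
  d1 - d0
}

#' Count the collective modes that open each gate pair
#'
#' Each of the top modes is applied to the reference structure at the fixed
#' deformation RMSD; a mode counts for a pair when its distance change
#' (under the sign policy) strictly exceeds `threshold`.
#'
#' @param modes A `gm_modes`.
#' @param x0 Reference M x 3 coordinates (same selection as the modes).
#' @param pairs List of `gm_gate_pair` (a single pair is accepted).
#' @param spec A `gm_deformation_spec`.
#' @param threshold Opening threshold in Angstrom (default 1.5).
#' @param selection Selection labelling the atoms.
#' @param segment_id Optional id string (subunit/block) for reporting.
#' @return A `gm_segment_counts`: data frame with one row per pair
#'   (`pair`, `count`) plus attributes `segment_id`, `k_max`, `threshold`,
#'   and the per-mode `delta_r` matrix (modes x pairs, max over the policy's
#'   signs).
#' @export
count_opening_modes <- function(modes, x0, pairs, spec, threshold = 1.5,
                                selection, segment_id = NULL) {
  if (inherits(pairs, "gm_gate_pair")) pairs <- list(pairs)
  if (length(pairs) == 0L) stopf("empty gate pair list")
  x0 <- as.matrix(x0)
  idx <- lapply(pairs, resolve_pair, selection = selection)
  d0 <- vapply(idx, function(ij)
    sqrt(sum((x0[ij[1], ] - x0[ij[2], ])^2)), numeric(1))
  signs <- switch(spec$sign_policy, both = c(1, -1), plus = 1, minus = -1)
  k <- modes$k_max
  dr <- matrix(-Inf, nrow = k, ncol = length(pairs))
  for (m in seq_len(k)) {
    for (s in signs) {
      x1 <- deform(x0, modes$vectors[, m], spec, sign = s)
      for (p in seq_along(pairs)) {
        ij <- idx[[p]]
        d1 <- sqrt(sum((x1[ij[1], ] - x1[ij[2], ])^2))
        dr[m, p] <- max(dr[m, p], d1 - d0[p])
      }
    }
  }
  colnames(dr) <- vapply(pairs, `[[`, character(1), "label")
  counts <- colSums(dr > threshold)
  out <- data.frame(pair = colnames(dr), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gm_segment_counts", "data.frame"),
            segment_id = segment_id, k_max = k, threshold = threshold,
            delta_r = dr)
}

#' Assemble per-segment counts into a segments x pairs matrix
#'
#' @param count_list List of `gm_segment_counts` (one per segment).
#' @return Integer matrix, rows named by segment id, columns by pair label.
#' @export
segment_count_table <- function(count_list) {
  stopifnot(length(count_list) >= 1L)
  pairs <- count_list[[1]]$pair
  mat <- t(vapply(count_list, function(sc) {
    if (!identical(sc$pair, pairs)) stopf("segments disagree on pair list")
    sc$count
  }, integer(length(pairs))))
  colnames(mat) <- pairs
  ids <- vapply(seq_along(count_list), function(i) {
    id <- attr(count_list[[i]], "segment_id")
    if (is.null(id)) sprintf("segment%d", i) else id
  }, character(1))
  rownames(mat) <- ids
  mat
}
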