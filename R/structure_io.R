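# Structure and trajectory IO: fixed-column PDB records plus a plain-text
# frame-matrix trajectory format. Binary MD formats are deliberately not
# parsed here; frames from such files enter through trajectory_from_coords()
# (the adapter seam).

KNOWN_TWO_LETTER <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CU", "SE", "CD")

#' Read a structure from PDB-format content
#'
#' Parses fixed-column `ATOM`/`HETATM` records. Only the first `MODEL` block is
#' returned (use [read_trajectory()] for multi-model files). Alternate
#' locations other than blank or `'A'` are dropped so that coordinates are a
#' deterministic single conformer; occupancies are ignored. Residue numbering
#' is the author numbering of the file, and insertion codes are preserved.
#'
#' @param file Path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or of length > 1 is treated as content).
#' @param model Which `MODEL` block to return (default first).
#' @return An object of class `gm_structure`: a list with `atoms` (data frame
#'   with columns `name`, `element`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `het`) and `title`.
#' @export
read_structure <- function(file, model = 1L) {
  lines <- pdb_lines(file)
  models <- parse_pdb_models(lines)
  if (length(models) == 0L)
    stopf("no ATOM/HETATM records found: empty structure")
  if (model > length(models))
    stopf("requested model %d but file has %d model(s)", model, length(models))
  title <- sub("^TITLE\\s+", "", grep("^TITLE", lines, value = TRUE)[1])
  if (is.na(title)) title <- if (is.character(file) && length(file) == 1L &&
                                 !grepl("\n", file)) basename(file) else "pdb"
  new_structure(models[[model]], title = title)
}

pdb_lines <- function(file) {
  if (is.character(file) && length(file) == 1L && !grepl("\n", file) &&
      file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
}

# split PDB lines into models, each a parsed atom data frame
parse_pdb_models <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_idx <- cumsum(grepl("^MODEL", lines))
  if (!any(model_idx > 0)) model_idx <- rep(1L, length(lines)) else
    model_idx[model_idx == 0L] <- 1L
  keep <- which(is_atom)
  if (length(keep) == 0L) return(list())
  atoms <- parse_atom_records(lines[keep], keep)
  split_f <- model_idx[keep]
  parts <- split(atoms, factor(split_f, levels = unique(split_f)))
  lapply(parts, filter_altloc)
}

parse_atom_records <- function(atom_lines, line_numbers) {
  f <- function(a, b) substr(atom_lines, a, b)
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  resno <- suppressWarnings(as.integer(f(23, 26)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resno))
  if (length(bad) > 0L)
    stopf("malformed fixed-width ATOM/HETATM record at line %d",
          line_numbers[bad[1]])
  name_raw <- f(13, 16)
  elem_col <- trimws(f(77, 78))
  data.frame(
    record  = trimws(f(1, 6)),
    name    = trimws(name_raw),
    altloc  = f(17, 17),
    resid   = trimws(f(18, 20)),
    chain   = f(22, 22),
    resno   = resno,
    insert  = f(27, 27),
    x = x, y = y, z = z,
    element = infer_element(name_raw, elem_col),
    het     = trimws(f(1, 6)) == "HETATM",
    stringsAsFactors = FALSE
  )
}

# element from the element column when present, else from the atom-name field
infer_element <- function(name_raw, elem_col) {
  el <- toupper(elem_col)
  need <- el == "" | is.na(el)
  if (any(need)) {
    two <- toupper(substr(name_raw[need], 1, 2))
    guess <- ifelse(two %in% KNOWN_TWO_LETTER, two, NA_character_)
    stripped <- gsub("[^A-Za-z]", "", trimws(name_raw[need]))
    first <- toupper(substr(stripped, 1, 1))
    el[need] <- ifelse(is.na(guess), first, guess)
  }
  el
}

filter_altloc <- function(atoms) {
  atoms <- atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
  atoms$altloc <- NULL
  atoms$record <- NULL
  rownames(atoms) <- NULL
  atoms
}

new_structure <- function(atoms, title = "structure") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("structure has non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key))
    stopf("duplicate atom records: %s", key[duplicated(key)][1])
  structure(list(atoms = atoms, title = title), class = "gm_structure")
}

#' Build a structure from bare coordinates
#'
#' Convenience constructor used by the synthetic-data generator: one CA atom
#' per residue, consecutive numbering per chain.
#'
#' @param xyz M x 3 coordinate matrix (Angstrom).
#' @param chain Chain id per atom (recycled).
#' @param resno Residue number per atom (default 1..n per chain).
#' @param name,resid,element Atom name, residue name, element (recycled).
#' @param title Structure title.
#' @export
structure_from_coords <- function(xyz, chain = "A", resno = NULL, name = "CA",
                                  resid = "ALA", element = "C",
                                  title = "synthetic") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  chain <- rep_len(chain, n)
  if (is.null(resno)) {
    resno <- integer(n)
    for (ch in unique(chain)) resno[chain == ch] <- seq_len(sum(chain == ch))
  }
  atoms <- data.frame(
    name = rep_len(name, n), element = rep_len(element, n),
    resid = rep_len(resid, n), chain = chain, resno = as.integer(resno),
    insert = " ", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = FALSE, stringsAsFactors = FALSE)
  new_structure(atoms, title = title)
}

#' @export
print.gm_structure <- function(x, ...) {
  cat(sprintf("<gm_structure> %s: %d atoms, chains %s\n", x$title,
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = "")))
  invisible(x)
}

#' Extract the coordinate matrix of a structure (optionally via a selection)
#' @param structure A `gm_structure`.
#' @param selection Optional `gm_selection`; if given, rows follow it.
#' @return M x 3 numeric matrix.
#' @export
coords <- function(structure, selection = NULL) {
  a <- structure$atoms
  if (!is.null(selection)) a <- a[selection$index, , drop = FALSE]
  unname(as.matrix(a[, c("x", "y", "z")]))
}

#' Write a structure as a PDB file
#' @param structure A `gm_structure`.
#' @param file Output path.
#' @export
write_structure <- function(structure, file) {
  writeLines(c(sprintf("TITLE     %s", structure$title),
               format_atom_lines(structure$atoms), "END"), file)
  invisible(file)
}

format_atom_lines <- function(a) {
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
                  sprintf("%-4s", a$name))
  sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(a)) %% 100000L, name4, a$resid,
          a$chain, a$resno, a$insert, a$x, a$y, a$z, 1, 0,
          formatC(a$element, width = 2, flag = " "))
}

#' Select atoms from a structure
#'
#' Matches by chain, residue number and atom name; output is ordered by
#' (chain, residue number, insertion code) regardless of file order, so the
#' selection is deterministic. `HETATM` records are excluded by default.
#'
#' @param structure A `gm_structure`.
#' @param chains Chain ids to keep (default all).
#' @param resno Residue numbers to keep (vector; default all). Ranges can be
#'   given as e.g. `c(10:40, 55:80)`.
#' @param atoms Atom names to keep (default `"CA"`).
#' @param het Include HETATM records (default `FALSE`).
#' @return A `gm_selection`: list with `index` (row indices into
#'   `structure$atoms`), `chain`, `resno`, `insert`, `atom`, `resid`, and `M`.
#' @export
select_atoms <- function(structure, chains = NULL, resno = NULL,
                         atoms = "CA", het = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!het) keep <- keep & !a$het
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  resmask <- keep
  if (!is.null(atoms)) keep <- keep & a$name %in% atoms
  if (!any(keep)) stopf("selection matched zero atoms")
  if (!is.null(atoms) && !is.null(resno)) {
    # residues requested and present, but lacking the named atom
    have <- unique(paste(a$chain[keep], a$resno[keep]))
    asked <- unique(paste(a$chain[resmask], a$resno[resmask]))
    missing <- setdiff(asked, have)
    if (length(missing) > 0L)
      stopf("residue(s) lacking atom %s: %s", paste(atoms, collapse = "/"),
            paste(missing, collapse = ", "))
  }
  idx <- which(keep)
  ord <- order(a$chain[idx], a$resno[idx], a$insert[idx], a$name[idx])
  idx <- idx[ord]
  structure(list(index = idx, chain = a$chain[idx], resno = a$resno[idx],
                 insert = a$insert[idx], atom = a$name[idx],
                 resid = a$resid[idx], M = length(idx)),
            class = "gm_selection")
}

#' @export
print.gm_selection <- function(x, ...) {
  cat(sprintf("<gm_selection> M = %d atoms (%s)\n", x$M,
              paste(unique(x$atom), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory from in-memory frames
#'
#' This is also the adapter seam for binary MD formats: any reader that can
#' yield an `n_frames x M x 3` array for a fixed selection can feed the
#' pipeline through this constructor.
#'
#' @param coords Array `n_frames x M x 3` (Angstrom).
#' @param selection A `gm_selection` with `M` atoms.
#' @param times Frame times in ns: full vector, a scalar time step, or `NULL`
#'   (0, 1, 2, ... ns).
#' @param subunits Subunit label per selected atom (default: the chain id).
#' @return A `gm_trajectory`.
#' @export
trajectory_from_coords <- function(coords, selection, times = NULL,
                                   subunits = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n <- dim(coords)[1]
  M <- dim(coords)[2]
  if (M != selection$M)
    stopf("coords have %d atoms but selection has M = %d", M, selection$M)
  if (!all(is.finite(coords))) {
    bad <- which(apply(!is.finite(coords), 1, any))[1]
    stopf("non-finite coordinates in frame %d", bad)
  }
  times <- expand_times(times, n)
  if (any(diff(times) <= 0)) stopf("frame times must be strictly increasing")
  if (is.null(subunits)) subunits <- selection$chain
  subunits <- rep_len(subunits, M)
  structure(list(coords = coords, times = times, selection = selection,
                 subunits = subunits), class = "gm_trajectory")
}

expand_times <- function(times, n) {
  if (is.null(times)) return(as.numeric(seq_len(n) - 1L))
  if (length(times) == 1L) return(as.numeric(times) * (seq_len(n) - 1L))
  if (length(times) != n)
    stopf("times has length %d but trajectory has %d frames", length(times), n)
  as.numeric(times)
}

#' @export
print.gm_trajectory <- function(x, ...) {
  cat(sprintf("<gm_trajectory> %d frames x %d atoms, %.6g-%.6g ns\n",
              n_frames(x), x$selection$M, min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `gm_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Read a trajectory from a multi-model PDB or frame-matrix file
#'
#' The frame-matrix format is a whitespace-delimited text file with header
#' line `FRAMES n ATOMS M` followed by `n` blocks of `M` lines of `x y z`
#' (6-decimal fixed point). For multi-model PDB input, each model must
#' contain every selected atom (matched by chain, residue number, atom name).
#'
#' @param file Input path.
#' @param selection A `gm_selection` defining atom order (for the frame-matrix
#'   format it supplies labels and must have matching `M`).
#' @param times Frame-time spec as in [trajectory_from_coords()].
#' @param format `"auto"` (default), `"pdb"` or `"mat"`.
#' @param subunits Optional subunit map (default: chain id per atom).
#' @return A `gm_trajectory`.
#' @export
read_trajectory <- function(file, selection, times = NULL,
                            format = c("auto", "pdb", "mat"),
                            subunits = NULL) {
  format <- match.arg(format)
  lines <- pdb_lines(file)
  if (format == "auto")
    format <- if (grepl("^FRAMES ", lines[1])) "mat" else "pdb"
  co <- if (format == "mat") read_mat_frames(lines, selection)
        else read_pdb_frames(lines, selection)
  trajectory_from_coords(co, selection, times = times, subunits = subunits)
}

read_mat_frames <- function(lines, selection) {
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 4L || hdr[1] != "FRAMES" || hdr[3] != "ATOMS")
    stopf("bad frame-matrix header: %s", lines[1])
  n <- as.integer(hdr[2]); M <- as.integer(hdr[4])
  if (M != selection$M)
    stopf("file has M = %d atoms per frame but selection has M = %d",
          M, selection$M)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n * M)
    stopf("expected %d coordinate lines, found %d (inconsistent M?)",
          n * M, length(body))
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != n * M * 3L) stopf("malformed coordinate line")
  aperm(array(vals, dim = c(3L, M, n)), c(3L, 2L, 1L))
}

read_pdb_frames <- function(lines, selection) {
  models <- parse_pdb_models(lines)
  if (length(models) == 0L) stopf("no ATOM/HETATM records in trajectory file")
  want <- paste(selection$chain, selection$resno, selection$atom)
  n <- length(models)
  co <- array(NA_real_, dim = c(n, selection$M, 3L))
  for (i in seq_len(n)) {
    a <- models[[i]]
    key <- paste(a$chain, a$resno, a$name)
    pos <- match(want, key)
    if (anyNA(pos))
      stopf("frame %d is missing selected atom %s", i, want[which(is.na(pos))[1]])
    co[i, , ] <- as.matrix(a[pos, c("x", "y", "z")])
  }
  co
}

#' Write a trajectory to disk
#'
#' @param traj A `gm_trajectory`.
#' @param file Output path.
#' @param format `"mat"` (frame-matrix text, default) or `"pdb"` (multi-model).
#' @export
write_trajectory <- function(traj, file, format = c("mat", "pdb")) {
  format <- match.arg(format)
  n <- n_frames(traj); M <- traj$selection$M
  if (format == "mat") {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("FRAMES %d ATOMS %d", n, M), con)
    for (i in seq_len(n)) {
      fr <- traj$coords[i, , , drop = TRUE]
      writeLines(sprintf("%.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), con)
    }
  } else {
    s <- traj$selection
    base <- data.frame(name = s$atom, element = "C", resid = s$resid,
                       chain = s$chain, resno = s$resno, insert = s$insert,
                       x = 0, y = 0, z = 0, het = FALSE,
                       stringsAsFactors = FALSE)
    out <- character(0)
    for (i in seq_len(n)) {
      base$x <- traj$coords[i, , 1]
      base$y <- traj$coords[i, , 2]
      base$z <- traj$coords[i, , 3]
      out <- c(out, sprintf("MODEL %8d", i), format_atom_lines(base), "ENDMDL")
    }
    writeLines(c(out, "END"), file)
  }
  invisible(file)
}

#' Subset a trajectory by frames and/or atoms
#' @param traj A `gm_trajectory`.
#' @param frames Frame indices (default all).
#' @param atoms Atom indices into the selection (default all).
#' @export
subset_trajectory <- function(traj, frames = NULL, atoms = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (is.null(atoms)) atoms <- seq_len(traj$selection$M)
  sel <- traj$selection
  sub_sel <- structure(list(index = sel$index[atoms], chain = sel$chain[atoms],
                            resno = sel$resno[atoms],
                            insert = sel$insert[atoms], atom = sel$atom[atoms],
                            resid = sel$resid[atoms], M = length(atoms)),
                       class = "gm_selection")
  trajectory_from_coords(traj$coords[frames, atoms, , drop = FALSE], sub_sel,
                         times = traj$times[frames],
                         subunits = traj$subunits[atoms])
}
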