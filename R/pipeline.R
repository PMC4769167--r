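# Orchestration of the full two-condition gate-motion analysis:
# read -> align -> split -> modes -> counts -> compare, from a single
# configuration, with a structured, reproducible report.

#' Analysis configuration
#'
#' Defaults are the standard study parameters: top 20 modes, deformation
#' RMSD 3.5 A, opening threshold 1.5 A, first 50 ns discarded, three time
#' blocks per subunit, both deformation signs counted.
#'
#' @param structure_a,structure_b Reference structure paths (condition A/B).
#' @param trajectory_a,trajectory_b Trajectory paths.
#' @param pairs List of `gm_gate_pair`.
#' @param chains Chains to select (default all).
#' @param resno Residue numbers to select (default all).
#' @param k_max Modes kept per segment (default 20).
#' @param mode_select `"count"` (use `k_max` modes) or `"variance"` (use the
#'   smallest k reaching `variance_target`, capped at `k_max`).
#' @param variance_target Variance fraction for `mode_select = "variance"`
#'   (default 0.75).
#' @param target_rmsd Deformation RMSD (A, default 3.5).
#' @param threshold Opening threshold (A, default 1.5).
#' @param discard_ns Discarded initial interval (ns, default 50).
#' @param n_blocks Time blocks (default 3).
#' @param sign_policy `"both"`, `"plus"` or `"minus"` (default `"both"`).
#' @param scope `"segment"` (per-subunit, per-block PCA; default) or
#'   `"whole"` (per-subunit PCA of the whole post-discard trajectory, one
#'   count per subunit).
#' @param frame_dt_ns Frame spacing used when a trajectory file carries no
#'   times (default 1).
#' @param seed Seed recorded in the report (the analysis itself is
#'   deterministic).
#' @return A `gm_config` list.
#' @export
analysis_config <- function(structure_a = NULL, structure_b = NULL,
                            trajectory_a = NULL, trajectory_b = NULL,
                            pairs = list(), chains = NULL, resno = NULL,
                            k_max = 20L,
                            mode_select = c("count", "variance"),
                            variance_target = 0.75,
                            target_rmsd = 3.5, threshold = 1.5,
                            discard_ns = 50, n_blocks = 3L,
                            sign_policy = "both",
                            scope = c("segment", "whole"),
                            frame_dt_ns = 1, seed = 1L) {
  structure(list(structure_a = structure_a, structure_b = structure_b,
                 trajectory_a = trajectory_a, trajectory_b = trajectory_b,
                 pairs = pairs, chains = chains, resno = resno,
                 k_max = as.integer(k_max),
                 mode_select = match.arg(mode_select),
                 variance_target = variance_target,
                 target_rmsd = target_rmsd, threshold = threshold,
                 discard_ns = discard_ns, n_blocks = as.integer(n_blocks),
                 sign_policy = sign_policy, scope = match.arg(scope),
                 frame_dt_ns = frame_dt_ns, seed = as.integer(seed)),
            class = "gm_config")
}

#' Write / read a configuration as a plain-text key = value file
#'
#' Round-trips losslessly. Gate pairs are encoded one per line as
#' `pair = label res_a res_b [chain]`.
#'
#' @param config A `gm_config`.
#' @param file Path.
#' @export
write_config <- function(config, file) {
  enc <- function(v) if (is.null(v)) "NULL" else paste(v, collapse = ",")
  keys <- setdiff(names(config), "pairs")
  lines <- vapply(keys, function(k) sprintf("%s = %s", k, enc(config[[k]])),
                  character(1))
  plines <- vapply(config$pairs, function(p)
    sprintf("pair = %s %s %s%s", p$label, p$res_a, p$res_b,
            if (is.null(p$chain)) "" else paste0(" ", p$chain)),
    character(1))
  writeLines(c("# gatemodes analysis configuration", lines, plines), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  lines <- grep("^\\s*(#|$)", readLines(file, warn = FALSE),
                value = TRUE, invert = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([a-z_]+)\\s*=\\s*(.*?)\\s*$", lines))
  cfg <- analysis_config()
  numeric_keys <- c("k_max", "variance_target", "target_rmsd", "threshold",
                    "discard_ns", "n_blocks", "frame_dt_ns", "seed")
  pairs <- list()
  for (m in kv) {
    if (length(m) != 3L) next
    key <- m[2]; val <- m[3]
    if (key == "pair") {
      parts <- strsplit(val, "\\s+")[[1]]
      pairs[[length(pairs) + 1L]] <-
        gate_pair(as.integer(parts[2]), as.integer(parts[3]),
                  label = parts[1],
                  chain = if (length(parts) >= 4) parts[4] else NULL)
    } else if (val == "NULL") {
      cfg[key] <- list(NULL)
    } else if (key %in% numeric_keys) {
      cfg[[key]] <- as.numeric(strsplit(val, ",")[[1]])
    } else {
      cfg[[key]] <- strsplit(val, ",")[[1]]
    }
  }
  cfg$k_max <- as.integer(cfg$k_max); cfg$n_blocks <- as.integer(cfg$n_blocks)
  cfg$seed <- as.integer(cfg$seed)
  cfg$pairs <- pairs
  cfg
}

#' Per-segment opening counts for one condition
#'
#' Core analysis for one trajectory: split into (subunit x block) segments,
#' align each segment to its mean, extract collective modes, deform the
#' reference subunit structure along each mode to the target RMSD, and count
#' the modes opening each gate pair.
#'
#' @param traj A `gm_trajectory` (dimer, both subunits).
#' @param reference A `gm_structure` providing the reference conformation
#'   X0 (matched to the trajectory selection by chain/resno/atom).
#' @param pairs List of `gm_gate_pair` (chain-relative residue numbers).
#' @param config A `gm_config` (only the analysis parameters are used).
#' @return List with `counts` (segments x pairs matrix), `segments`
#'   (per-segment detail: k used, variance fraction), `count_list`.
#' @export
condition_counts <- function(traj, reference, pairs, config = analysis_config()) {
  if (config$scope == "segment") {
    plan <- segment_plan(traj, discard_ns = config$discard_ns,
                         n_blocks = config$n_blocks)
    segs <- split_segments(traj, plan)
  } else {
    keep <- which(traj$times >= config$discard_ns)
    if (length(keep) < 2L) stopf("discard leaves fewer than 2 frames")
    segs <- list()
    for (su in unique(traj$subunits)) {
      segs[[paste0(su, ".whole")]] <-
        subset_trajectory(traj, frames = keep,
                          atoms = which(traj$subunits == su))
    }
  }
  ref_all <- coords_for_selection(reference, traj$selection)
  count_list <- list()
  detail <- list()
  for (nm in names(segs)) {
    seg <- segs[[nm]]
    seg <- align_trajectory(seg, "mean")
    cv <- covariance_model(seg)
    modes <- eigenmodes(cv, k_max = config$k_max, provenance = nm)
    k_use <- if (config$mode_select == "variance")
      n_modes_for_variance(modes, cv, config$variance_target) else modes$k_max
    modes_use <- modes
    modes_use$values <- modes$values[seq_len(k_use)]
    modes_use$vectors <- modes$vectors[, seq_len(k_use), drop = FALSE]
    modes_use$k_max <- k_use
    spec <- deformation_spec(seg$selection$M, target_rmsd = config$target_rmsd,
                             sign_policy = config$sign_policy)
    # reference coordinates for this segment's atoms
    atom_idx <- match(paste(seg$selection$chain, seg$selection$resno,
                            seg$selection$atom),
                      paste(traj$selection$chain, traj$selection$resno,
                            traj$selection$atom))
    x0 <- ref_all[atom_idx, , drop = FALSE]
    count_list[[nm]] <- count_opening_modes(
      modes_use, x0, pairs, spec, threshold = config$threshold,
      selection = seg$selection, segment_id = nm)
    detail[[nm]] <- data.frame(
      segment = nm, n_frames = n_frames(seg), k_used = k_use,
      variance_fraction = variance_fraction(modes, cv, k_use),
      stringsAsFactors = FALSE)
  }
  list(counts = segment_count_table(count_list),
       segments = do.call(rbind, c(detail, list(make.row.names = FALSE))),
       count_list = count_list)
}

# reference coordinates matched to a trajectory selection
coords_for_selection <- function(reference, selection) {
  at <- reference$atoms
  key_ref <- paste(at$chain, at$resno, at$name)
  key_sel <- paste(selection$chain, selection$resno, selection$atom)
  pos <- match(key_sel, key_ref)
  if (anyNA(pos))
    stopf("reference structure is missing selected atom %s",
          key_sel[which(is.na(pos))[1]])
  unname(as.matrix(at[pos, c("x", "y", "z")]))
}

#' Run the full two-condition gate-motion analysis
#'
#' Executes read -> align -> split -> modes -> counts -> compare for two
#' conditions and returns a structured report with every intermediate
#' parameter, per-segment mode counts (so box plots can be reproduced from
#' the report alone), per-pair exact rank-sum tests, and provenance (input
#' digests + seed). Identical configurations yield identical reports.
#'
#' @param config A `gm_config` with file paths set, or the result of
#'   [study_inputs()] for in-memory inputs.
#' @return A `gm_report`.
#' @export
run_pipeline <- function(config) {
  inputs <- if (inherits(config, "gm_study_inputs")) config else {
    for (f in c("structure_a", "structure_b", "trajectory_a", "trajectory_b"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stopf("config %s: file not found (%s)", f,
              if (is.null(config[[f]])) "NULL" else config[[f]])
    ref_a <- read_structure(config$structure_a)
    ref_b <- read_structure(config$structure_b)
    sel_a <- select_atoms(ref_a, chains = config$chains, resno = config$resno)
    sel_b <- select_atoms(ref_b, chains = config$chains, resno = config$resno)
    list(config = config,
         reference_a = ref_a, reference_b = ref_b,
         trajectory_a = read_trajectory(config$trajectory_a, sel_a,
                                        times = config$frame_dt_ns),
         trajectory_b = read_trajectory(config$trajectory_b, sel_b,
                                        times = config$frame_dt_ns),
         digests = tryCatch(tools::md5sum(c(
           a_structure = config$structure_a, b_structure = config$structure_b,
           a_trajectory = config$trajectory_a,
           b_trajectory = config$trajectory_b)), error = function(e) NULL))
  }
  cfg <- inputs$config
  if (length(cfg$pairs) == 0L) stopf("config has no gate pairs")
  res_a <- with_stage("condition A", condition_counts(
    inputs$trajectory_a, inputs$reference_a, cfg$pairs, cfg))
  res_b <- with_stage("condition B", condition_counts(
    inputs$trajectory_b, inputs$reference_b, cfg$pairs, cfg))
  cmp <- with_stage("compare", compare_conditions(res_a$counts, res_b$counts))
  structure(list(config = cfg,
                 counts_a = res_a$counts, counts_b = res_b$counts,
                 segments_a = res_a$segments, segments_b = res_b$segments,
                 tests = cmp$table, summary = cmp$summary,
                 provenance = list(digests = inputs$digests,
                                   seed = cfg$seed,
                                   package_version = as.character(
                                     utils::packageVersion("gatemodes")))),
            class = "gm_report")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage [%s] failed: %s", stage, conditionMessage(e)))
}

#' Bundle in-memory study inputs for [run_pipeline()]
#'
#' @param trajectory_a,trajectory_b `gm_trajectory` objects.
#' @param reference_a,reference_b `gm_structure` objects.
#' @param config A `gm_config` (paths ignored).
#' @export
study_inputs <- function(trajectory_a, trajectory_b, reference_a,
                         reference_b, config) {
  structure(list(config = config, trajectory_a = trajectory_a,
                 trajectory_b = trajectory_b, reference_a = reference_a,
                 reference_b = reference_b, digests = NULL),
            class = "gm_study_inputs")
}

#' @export
print.gm_report <- function(x, ...) {
  cat("<gm_report> gate-opening mode analysis\n")
  cat(sprintf("  scope %s, k_max %d (%s), RMSD %.2f A, threshold %.2f A\n",
              x$config$scope, x$config$k_max, x$config$mode_select,
              x$config$target_rmsd, x$config$threshold))
  cat("  counts A:\n"); print(x$counts_a)
  cat("  counts B:\n"); print(x$counts_b)
  cat("  tests:\n"); print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Write a report as tab-separated tables plus a manifest
#'
#' @param report A `gm_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cbind(segment = rownames(report$counts_a),
           as.data.frame(report$counts_a)), "counts_a.tsv")
  wt(cbind(segment = rownames(report$counts_b),
           as.data.frame(report$counts_b)), "counts_b.tsv")
  wt(report$tests, "tests.tsv")
  wt(report$summary, "summary.tsv")
  wt(rbind(report$segments_a, report$segments_b), "segments.tsv")
  manifest <- c(sprintf("seed = %d", report$provenance$seed),
                sprintf("package_version = %s",
                        report$provenance$package_version),
                if (!is.null(report$provenance$digests))
                  sprintf("md5 %s = %s", names(report$provenance$digests),
                          report$provenance$digests))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
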