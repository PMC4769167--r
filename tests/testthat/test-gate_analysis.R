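test_that("deformation hits the target RMSD exactly for unit modes", {
  # M = 1: a single atom moves exactly target_rmsd along the mode
  spec1 <- deformation_spec(1, target_rmsd = 3.5)
  x0 <- matrix(0, 1, 3)
  x1 <- deform(x0, c(1, 0, 0), spec1, 1)
  expect_equal(as.numeric(x1), c(3.5, 0, 0))

  # A = target * sqrt(M); the study constants give A = 3.5 * sqrt(538) = 81.18
  spec538 <- deformation_spec(538, target_rmsd = 3.5)
  expect_equal(spec538$A, 3.5 * sqrt(538))
  expect_equal(round(spec538$A, 2), 81.18)

  # identity over 100 random unit modes at M = 538
  set.seed(42)
  x0 <- matrix(rnorm(538 * 3), 538, 3)
  for (i in 1:100) {
    u <- random_unit_mode(538)
    sgn <- sample(c(-1, 1), 1)
    expect_equal(rmsd_coords(x0, deform(x0, u, spec538, sgn)), 3.5,
                 tolerance = 1e-9)
  }

  # A = 0 leaves the structure unchanged
  spec0 <- deformation_spec(4, target_rmsd = 1)
  spec0$A <- 0
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(deform(x, random_unit_mode(4), spec0, 1), x)

  # non-unit modes and M mismatches are rejected
  expect_error(deform(x, rnorm(12), deformation_spec(4)), "unit")
  expect_error(deform(x, random_unit_mode(5), deformation_spec(5)), "atoms")
})

test_that("delta_r measures signed pair-distance change", {
  s <- structure_from_coords(rbind(c(0, 0, 0), c(3, 0, 0)))
  sel <- select_atoms(s)
  pair <- gate_pair(1, 2)
  x0 <- coords(s)
  expect_equal(delta_r(x0, x0, pair, sel), 0)
  x1 <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(delta_r(x0, x1, pair, sel), 2.0)
  x2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(delta_r(x0, x2, pair, sel), -2.0)
  expect_error(delta_r(x0, x1, gate_pair(1, 9), sel), "not found")
})

test_that("a two-atom separation mode gives the closed-form delta_r", {
  # mode moves the pair atoms apart along their axis by d each at amplitude A
  s <- toy_chain(6)
  sel <- select_atoms(s)
  x0 <- coords(s)
  u <- numeric(18)
  d <- 1 / sqrt(2)                        # unit mode: all norm on the pair
  u[3 * (1 - 1) + 3] <- -d                # atom 1, z component
  u[3 * (4 - 1) + 3] <- +d                # atom 4
  spec <- deformation_spec(6, target_rmsd = 2)
  x1 <- deform(x0, u, spec, 1)
  expect_equal(delta_r(x0, x1, gate_pair(1, 4), sel), 2 * spec$A * d,
               tolerance = 1e-9)
})

test_that("opening-mode counts obey the threshold and sign-policy laws", {
  s <- toy_chain(6)
  sel <- select_atoms(s)
  x0 <- coords(s)
  u <- numeric(18); u[3] <- -1 / sqrt(2); u[12] <- 1 / sqrt(2)
  modes <- structure(list(values = c(2, 1), vectors = cbind(u, c(
    rep(0, 16), 1, 0)), k_max = 2L, all_values = c(2, 1)),
    class = "gm_modes")
  pairs <- list(gate_pair(1, 4, label = "p14"), gate_pair(2, 5, label = "p25"))
  spec <- deformation_spec(6, target_rmsd = 2)

  counts <- count_opening_modes(modes, x0, pairs, spec, threshold = 1.5,
                                selection = sel)
  expect_equal(counts$count[counts$pair == "p14"], 1L)
  expect_equal(counts$count[counts$pair == "p25"], 0L)

  # threshold = +Inf kills all counts; monotone nonincreasing in threshold
  cts <- vapply(c(0.5, 1.5, 3, Inf), function(th)
    count_opening_modes(modes, x0, pairs, spec, threshold = th,
                        selection = sel)$count[1], integer(1))
  expect_true(all(diff(cts) <= 0))
  expect_equal(cts[length(cts)], 0L)

  # sign-policy dominance: both >= plus, both >= minus (per pair)
  set.seed(8)
  M <- 20
  x0r <- matrix(rnorm(3 * M, sd = 4), M, 3)
  selr <- select_atoms(structure_from_coords(x0r))
  vec <- qr.Q(qr(matrix(rnorm(3 * M * 5), 3 * M, 5)))
  modesr <- structure(list(values = 5:1, vectors = vec, k_max = 5L,
                           all_values = 5:1), class = "gm_modes")
  pr <- list(gate_pair(2, 11), gate_pair(5, 17))
  for (th in c(0.5, 1.5)) {
    n_both <- count_opening_modes(modesr, x0r, pr,
      deformation_spec(M, sign_policy = "both"), th, selr)$count
    n_plus <- count_opening_modes(modesr, x0r, pr,
      deformation_spec(M, sign_policy = "plus"), th, selr)$count
    n_minus <- count_opening_modes(modesr, x0r, pr,
      deformation_spec(M, sign_policy = "minus"), th, selr)$count
    expect_true(all(n_both >= n_plus))
    expect_true(all(n_both >= n_minus))
  }

  expect_error(count_opening_modes(modesr, x0r, list(),
                                   deformation_spec(M), 1.5, selr), "empty")
})

test_that("counts are invariant to consistently rotated input", {
  set.seed(13)
  M <- 15
  x0 <- matrix(rnorm(3 * M, sd = 5), M, 3)
  sel <- select_atoms(structure_from_coords(x0))
  vec <- qr.Q(qr(matrix(rnorm(3 * M * 4), 3 * M, 4)))
  modes <- structure(list(values = 4:1, vectors = vec, k_max = 4L,
                          all_values = 4:1), class = "gm_modes")
  pairs <- list(gate_pair(1, 8), gate_pair(4, 12))
  spec <- deformation_spec(M)
  base <- count_opening_modes(modes, x0, pairs, spec, 1.0, sel)$count

  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- gatemodes:::rotation_matrix(ax, 1.1)
  x0r <- x0 %*% R
  vecr <- apply(vec, 2, function(v) as.vector(t(matrix(v, ncol = 3,
                                                       byrow = TRUE) %*% R)))
  modesr <- modes; modesr$vectors <- vecr
  rot <- count_opening_modes(modesr, x0r, pairs, spec, 1.0, sel)$count
  expect_equal(base, rot)
})

test_that("counts are invariant to mode sign flips", {
  model <- default_planted_model(n_per_subunit = 30L, seed = 6)
  traj <- sample_trajectory(model, 300, seed = 6)
  idxA <- which(traj$subunits == "A")
  seg <- align_trajectory(subset_trajectory(traj, atoms = idxA), "mean")
  cv <- covariance_model(seg)
  ms <- eigenmodes(cv, k_max = 5)
  x0 <- coords(model$template)[idxA, ]
  spec <- deformation_spec(length(idxA))
  pairs <- list(model$gate_pairs$target, model$gate_pairs$control)
  base <- count_opening_modes(ms, x0, pairs, spec, 1.5, seg$selection)$count
  set.seed(99)
  for (rep in 1:3) {
    flip <- sample(c(-1, 1), ms$k_max, replace = TRUE)
    msf <- ms; msf$vectors <- sweep(ms$vectors, 2, flip, `*`)
    expect_equal(count_opening_modes(msf, x0, pairs, spec, 1.5,
                                     seg$selection)$count, base)
  }
})
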