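test_that("dimer template is deterministic, C2-symmetric and well labeled", {
  t1 <- make_dimer_template(n_per_subunit = 10L, seed = 1)
  t2 <- make_dimer_template(n_per_subunit = 10L, seed = 1)
  expect_identical(coords(t1), coords(t2))
  expect_equal(nrow(t1$atoms), 20L)
  expect_equal(unique(t1$atoms$chain), c("A", "B"))
  expect_equal(t1$atoms$resno[t1$atoms$chain == "B"], 1:10)

  # chain B is the exact 180-degree rotation of chain A about z
  a <- coords(t1)[1:10, ]; b <- coords(t1)[11:20, ]
  expect_lt(max(abs(b - a %*% diag(c(-1, -1, 1)))), 1e-12)

  # subunit centroids sit exactly dimer_sep apart
  t3 <- make_dimer_template(n_per_subunit = 16L, dimer_sep = 30, seed = 2)
  ca <- colMeans(coords(t3)[1:16, ]); cb <- colMeans(coords(t3)[17:32, ])
  expect_equal(sqrt(sum((ca - cb)^2)), 30, tolerance = 1e-9)
  # mirrored-pair distance follows the placement formula: 2 * in-plane radius
  xyz <- coords(t3)
  for (i in c(1, 7, 16)) {
    expected <- 2 * sqrt(sum(xyz[i, 1:2]^2))
    expect_equal(sqrt(sum((xyz[i, ] - xyz[16 + i, ])^2)), expected,
                 tolerance = 1e-9)
  }

  expect_error(make_dimer_template(3L), "at least 4")
  expect_false(identical(coords(make_dimer_template(10L, seed = 5)),
                         coords(t1)))
})

test_that("planted gate mode opens its pair, stays local, and is orthonormal", {
  template <- make_dimer_template(seed = 1)
  pair <- gate_pair(12, 37, label = "target", chain = "A")
  protect <- list("A:3:CA", "A:28:CA")
  u <- plant_gate_mode(template, pair, protect = protect, seed = 2)
  M <- nrow(template$atoms)
  expect_length(u, 3 * M)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-9)

  sel <- select_atoms(template)
  x0 <- coords(template)
  spec <- deformation_spec(M, target_rmsd = 10 / sqrt(M))  # A = 10
  x1 <- deform(x0, u, spec, 1)
  dr_target <- delta_r(x0, x1, pair, sel)
  expect_gt(dr_target, 0)
  # protected (control) pair does not move at all
  dr_ctrl <- abs(delta_r(x0, x1, gate_pair(3, 28, chain = "A"), sel))
  expect_lt(dr_ctrl, 0.1 * dr_target)
  expect_lt(dr_ctrl, 1e-9)

  # orthogonalised against previously planted modes
  u2 <- plant_gate_mode(template, gate_pair(5, 30, chain = "A"),
                        prev_modes = cbind(u), seed = 3)
  expect_lt(abs(sum(u * u2)), 1e-9)

  expect_error(plant_gate_mode(template, pair, support = c(1, 2, 3)),
               "support")
})

test_that("planted model validates its invariants", {
  model <- default_planted_model(seed = 1)
  gram <- crossprod(model$modes)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-9)
  expect_true(all(model$amplitudes > 0))
  # modes carry no rigid-body component of their own subunit
  xyz <- coords(model$template)
  for (ch in c("A", "B")) {
    idx <- which(model$template$atoms$chain == ch)
    g <- gatemodes:::rigid_generators(xyz, idx)
    ov <- crossprod(g, model$modes)
    expect_lt(max(abs(ov)), 1e-8)
  }
  expect_error(planted_model(model$template, model$modes[, 1:2],
                             c(1, -1)), "positive")
  expect_error(planted_model(model$template,
                             cbind(model$modes[, 1], model$modes[, 1]),
                             c(1, 1)), "orthonormal")
})

test_that("trajectory sampling is reproducible and respects trivial limits", {
  model <- default_planted_model(n_per_subunit = 30L, seed = 4)
  t1 <- sample_trajectory(model, 10, seed = 5)
  t2 <- sample_trajectory(model, 10, seed = 5)
  expect_identical(t1$coords, t2$coords)
  t3 <- sample_trajectory(model, 10, seed = 6)
  expect_false(identical(t1$coords, t3$coords))

  # all amplitudes ~0, no noise, no jitter -> every frame is the template
  still <- model
  still$amplitudes[] <- 1e-300
  still$sigma <- 0
  still$jitter <- list(max_rot_deg = 0, max_trans = 0)
  ts <- sample_trajectory(still, 3, seed = 1)
  for (i in 1:3)
    expect_lt(max(abs(ts$coords[i, , ] - coords(model$template))), 1e-12)

  expect_error(sample_trajectory(model, 1), "at least 2")
})

test_that("dampening scales amplitudes and recovered eigenvalues", {
  model <- default_planted_model(seed = 7)
  expect_identical(dampen(model, "gate", 1)$amplitudes, model$amplitudes)
  d3 <- dampen(model, "gate", 1 / 3)
  expect_equal(unname(d3$amplitudes[c("gate.A", "gate.B")]),
               unname(model$amplitudes[c("gate.A", "gate.B")] / 3))
  expect_identical(d3$amplitudes[-grep("^gate", names(d3$amplitudes))],
                   model$amplitudes[-grep("^gate", names(model$amplitudes))])
  expect_error(dampen(model, "gate", 0), "factor")
  expect_error(dampen(model, "nosuch", 0.5), "no such")

  # the gate eigenvalue in recovered spectra scales by ~ 1/9
  recover_gate_lambda <- function(m) {
    tr <- sample_trajectory(m, 4000, seed = 8)
    idxA <- which(tr$subunits == "A")
    seg <- align_trajectory(subset_trajectory(tr, atoms = idxA), "mean")
    ms <- eigenmodes(covariance_model(seg), k_max = 6)
    rows <- as.vector(vapply(idxA, function(i) 3L * (i - 1L) + 1:3,
                             integer(3)))
    gate <- m$modes[rows, "gate.A"]
    # eigenvalue of the recovered mode best aligned with the planted gate
    align <- abs(crossprod(ms$vectors, gate))
    ms$values[which.max(align)]
  }
  lam_full <- recover_gate_lambda(model)
  lam_damp <- recover_gate_lambda(d3)
  expect_equal(lam_damp / lam_full, 1 / 9, tolerance = 0.15)
})
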