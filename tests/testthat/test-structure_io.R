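test_that("PDB parsing reads fixed columns, altlocs and models correctly", {
  s <- read_structure(toy_pdb_two_atoms())
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(pair_distance(s, "A:1:CA", "A:2:CA"), 8.8)

  # altloc: keep blank and 'A', drop others
  txt <- paste(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       0.000   2.000   0.000  1.00  0.00           C",
    sep = "\n")
  s2 <- read_structure(txt)
  expect_equal(nrow(s2$atoms), 2L)
  expect_equal(s2$atoms$x[1], 1.0)

  # multi-model: read_structure takes the first model only
  multi <- paste("MODEL 1", toy_pdb_two_atoms(), "ENDMDL",
                 "MODEL 2",
                 "ATOM      1  CA  GLY A   1       5.000   0.000   0.000  1.00  0.00           C",
                 "ATOM      2  CA  GLY A   2       5.000   0.000   8.800  1.00  0.00           C",
                 "ENDMDL", sep = "\n")
  sm <- read_structure(multi)
  expect_equal(sm$atoms$x[1], 0.0)
  expect_equal(read_structure(multi, model = 2)$atoms$x[1], 5.0)

  # HETATM element inference and het flag
  het <- paste(toy_pdb_two_atoms(),
    "HETATM    3 CL    CL A 501       1.000   1.000   4.000  1.00  0.00",
    sep = "\n")
  sh <- read_structure(het)
  expect_true(sh$atoms$het[3])
  expect_equal(sh$atoms$element[3], "CL")
})

test_that("malformed and empty PDB input raise informative errors", {
  bad <- paste(toy_pdb_two_atoms(),
               "ATOM      3  CA  GLY A   3      bad.00   0.000   0.000",
               sep = "\n")
  expect_error(read_structure(bad), "line 3")
  expect_error(read_structure("REMARK nothing here"), "empty structure")
})

test_that("selection is ordered, deterministic, and validates atoms", {
  s <- toy_chain(10)
  sel <- select_atoms(s, resno = 1:10)
  expect_equal(sel$M, 10L)
  expect_equal(sel$resno, 1:10)

  expect_error(select_atoms(s, resno = 999), "zero atoms")
  # residue present but lacking the requested atom name
  s$atoms$name[5] <- "CB"
  expect_error(select_atoms(s, resno = 1:10), "lacking atom CA")
  expect_error(select_atoms(s, resno = 1:10, atoms = "CB"), "lacking atom CB")

  # output order invariant to atom order in the file
  sperm <- s
  sperm$atoms <- sperm$atoms[sample(nrow(sperm$atoms)), ]
  s$atoms$name[5] <- "CA"; sperm$atoms$name[sperm$atoms$resno == 5] <- "CA"
  a <- select_atoms(s, resno = 1:10)
  b <- select_atoms(sperm, resno = 1:10)
  expect_equal(a$resno, b$resno)
  expect_equal(coords(s, a), coords(sperm, b))
})

test_that("two-atom toy selection matches requested gate residues", {
  s <- toy_chain(500)
  sel <- select_atoms(s, resno = c(148, 445))
  expect_equal(sel$M, 2L)
  sel10 <- select_atoms(toy_chain(10), resno = 1:10)
  expect_equal(sel10$M, 10L)
})

test_that("trajectory IO round-trips to the format's stated precision", {
  model <- default_planted_model(n_per_subunit = 30L, seed = 7)
  traj <- sample_trajectory(model, n_frames = 5, seed = 7)
  # frame-matrix carries 6 decimals, PDB fixed columns carry 3
  precision <- c(mat = 1e-6, pdb = 5e-4 + 1e-12)
  for (fmt in names(precision)) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trajectory(traj, f, format = fmt)
    back <- read_trajectory(f, traj$selection)
    expect_lte(max(abs(back$coords - traj$coords)), precision[[fmt]])
  }
  # a second write/read cycle is the identity (no drift)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trajectory(traj, f1, format = "mat")
  t1 <- read_trajectory(f1, traj$selection)
  write_trajectory(t1, f2, format = "mat")
  t2 <- read_trajectory(f2, traj$selection)
  expect_identical(t1$coords, t2$coords)
})

test_that("frame-matrix and multi-model PDB readers validate their input", {
  model <- default_planted_model(n_per_subunit = 30L, seed = 7)
  traj <- sample_trajectory(model, n_frames = 3, seed = 7)
  # 3-model PDB of a 2-atom system
  s <- toy_chain(2)
  sel <- select_atoms(s)
  small <- trajectory_from_coords(array(rnorm(3 * 2 * 3), c(3, 2, 3)), sel)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(small, f, format = "pdb")
  expect_equal(n_frames(read_trajectory(f, sel)), 3L)

  # frame-matrix: 5 blocks x 4 atoms
  s4 <- toy_chain(4)
  sel4 <- select_atoms(s4)
  t4 <- trajectory_from_coords(array(rnorm(5 * 4 * 3), c(5, 4, 3)), sel4)
  f2 <- withr::local_tempfile(fileext = ".mat")
  write_trajectory(t4, f2)
  r4 <- read_trajectory(f2, sel4)
  expect_equal(n_frames(r4), 5L)
  expect_equal(r4$selection$M, 4L)
  # selection/file M mismatch
  expect_error(read_trajectory(f2, sel), "M = ")

  # multi-model PDB with an atom missing from one frame
  lines <- readLines(f)
  drop <- grep("CA  ALA A   2", lines)[2]
  writeLines(lines[-drop], f)
  expect_error(read_trajectory(f, sel), "frame 2 is missing selected atom")
})

test_that("structure writer round-trips and bio3d can read our PDB output", {
  skip_if_not_installed("bio3d")
  s <- make_dimer_template(n_per_subunit = 10L, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  back <- read_structure(f)
  expect_lt(max(abs(coords(back) - coords(s))), 1e-3 + 1e-9)
  pdb <- bio3d::read.pdb(f)
  ca <- pdb$atom[pdb$atom$elety == "CA", c("x", "y", "z")]
  expect_lt(max(abs(as.matrix(ca) - coords(s))), 1e-3 + 1e-9)
  expect_equal(sort(unique(pdb$atom$chain)), c("A", "B"))
})
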