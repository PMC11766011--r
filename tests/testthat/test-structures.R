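# structures_io: PDB round trips, toy builder geometry, Kabsch superposition.

test_that("read_pdb parses minimal files and rejects malformed ones", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00"), p)
  s <- read_pdb(p)
  expect_s3_class(s, "vsd_structure")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$residue_name, c("ALA", "GLY"))
  expect_equal(s$atoms$x, c(1, 4))

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A   1         abc   2.000   3.000", bad)
  expect_error(read_pdb(bad), "line 1")

  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_pdb(empty), "empty")
  expect_error(read_pdb("no/such/file.pdb"), "not found")
})

test_that("write/read round trip preserves atoms to PDB column precision", {
  s <- build_toy_vsd(variant = "WT")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, p)
  s2 <- read_pdb(p)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$residue_name, s$atoms$residue_name)
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$y, s$atoms$y, tolerance = 1e-3)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-3)
})

test_that("multi-model files hold trajectories; empty structures are refused", {
  s <- build_toy_vsd(variant = "WT")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(list(s, s, s), p)
  models <- read_pdb(p)
  expect_length(models, 3)
  expect_equal(nrow(models[[2]]$atoms), nrow(s$atoms))

  one <- vsd_structure(data.frame(name = "CA", residue_name = "ALA",
                                  residue_index = 1L, chain = "A",
                                  x = 0, y = 0, z = 0))
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(one, p1)
  expect_equal(sum(startsWith(readLines(p1), "ATOM")), 1)
  expect_error(write_pdb(list(), p1), "non-empty")
})

test_that("toy builder produces ideal helix geometry", {
  s <- build_toy_vsd(variant = "WT")
  expect_setequal(names(s$helices), c("S1", "S2", "S3", "S4"))
  expect_gte(nrow(charged_sites(s)), 5)

  # consecutive CA chord length: closed form from rise 1.5, 100 deg, r 2.3
  for (ch in c("A", "B", "C", "D")) {
    ca <- s$atoms[s$atoms$chain == ch & s$atoms$name == "CA", ]
    ca <- ca[order(ca$residue_index), ]
    d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
    expect_true(all(abs(d - 3.80) < 0.05))
  }

  # S4 CA atoms within 2.4 A of the declared axis; rise exactly 1.5/residue
  hx <- s$helices$S4
  ca <- s$atoms[s$atoms$chain == hx$chain & s$atoms$name == "CA", ]
  ca <- ca[order(ca$residue_index), ]
  r_axial <- sqrt((ca$x - hx$axis_origin[1])^2 + (ca$y - hx$axis_origin[2])^2)
  expect_true(all(r_axial <= 2.4))
  expect_equal(diff(ca$z), rep(-1.5, nrow(ca) - 1), tolerance = 1e-6)
})

test_that("R1 -> Glu variant flips one charge without moving the backbone", {
  wt <- build_toy_vsd(variant = "WT")
  mut <- build_toy_vsd(variant = "R1E")
  wt_ca <- wt$atoms[wt$atoms$name == "CA", c("x", "y", "z")]
  mut_ca <- mut$atoms[mut$atoms$name == "CA", c("x", "y", "z")]
  expect_equal(mut_ca, wt_ca)
  cs_wt <- charged_sites(wt); cs_mut <- charged_sites(mut)
  expect_equal(nrow(cs_mut), nrow(cs_wt))
  expect_equal(sum(cs_mut$charge), sum(cs_wt$charge) - 2)
  expect_equal(cs_mut$charge[cs_mut$chain == "D" & cs_mut$residue_index == 3], -1)
})

test_that("builder rejects an S4 without the basic-residue lattice", {
  sp <- toy_vsd_specs("WT")
  sp$S4 <- helix_spec("AARAARAAAAAAAA", c(12, 12, 25.5), c(0, 0, -1), -20)
  expect_error(build_toy_vsd(sp), "i, i\\+3, i\\+6, i\\+9")
})

test_that("superpose recovers exact rigid transforms", {
  s <- build_toy_vsd(variant = "WT")
  sel <- atom_index(s, name = "CA")

  sp <- superpose(s, s, sel)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  shifted <- s; shifted$atoms$x <- shifted$atoms$x + 5
  sp <- superpose(shifted, s, sel)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(sp$translation, c(-5, 0, 0), tolerance = 1e-8)

  rot <- rotate_z(s, 30)
  sp <- superpose(rot, s, sel)
  expect_equal(sp$rmsd, 0, tolerance = 1e-6)
  ang <- acos((sum(diag(sp$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-6)

  expect_error(superpose(s, s, sel[1:2]), "3 paired")
  line <- vsd_structure(data.frame(name = "CA", residue_name = "ALA",
                                   residue_index = 1:4, chain = "A",
                                   x = 1:4, y = 0, z = 0))
  expect_error(superpose(line, line, 1:4), "collinear")
})

test_that("Kabsch rmsd is invariant under joint rigid transforms", {
  set.seed(11)
  a <- build_toy_vsd(variant = "WT")
  b <- a
  b$atoms$x <- b$atoms$x + stats::rnorm(nrow(b$atoms), 0, 0.4)
  b$atoms$y <- b$atoms$y + stats::rnorm(nrow(b$atoms), 0, 0.4)
  b$atoms$z <- b$atoms$z + stats::rnorm(nrow(b$atoms), 0, 0.4)
  sel <- atom_index(a, name = "CA")
  base <- superpose(a, b, sel)$rmsd
  for (i in 1:20) {
    R <- random_rotation(); tr <- stats::rnorm(3, 0, 20)
    expect_equal(superpose(transform_structure(a, R, tr),
                           transform_structure(b, R, tr), sel)$rmsd,
                 base, tolerance = 1e-8)
  }
})
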