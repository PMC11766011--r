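# Contact analysis: site extraction, salt-bridge classification, distance
# series, rotation sign conventions.

test_that("charged sites are counted and signed correctly", {
  s5 <- build_toy_vsd(minimal_vsd_specs("WT"))
  cs <- charged_sites(s5)
  expect_equal(nrow(cs), 5)        # 4 basics on S4 + one Glu on S2
  expect_equal(sum(cs$charge), 3)

  mut <- build_toy_vsd(minimal_vsd_specs("R1E"))
  cs_mut <- charged_sites(mut)
  expect_equal(nrow(cs_mut), 5)
  expect_equal(sum(cs_mut$charge), 1)

  bare <- vsd_structure(data.frame(name = "CA", residue_name = "ALA",
                                   residue_index = 1:5, chain = "A",
                                   x = 1:5, y = 0, z = 0))
  expect_equal(nrow(charged_sites(bare)), 0)
})

test_that("ionizable residues missing their site atom are skipped with warning", {
  s <- vsd_structure(data.frame(name = c("CA", "CA"),
                                residue_name = c("ARG", "GLU"),
                                residue_index = 1:2, chain = "A",
                                x = c(0, 5), y = 0, z = 0))
  w <- capture_warnings(cs <- charged_sites(s))
  expect_true(all(grepl("lacks its site atom", w)) && length(w) == 2)
  expect_equal(nrow(cs), 0)
})

test_that("salt_bridges classifies by charge sign and respects the cutoff", {
  mk <- function(d, types = c("ARG", "GLU")) {
    nm <- c(ARG = "CZ", LYS = "NZ", GLU = "CD", ASP = "CG")
    vsd_structure(data.frame(name = unname(nm[types]), residue_name = types,
                             residue_index = c(1L, 1L), chain = c("A", "B"),
                             x = c(0, d), y = 0, z = 0))
  }
  sb <- salt_bridges(mk(3.0))
  expect_equal(nrow(sb), 1)
  expect_equal(sb$kind, "salt_bridge")
  expect_equal(sb$distance, 3.0)

  expect_equal(nrow(salt_bridges(mk(4.6))), 0)

  rep_ <- salt_bridges(mk(3.0, c("ARG", "LYS")))
  expect_equal(rep_$kind, "repulsive_pair")
  expect_error(salt_bridges(mk(3), cutoff = 0), "cutoff")
})

test_that("bridge sets are nested in the cutoff and invariant to rigid moves", {
  s <- build_toy_vsd(variant = "WT")
  b3 <- salt_bridges(s, cutoff = 3.5)
  b6 <- salt_bridges(s, cutoff = 6)
  b12 <- salt_bridges(s, cutoff = 12)
  key <- function(b) paste(b$chain_a, b$res_a, b$chain_b, b$res_b)
  expect_true(all(key(b3) %in% key(b6)))
  expect_true(all(key(b6) %in% key(b12)))

  set.seed(5)
  moved <- transform_structure(s, random_rotation(), stats::rnorm(3, 0, 15))
  b_m <- salt_bridges(moved, cutoff = 12)
  expect_equal(key(b_m), key(b12))
  expect_equal(b_m$distance, b12$distance, tolerance = 1e-8)
})

test_that("bridge_distance_series tracks pairs across steps", {
  s <- build_toy_vsd(variant = "WT")
  static <- list(steps = lapply(0:4, function(i) {
    list(index = i, z_offset = -0.5 * i, structure = s)
  }))
  class(static) <- "vsd_trajectory"
  bs <- bridge_distance_series(static, "D:3", "B:9")
  expect_equal(nrow(bs), 5)
  expect_equal(bs$distance, rep(bs$distance[1], 5))
  expect_error(bridge_distance_series(static, "D:3", "A:1"), "no charged site")
})

test_that("rotation series sign convention: +5 deg steps are anticlockwise", {
  s <- build_toy_vsd(variant = "WT")
  center <- c(12, 12)
  spin <- function(sign) {
    steps <- lapply(0:6, function(i) {
      st <- rotate_z(s, sign * 5 * i, center)
      list(index = i, z_offset = 0, structure = st)
    })
    structure(list(steps = steps), class = "vsd_trajectory")
  }
  # the helix axis is estimated by PCA of the CA cloud and is ~0.2% tilted
  # from z for a 14-residue helix, so azimuths about it carry that factor
  up <- s4_rotation_series(spin(+1), "D:3")
  expect_equal(up$angle, 5 * (0:6), tolerance = 5e-3)
  down <- s4_rotation_series(spin(-1), "D:3")
  expect_equal(down$angle, -5 * (0:6), tolerance = 5e-3)

  slide <- list(steps = lapply(0:3, function(i) {
    st <- s; st$atoms$x <- st$atoms$x + i; st$atoms$z <- st$atoms$z - 0.5 * i
    list(index = i, z_offset = -0.5 * i, structure = st)
  }))
  class(slide) <- "vsd_trajectory"
  pure <- s4_rotation_series(slide, "D:3")
  expect_equal(pure$angle, rep(0, 4), tolerance = 1e-6)

  expect_error(s4_rotation_series(spin(1), "A:3"), "must lie on")
})
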