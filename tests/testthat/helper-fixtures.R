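# Shared fixtures. Trajectories are expensive (Monte-Carlo minimization at
# every downshift step), so the full WT / R1E runs are computed once per test
# session and reused by the property and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

toy_trajectory <- function(variant = c("WT", "R1E"), seed = 7) {
  variant <- match.arg(variant)
  key <- paste0("traj_", variant, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    s <- build_toy_vsd(variant = variant)
    .fixture_cache[[key]] <- deactivate_s4(s, config = mc_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# two free opposite unit charges represented by their site atoms
two_charge_structure <- function(d = 5, z = 0) {
  vsd_structure(data.frame(
    name = c("CZ", "CD"), residue_name = c("ARG", "GLU"),
    residue_index = c(1L, 1L), chain = c("A", "B"),
    x = c(0, d), y = c(0, 0), z = c(z, z)))
}

# minimal single-glutamate toy (the 5-site configuration used by the
# contact-analysis counting examples)
minimal_vsd_specs <- function(variant = c("WT", "R1E")) {
  variant <- match.arg(variant)
  sp <- toy_vsd_specs(variant)
  sp$S2 <- helix_spec("AAAAAAAAEAAAAA", c(0, 12, 0), c(0, 0, 1), phase = -800)
  sp$S3 <- helix_spec("AAAAAAAAAAAAAA", c(12, 0, 0), c(0, 0, 1), phase = -110)
  sp
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

transform_structure <- function(s, R, t) {
  X <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- X[, 1] + t[1]; s$atoms$y <- X[, 2] + t[2]; s$atoms$z <- X[, 3] + t[3]
  s
}

rotate_z <- function(s, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  dx <- s$atoms$x - center[1]; dy <- s$atoms$y - center[2]
  s$atoms$x <- center[1] + cos(th) * dx - sin(th) * dy
  s$atoms$y <- center[2] + sin(th) * dx + cos(th) * dy
  s
}
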