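# Steered S4 deactivation: stepped 0.5-A downshifts of the four basic-residue
# CA atoms (plane-constrained), flat-bottom restraints on S1-S3 CA atoms, and
# Monte-Carlo energy minimization at every step.

#' Steered deactivation of the S4 sliding helix
#'
#' Step `i` (i = 1..n_steps) translates S4 down by a cumulative `-step_size*i`
#' along z, constrains the four voltage-sensing CA atoms to their downshifted
#' plane (free in-plane motion, fixed z), re-minimizes the energy by Monte
#' Carlo, and records the minimized structure. Step 0 is the minimized
#' starting state (z-offset 0). S1-S3 CA atoms carry flat-bottom restraints to
#' their step-0 positions throughout (free up to `fb_radius`, harmonic
#' `fb_k*(d - fb_radius)^2` beyond).
#'
#' @param structure a `vsd_structure` with annotated helices S1-S4.
#' @param s4_ca integer row indices of the 4 S4 basic-residue CA atoms
#'   (default: located with [s4_basic_ca()]).
#' @param n_steps number of downshift steps (default 21: two helical turns at
#'   0.5 A, total 10.5 A).
#' @param step_size downshift per step, A.
#' @param model an [energy_model()].
#' @param config an [mc_config()]; its seed governs the whole trajectory.
#' @param fb_radius,fb_k flat-bottom restraint parameters for S1-S3 CAs.
#' @return Object of class `vsd_trajectory`: list with `steps` (each holding
#'   `index`, `z_offset`, `structure`, `energy`, `n_moves`) and `provenance`.
#' @export
deactivate_s4 <- function(structure, s4_ca = NULL, n_steps = 21, step_size = 0.5,
                          model = energy_model(), config = mc_config(seed = 1),
                          fb_radius = 4.0, fb_k = 10) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (is.null(s4_ca)) s4_ca <- s4_basic_ca(structure)
  if (length(s4_ca) != 4) stop("s4_ca must name exactly 4 CA atoms")
  hel <- atom_helix(structure)
  if (!all(hel[s4_ca] == "S4", na.rm = FALSE) || anyNA(hel[s4_ca])) {
    stop("the 4 constrained CA atoms must lie on the annotated S4 helix")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config; cfg$seed <- NULL   # one RNG stream across all steps

  a <- structure$atoms
  s1s3 <- which(hel %in% c("S1", "S2", "S3") & a$name == "CA")
  X_start <- coords(structure)
  fbs <- lapply(s1s3, function(i) {
    flat_bottom_restraint(i, X_start[i, ], free_radius = fb_radius, force_k = fb_k)
  })
  s4_rows <- which(hel == "S4")
  z0 <- X_start[s4_ca, 3]

  steps <- vector("list", n_steps + 1L)
  cur <- structure
  for (i in 0:n_steps) {
    if (i > 0) {
      X <- coords(cur)
      X[s4_rows, 3] <- X[s4_rows, 3] - step_size  # rigid downshift of S4
      coords(cur) <- X
    }
    target_z <- z0 - step_size * i
    restr <- c(list(plane_constraint(s4_ca, target_z)), fbs)
    fit <- mc_minimize(cur, model, restr, cfg)
    cur <- fit$structure
    steps[[i + 1L]] <- list(index = i, z_offset = -step_size * i,
                            structure = cur, energy = fit$energy,
                            n_moves = fit$n_moves)
  }
  structure(list(steps = steps,
                 provenance = list(model = model, config = config,
                                   n_steps = n_steps, step_size = step_size,
                                   s4_ca = s4_ca)),
            class = "vsd_trajectory")
}

#' @export
print.vsd_trajectory <- function(x, ...) {
  n <- length(x$steps)
  cat("<vsd_trajectory> ", n, " states (baseline + ", n - 1L,
      " downshifted), step ", x$provenance$step_size, " A\n", sep = "")
  invisible(x)
}

#' Number of downshifted MC-minimized structures in a trajectory
#'
#' The baseline (z-offset 0) state is not counted.
#' @param trajectory a `vsd_trajectory`.
#' @export
n_downshifted <- function(trajectory) {
  sum(vapply(trajectory$steps, function(s) s$z_offset < 0, logical(1)))
}

#' Per-step energy table of a trajectory
#'
#' @param trajectory a `vsd_trajectory`.
#' @return data.frame: step, z_offset, coulomb, lj, backbone, restraint, total.
#' @export
trajectory_energies <- function(trajectory) {
  do.call(rbind, lapply(trajectory$steps, function(s) {
    data.frame(step = s$index, z_offset = s$z_offset,
               coulomb = s$energy[["coulomb"]], lj = s$energy[["lj"]],
               backbone = s$energy[["backbone"]],
               restraint = s$energy[["restraint"]], total = s$energy[["total"]])
  }))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory a `vsd_trajectory`.
#' @param path output path.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  write_pdb(lapply(trajectory$steps, function(s) s$structure), path)
}
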