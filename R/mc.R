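# Monte-Carlo energy minimization: random move -> local coordinate descent ->
# Metropolis acceptance, over a reduced set of degrees of freedom (rigid
# annotated helices + individually mobile interaction sites / free atoms).

#' Monte-Carlo minimization configuration
#'
#' @param seed integer, or `NULL` to continue the caller's RNG stream.
#' @param temperature Metropolis temperature, K.
#' @param s4_shift,s4_rot,helix_shift,site_jitter random-move scales
#'   (A, degrees, A, A). `s4_shift`/`s4_rot` apply to plane-constrained rigid
#'   helices, `helix_shift` to the others.
#' @param termination_window stop after this many consecutive candidate
#'   minimizations that fail to improve the best energy (improvements smaller
#'   than 1e-9 kcal/mol count as non-improving).
#' @param max_moves hard cap on candidate moves.
#' @param descent_iters step-halving sweeps of the local coordinate descent
#'   run after each random move.
#' @param shake_prob,shake_factor probability and scale multiplier of
#'   occasional large site moves (lets side-chain sites cross steric barriers
#'   and swap salt-bridge partners).
#' @export
mc_config <- function(seed = NULL, temperature = 300,
                      s4_shift = 0.3, s4_rot = 3, helix_shift = 0.15,
                      site_jitter = 0.3,
                      termination_window = 100, max_moves = 3000,
                      descent_iters = 20, shake_prob = 0.25, shake_factor = 5) {
  stopifnot(termination_window >= 1, max_moves >= 1, descent_iters >= 1,
            temperature > 0, shake_prob >= 0, shake_prob <= 1, shake_factor >= 1)
  structure(list(seed = seed, temperature = temperature, s4_shift = s4_shift,
                 s4_rot = s4_rot, helix_shift = helix_shift,
                 site_jitter = site_jitter,
                 termination_window = as.integer(termination_window),
                 max_moves = as.integer(max_moves),
                 descent_iters = as.integer(descent_iters),
                 shake_prob = shake_prob, shake_factor = shake_factor),
            class = "mc_config")
}

# Degree-of-freedom layout. Components:
#   helix: rigid in-plane translation (+ rotation about the vertical axis
#          through the helix CA centroid); dz included only when no atom of
#          the helix is plane-constrained.
#   atom:  per-atom offsets (x, y[, z]) for site atoms and unannotated atoms.
build_dofs <- function(s, plane_atoms, config) {
  a <- s$atoms
  hel <- atom_helix(s)
  comps <- list()
  for (h in names(s$helices)) {
    rows <- which(hel == h)
    if (!length(rows)) next
    ca <- rows[a$name[rows] == "CA"]
    constrained <- any(rows %in% plane_atoms)
    centroid <- c(mean(a$x[ca]), mean(a$y[ca]))
    scale_t <- if (constrained) config$s4_shift else config$helix_shift
    comps[[length(comps) + 1L]] <- list(
      type = "helix", rows = rows, centroid = centroid,
      has_dz = !constrained, rot = constrained,
      npar = 2L + (!constrained) + constrained,  # dx, dy [, dz] [, phi]
      move_scale = c(scale_t, scale_t,
                     if (!constrained) scale_t,
                     if (constrained) config$s4_rot * pi / 180),
      descent_step = c(0.4, 0.4, if (!constrained) 0.4, if (constrained) 5 * pi / 180))
  }
  helixed <- if (length(s$helices)) which(!is.na(hel)) else integer(0)
  singles <- c(which(is_site_atom(a)), setdiff(seq_len(nrow(a)), helixed))
  singles <- sort(unique(singles))
  for (i in singles) {
    has_z <- !(i %in% plane_atoms)
    np <- 2L + has_z
    comps[[length(comps) + 1L]] <- list(
      type = "atom", rows = i, has_dz = has_z, rot = FALSE, npar = np,
      move_scale = rep(config$site_jitter, np),
      descent_step = rep(0.3, np))
  }
  offs <- cumsum(c(0L, vapply(comps, function(cm) cm$npar, integer(1))))
  for (k in seq_along(comps)) comps[[k]]$par_idx <- (offs[k] + 1L):offs[k + 1L]
  list(comps = comps, npar = offs[length(offs)])
}

# Apply one component's parameters to the base coordinates (rows only).
component_coords <- function(cm, X0, theta) {
  p <- theta[cm$par_idx]
  Xr <- X0[cm$rows, , drop = FALSE]
  if (cm$type == "helix") {
    k <- 3L
    if (cm$rot) {
      phi <- p[length(p)]
      if (phi != 0) {
        cx <- cm$centroid[1]; cy <- cm$centroid[2]
        dx <- Xr[, 1] - cx; dy <- Xr[, 2] - cy
        co <- cos(phi); si <- sin(phi)
        Xr[, 1] <- cx + co * dx - si * dy
        Xr[, 2] <- cy + si * dx + co * dy
      }
    }
    Xr[, 1] <- Xr[, 1] + p[1]
    Xr[, 2] <- Xr[, 2] + p[2]
    if (cm$has_dz) Xr[, 3] <- Xr[, 3] + p[3]
  } else {
    Xr[1, 1] <- Xr[1, 1] + p[1]
    Xr[1, 2] <- Xr[1, 2] + p[2]
    if (cm$has_dz) Xr[1, 3] <- Xr[1, 3] + p[3]
  }
  Xr
}

theta_to_coords <- function(dofs, X0, theta, site_rows_by_comp = NULL) {
  X <- X0
  for (cm in dofs$comps) {
    if (cm$type == "helix") {
      X[cm$rows, ] <- component_coords(cm, X0, theta)
    }
  }
  # atom offsets apply on top of any rigid transform their helix received
  for (cm in dofs$comps) {
    if (cm$type == "atom") {
      p <- theta[cm$par_idx]
      X[cm$rows, 1] <- X[cm$rows, 1] + p[1]
      X[cm$rows, 2] <- X[cm$rows, 2] + p[2]
      if (cm$has_dz) X[cm$rows, 3] <- X[cm$rows, 3] + p[3]
    }
  }
  X
}

#' Monte-Carlo energy minimization
#'
#' Alternates a random move (rigid helix shift/rotation or per-site jitter), a
#' local step-halving coordinate descent over all degrees of freedom, and a
#' Metropolis acceptance test. Terminates when `termination_window` consecutive
#' candidate minimizations fail to improve the best energy, or at `max_moves`.
#' Plane constraints are enforced exactly by construction (constrained z is
#' never a degree of freedom; the input is projected onto the plane first).
#'
#' @param structure a `vsd_structure`.
#' @param model an [energy_model()].
#' @param restraints list of [plane_constraint()] / [flat_bottom_restraint()].
#' @param config an [mc_config()].
#' @return List: `structure` (best), `energy` (named terms), `trace`
#'   (best-energy after each improvement), `n_moves`, `n_accepted`.
#' @export
mc_minimize <- function(structure, model = energy_model(), restraints = list(),
                        config = mc_config()) {
  if (is.function(model$dielectric)) {
    stop("mc_minimize requires the \"r\" or constant dielectric (C++ hot loop)")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  planes <- Filter(function(r) inherits(r, "plane_constraint"), restraints)
  fbs <- Filter(function(r) inherits(r, "flat_bottom_restraint"), restraints)
  plane_atoms <- unlist(lapply(planes, function(p) p$atoms))
  bad <- plane_atoms < 1 | plane_atoms > n_atoms(structure)
  if (length(plane_atoms) && any(bad)) stop("plane constraint references a missing atom")

  X0 <- coords(structure)
  for (p in planes) X0[p$atoms, 3] <- p$target_z   # projection: pre-satisfy
  sys <- compile_energy_system(structure, model, fbs)
  dofs <- build_dofs(structure, plane_atoms, config)
  if (dofs$npar == 0L) stop("structure has no degrees of freedom")

  e_of <- function(theta) {
    e <- eval_energy(sys, theta_to_coords(dofs, X0, theta))
    if (!is.finite(e[["total"]])) {
      stop("non-finite energy during MC minimization; offending state dumped ",
           "to attribute 'theta'", call. = FALSE)
    }
    e
  }

  descend <- function(theta, e, idx = seq_len(dofs$npar)) {
    steps <- numeric(dofs$npar)
    for (cm in dofs$comps) steps[cm$par_idx] <- cm$descent_step
    for (sweep in seq_len(config$descent_iters)) {
      improved <- FALSE
      for (i in idx) {
        for (sgn in c(1, -1)) {
          th2 <- theta; th2[i] <- th2[i] + sgn * steps[i]
          e2 <- e_of(th2)
          if (e2[["total"]] < e[["total"]] - 1e-12) {
            theta <- th2; e <- e2; improved <- TRUE
            break
          }
        }
      }
      steps <- steps / 2
      if (!improved && sweep >= 3) break
    }
    list(theta = theta, e = e)
  }

  kT <- 0.0019872041 * config$temperature
  theta <- numeric(dofs$npar)
  e_cur <- e_of(theta)
  d0 <- descend(theta, e_cur)
  theta <- d0$theta; e_cur <- d0$e
  best_theta <- theta; e_best <- e_cur
  trace <- e_best[["total"]]
  since_best <- 0L; n_acc <- 0L; n_moves <- 0L

  while (since_best < config$termination_window && n_moves < config$max_moves) {
    n_moves <- n_moves + 1L
    cm <- dofs$comps[[sample.int(length(dofs$comps), 1L)]]
    cand <- theta
    # occasional large "shake" lets interaction sites cross LJ barriers and
    # swap salt-bridge partners; routine moves stay at the base scales
    boost <- if (cm$type == "atom" && stats::runif(1) < config$shake_prob)
      config$shake_factor else 1
    cand[cm$par_idx] <- cand[cm$par_idx] +
      stats::rnorm(cm$npar, 0, boost * cm$move_scale)
    # local minimization over the moved component's degrees of freedom
    d <- descend(cand, e_of(cand), idx = cm$par_idx)
    dE <- d$e[["total"]] - e_cur[["total"]]
    if (dE <= 0 || stats::runif(1) < exp(-dE / kT)) {
      theta <- d$theta; e_cur <- d$e; n_acc <- n_acc + 1L
    }
    if (d$e[["total"]] < e_best[["total"]] - 1e-9) {
      best_theta <- d$theta; e_best <- d$e; since_best <- 0L
      trace <- c(trace, e_best[["total"]])
    } else {
      since_best <- since_best + 1L
    }
  }

  out <- structure
  coords(out) <- theta_to_coords(dofs, X0, best_theta)
  list(structure = out, energy = e_best, trace = trace,
       n_moves = n_moves, n_accepted = n_acc)
}
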