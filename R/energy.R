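# Surrogate energy model and restraints for the coarse-grained VSD.
#
# The model works on a CA trace plus one charged interaction site per
# ionizable side chain. It replaces the original all-atom force field with a
# declared surrogate that preserves the sign structure of the interactions:
# Coulomb with a distance-dependent dielectric, 12-6 Lennard-Jones on
# nonbonded site/CA pairs, harmonic intra-helix virtual bonds, and harmonic
# site tethers keeping each interaction site near its ideal CA offset.

#' Surrogate energy model
#'
#' @param coulomb_constant kcal*A/(mol*e^2); 332.06.
#' @param dielectric either the string `"r"` (distance-proportional dielectric,
#'   eps(r) = dielectric_scale * r, the default surrogate) or a positive number
#'   (constant dielectric). Arbitrary functions are accepted by
#'   [total_energy()] but not inside the Monte-Carlo hot loop.
#' @param dielectric_scale multiplier for the `"r"` mode.
#' @param lj_sigma,lj_epsilon 12-6 Lennard-Jones parameters (A, kcal/mol).
#' @param backbone_k force constant for intra-helix virtual bonds and site
#'   tethers, kcal/(mol*A^2).
#' @param charges named charge map by 3-letter residue type, e.
#' @return List of class `energy_model`.
#' @export
energy_model <- function(coulomb_constant = 332.06,
                         dielectric = "r",
                         dielectric_scale = 1,
                         lj_sigma = 4.0,
                         lj_epsilon = 0.1,
                         backbone_k = 10,
                         charges = c(ARG = 1, LYS = 1, GLU = -1, ASP = -1)) {
  stopifnot(coulomb_constant > 0, lj_sigma > 0, lj_epsilon > 0, backbone_k > 0)
  if (!(identical(dielectric, "r") || is.function(dielectric) ||
        (is.numeric(dielectric) && dielectric > 0))) {
    stop("dielectric must be \"r\", a positive constant, or a function of r")
  }
  structure(list(coulomb_constant = coulomb_constant, dielectric = dielectric,
                 dielectric_scale = dielectric_scale, lj_sigma = lj_sigma,
                 lj_epsilon = lj_epsilon, backbone_k = backbone_k,
                 charges = charges),
            class = "energy_model")
}

#' Flat-bottom positional restraint
#'
#' Zero penalty for deviations up to `free_radius` from `reference`; harmonic
#' penalty `force_k * (d - free_radius)^2` beyond it.
#'
#' @param atom integer atom row index.
#' @param reference 3-vector reference position (A).
#' @param free_radius penalty-free radius, A.
#' @param force_k kcal/(mol*A^2).
#' @export
flat_bottom_restraint <- function(atom, reference, free_radius = 4.0, force_k = 10) {
  stopifnot(length(atom) == 1, length(reference) == 3, free_radius >= 0, force_k >= 0)
  structure(list(atom = as.integer(atom), reference = as.numeric(reference),
                 free_radius = free_radius, force_k = force_k),
            class = "flat_bottom_restraint")
}

#' Plane (fixed-z) constraint
#'
#' Constrained atoms may move freely within the plane normal to the membrane
#' axis (z) but may not leave it: their z coordinate equals `target_z` exactly
#' after every accepted move.
#'
#' @param atoms integer atom row indices.
#' @param target_z plane height, A (recycled).
#' @export
plane_constraint <- function(atoms, target_z) {
  structure(list(atoms = as.integer(atoms),
                 target_z = rep_len(as.numeric(target_z), length(atoms))),
            class = "plane_constraint")
}

is_site_atom <- function(atoms) atoms$name %in% unname(SITE_ATOM)

# Helix membership per atom: helix name or NA.
atom_helix <- function(s) {
  out <- rep(NA_character_, nrow(s$atoms))
  for (h in names(s$helices)) {
    hh <- s$helices[[h]]
    sel <- s$atoms$chain == hh$chain &
      s$atoms$residue_index >= hh$from & s$atoms$residue_index <= hh$to
    out[sel] <- h
  }
  out
}

# Precompile structure + model + restraints into flat pair lists for the C++
# energy kernel. Nonbonded pairs are pairs on different helices (or different
# chains when unannotated) or >= 3 residues apart within a chain.
compile_energy_system <- function(s, model, restraints = list()) {
  a <- s$atoms
  n <- nrow(a)
  hel <- atom_helix(s)
  grp <- ifelse(is.na(hel), paste0("chain:", a$chain), hel)
  q <- rep(0, n)
  site <- is_site_atom(a)
  known <- a$residue_name %in% names(model$charges)
  q[site & known] <- model$charges[a$residue_name[site & known]]
  if (any(site & !known)) {
    warning("ionizable site atoms with no charge entry treated as neutral: ",
            paste(unique(a$residue_name[site & !known]), collapse = ", "))
  }

  idx <- seq_len(n)
  pairs_i <- rep(idx, times = n - idx)
  pairs_j <- unlist(lapply(idx[-n], function(i) (i + 1L):n), use.names = FALSE)
  same_res <- a$chain[pairs_i] == a$chain[pairs_j] &
    a$residue_index[pairs_i] == a$residue_index[pairs_j]
  nonbonded <- !same_res &
    (grp[pairs_i] != grp[pairs_j] |
       abs(a$residue_index[pairs_i] - a$residue_index[pairs_j]) >= 3L)

  qq <- nonbonded & q[pairs_i] != 0 & q[pairs_j] != 0
  lj <- nonbonded

  # intra-helix virtual bonds on the CA trace: (i, i+1) at 3.8 A, (i, i+4) at
  # 6.2 A; plus a tether from each site atom to its own CA at the build offset
  b_i <- integer(0); b_j <- integer(0); b_len <- numeric(0)
  for (g in unique(grp)) {
    ca <- which(grp == g & a$name == "CA")
    ca <- ca[order(a$residue_index[ca])]
    ri <- a$residue_index[ca]
    for (off in c(1L, 4L)) {
      len <- if (off == 1L) 3.8 else 6.2
      m <- match(ri + off, ri)
      ok <- !is.na(m)
      b_i <- c(b_i, ca[ok]); b_j <- c(b_j, ca[m[ok]])
      b_len <- c(b_len, rep(len, sum(ok)))
    }
  }
  for (k in which(site & a$residue_name %in% names(SITE_DIST))) {
    ca <- which(a$chain == a$chain[k] & a$residue_index == a$residue_index[k] &
                  a$name == "CA")
    if (length(ca) == 1) {
      b_i <- c(b_i, k); b_j <- c(b_j, ca)
      b_len <- c(b_len, unname(SITE_DIST[a$residue_name[k]]))
    }
  }

  fb <- Filter(function(r) inherits(r, "flat_bottom_restraint"), restraints)
  bad <- vapply(fb, function(r) r$atom < 1 || r$atom > n, logical(1))
  if (any(bad)) stop("flat-bottom restraint references a missing atom")
  fb_i <- vapply(fb, function(r) r$atom, integer(1))
  fb_ref <- if (length(fb)) do.call(rbind, lapply(fb, function(r) r$reference)) else
    matrix(0, 0, 3)
  fb_r <- vapply(fb, function(r) r$free_radius, numeric(1))
  fb_k <- vapply(fb, function(r) r$force_k, numeric(1))

  dielectric_mode <- if (identical(model$dielectric, "r")) 0L else 1L
  eps_param <- if (dielectric_mode == 0L) model$dielectric_scale
  else if (is.function(model$dielectric)) NA_real_   # R evaluation path only
  else as.numeric(model$dielectric)

  list(n = n, charges = q,
       qq_i = pairs_i[qq] - 1L, qq_j = pairs_j[qq] - 1L,
       qprod = q[pairs_i[qq]] * q[pairs_j[qq]],
       lj_i = pairs_i[lj] - 1L, lj_j = pairs_j[lj] - 1L,
       b_i = b_i - 1L, b_j = b_j - 1L, b_len = b_len,
       b_k = rep(model$backbone_k, length(b_len)),
       fb_i = fb_i - 1L, fb_ref = fb_ref, fb_r = fb_r, fb_k = fb_k,
       dielectric_mode = dielectric_mode, eps_param = eps_param,
       model = model)
}

eval_energy <- function(sys, X) {
  energy_terms_cpp(X, sys$qq_i, sys$qq_j, sys$qprod,
                   sys$model$coulomb_constant, sys$dielectric_mode, sys$eps_param,
                   sys$lj_i, sys$lj_j, sys$model$lj_sigma, sys$model$lj_epsilon,
                   sys$b_i, sys$b_j, sys$b_len, sys$b_k,
                   sys$fb_i, sys$fb_ref, sys$fb_r, sys$fb_k)
}

#' Total surrogate energy of a structure
#'
#' @param structure a `vsd_structure`.
#' @param model an [energy_model()].
#' @param restraints list of [flat_bottom_restraint()]s (plane constraints are
#'   hard constraints and carry no energy).
#' @return Named numeric vector: `coulomb`, `lj`, `backbone`, `restraint`,
#'   `total` (kcal/mol).
#' @export
total_energy <- function(structure, model = energy_model(), restraints = list()) {
  sys <- compile_energy_system(structure, model, restraints)
  X <- coords(structure)
  if (is.function(model$dielectric)) {
    return(eval_energy_r(sys, X, model$dielectric))
  }
  e <- eval_energy(sys, X)
  if (!all(is.finite(e))) stop("non-finite energy encountered")
  e
}

# Reference R evaluation, also the path for user-supplied dielectric closures.
eval_energy_r <- function(sys, X, dielectric_fun = NULL) {
  d_of <- function(i0, j0) {
    sqrt(rowSums((X[i0 + 1L, , drop = FALSE] - X[j0 + 1L, , drop = FALSE])^2))
  }
  e_coul <- 0
  if (length(sys$qq_i)) {
    r <- pmax(d_of(sys$qq_i, sys$qq_j), 1e-6)
    eps <- if (!is.null(dielectric_fun)) dielectric_fun(r)
    else if (sys$dielectric_mode == 0L) sys$eps_param * r else sys$eps_param
    e_coul <- sum(sys$model$coulomb_constant * sys$qprod / (eps * r))
  }
  e_lj <- 0
  if (length(sys$lj_i)) {
    r <- pmax(d_of(sys$lj_i, sys$lj_j), 1e-6)
    s6 <- (sys$model$lj_sigma / r)^6
    e_lj <- sum(4 * sys$model$lj_epsilon * (s6^2 - s6))
  }
  e_bond <- 0
  if (length(sys$b_i)) {
    r <- d_of(sys$b_i, sys$b_j)
    e_bond <- sum(sys$b_k * (r - sys$b_len)^2)
  }
  e_restr <- 0
  if (length(sys$fb_i)) {
    d <- sqrt(rowSums((X[sys$fb_i + 1L, , drop = FALSE] - sys$fb_ref)^2))
    over <- pmax(d - sys$fb_r, 0)
    e_restr <- sum(sys$fb_k * over^2)
  }
  c(coulomb = e_coul, lj = e_lj, backbone = e_bond, restraint = e_restr,
    total = e_coul + e_lj + e_bond + e_restr)
}

#' Coulomb term of a single charged-site pair
#'
#' Useful for sign diagnostics along trajectories (attraction < 0,
#' repulsion > 0).
#'
#' @param structure a `vsd_structure`.
#' @param res_a,res_b residue ids as `"chain:residue_index"` strings.
#' @param model an [energy_model()].
#' @return Energy in kcal/mol.
#' @export
pair_coulomb <- function(structure, res_a, res_b, model = energy_model()) {
  site <- function(id) {
    p <- strsplit(id, ":", fixed = TRUE)[[1]]
    i <- atom_index(structure, chain = p[1], residue_index = as.integer(p[2]))
    i <- i[is_site_atom(structure$atoms[i, , drop = FALSE])]
    if (length(i) != 1) stop("no unique charged site for residue ", id)
    i
  }
  ia <- site(res_a); ib <- site(res_b)
  a <- structure$atoms
  qa <- model$charges[[a$residue_name[ia]]]
  qb <- model$charges[[a$residue_name[ib]]]
  r <- sqrt(sum((coords(structure)[ia, ] - coords(structure)[ib, ])^2))
  eps <- if (identical(model$dielectric, "r")) model$dielectric_scale * r
  else if (is.function(model$dielectric)) model$dielectric(r)
  else as.numeric(model$dielectric)
  model$coulomb_constant * qa * qb / (eps * r)
}
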