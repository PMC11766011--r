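# Structures: atom tables, PDB I/O, toy voltage-sensor construction, Kabsch superposition.

#' Construct a structure object
#'
#' A structure is an ordered atom table plus optional helix annotations. Atoms
#' are identified by (chain, residue_index, name), which must be unique.
#'
#' @param atoms data.frame with columns `name`, `residue_name`, `residue_index`,
#'   `chain`, `x`, `y`, `z`.
#' @param helices named list of helix annotations; each element is a list with
#'   `chain`, `from`, `to` (residue-index range) and optionally `axis_origin`,
#'   `axis_direction` for builder-made ideal helices.
#' @return An object of class `vsd_structure`.
#' @export
vsd_structure <- function(atoms, helices = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "residue_name", "residue_index", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms$residue_index <- as.integer(atoms$residue_index)
  key <- paste(atoms$chain, atoms$residue_index, atoms$name)
  if (anyDuplicated(key)) stop("duplicate (chain, residue_index, name) atom keys")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  for (h in names(helices)) {
    hh <- helices[[h]]
    if (hh$to - hh$from + 1L < 4L) stop("annotated helix '", h, "' has fewer than 4 residues")
  }
  structure(list(atoms = atoms, helices = helices), class = "vsd_structure")
}

#' @export
print.vsd_structure <- function(x, ...) {
  cat("<vsd_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)", sep = "")
  if (length(x$helices)) {
    cat(", helices: ", paste(names(x$helices), collapse = " "), sep = "")
  }
  cat("\n")
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

`coords<-` <- function(s, value) {
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Locate atoms by chain / residue / name
#'
#' @param s a `vsd_structure`
#' @param chain,residue_index,name selection values; `NULL` matches anything.
#' @return Integer row indices into `s$atoms`.
#' @export
atom_index <- function(s, chain = NULL, residue_index = NULL, name = NULL) {
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  if (!is.null(residue_index)) keep <- keep & s$atoms$residue_index %in% residue_index
  if (!is.null(name)) keep <- keep & s$atoms$name %in% name
  which(keep)
}

# ---- PDB I/O ----------------------------------------------------------------

parse_pdb_lines <- function(lines, path = "<text>") {
  recs <- which(startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM"))
  if (!length(recs)) stop("no ATOM/HETATM records in ", path)
  sub_num <- function(ln, a, b, what, i) {
    v <- suppressWarnings(as.numeric(substr(ln, a, b)))
    if (is.na(v)) stop("PDB format error at line ", i, " of ", path,
                       ": unparseable ", what, " field")
    v
  }
  n <- length(recs)
  name <- character(n); resn <- character(n); resi <- integer(n); chain <- character(n)
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  altloc_seen <- FALSE
  for (k in seq_len(n)) {
    i <- recs[k]; ln <- lines[i]
    name[k]  <- trimws(substr(ln, 13, 16))
    if (substr(ln, 17, 17) != " ") altloc_seen <- TRUE
    resn[k]  <- trimws(substr(ln, 18, 20))
    chain[k] <- substr(ln, 22, 22)
    resi[k]  <- as.integer(sub_num(ln, 23, 26, "residue number", i))
    x[k] <- sub_num(ln, 31, 38, "x", i)
    y[k] <- sub_num(ln, 39, 46, "y", i)
    z[k] <- sub_num(ln, 47, 54, "z", i)
  }
  if (altloc_seen) warning("altloc/insertion codes present and ignored")
  vsd_structure(data.frame(name = name, residue_name = resn, residue_index = resi,
                           chain = chain, x = x, y = y, z = z,
                           stringsAsFactors = FALSE))
}

#' Read a PDB file
#'
#' Fixed-column ATOM/HETATM parsing. Files containing MODEL/ENDMDL blocks are
#' read as a list of structures (the package's trajectory interchange dialect).
#'
#' @param path PDB file path.
#' @return A `vsd_structure`, or a list of them for multi-model files.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDB file: ", path)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) return(parse_pdb_lines(lines, path))
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  lapply(seq_along(model_starts), function(m) {
    parse_pdb_lines(lines[(model_starts[m] + 1L):(model_ends[m] - 1L)], path)
  })
}

format_atom_line <- function(serial, name, resn, chain, resi, x, y, z) {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, nm, resn, chain, resi %% 10000L, x, y, z)
}

structure_pdb_lines <- function(s) {
  a <- s$atoms
  vapply(seq_len(nrow(a)), function(i) {
    format_atom_line(i, a$name[i], a$residue_name[i], a$chain[i],
                     a$residue_index[i], a$x[i], a$y[i], a$z[i])
  }, character(1))
}

#' Write one structure (or several, as MODEL blocks) to a PDB file
#'
#' @param structure a `vsd_structure` or a list of them.
#' @param path output path.
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "vsd_structure")) {
    if (!n_atoms(structure)) stop("refusing to write an empty structure")
    lines <- c(structure_pdb_lines(structure), "END")
  } else if (is.list(structure) && length(structure) &&
             all(vapply(structure, inherits, logical(1), "vsd_structure"))) {
    lines <- unlist(lapply(seq_along(structure), function(m) {
      c(sprintf("MODEL     %4d", m), structure_pdb_lines(structure[[m]]), "ENDMDL")
    }))
    lines <- c(lines, "END")
  } else {
    stop("structure must be a vsd_structure or a non-empty list of them")
  }
  con <- file(path, "wb")  # fixed newline convention => byte-identical output
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- toy voltage-sensor builder --------------------------------------------

# Representative side-chain interaction-site atom per ionizable residue type,
# and its distance from CA along the outward (axis -> CA) radial direction.
SITE_ATOM <- c(ARG = "CZ", LYS = "NZ", GLU = "CD", ASP = "CG")
SITE_DIST <- c(ARG = 4.1,  LYS = 3.9,  GLU = 3.1,  ASP = 2.5)
SITE_CHARGE <- c(ARG = +1, LYS = +1, GLU = -1, ASP = -1)

AA3 <- c(A = "ALA", R = "ARG", K = "LYS", E = "GLU", D = "ASP", G = "GLY",
         L = "LEU", V = "VAL", I = "ILE", S = "SER", T = "THR", N = "ASN",
         Q = "GLN", F = "PHE", Y = "TYR", W = "TRP", H = "HIS", M = "MET",
         C = "CYS", P = "PRO")

#' Ideal-helix build specification
#'
#' @param sequence one-letter amino-acid string.
#' @param axis_origin 3-vector, CA-level position of residue 1's axis point (A).
#' @param axis_direction unit 3-vector; residues advance 1.5 A per residue
#'   along it.
#' @param phase degrees; azimuth of residue 1's CA about the axis.
#' @return A list of class `helix_spec`.
#' @export
helix_spec <- function(sequence, axis_origin, axis_direction = c(0, 0, 1), phase = 0) {
  if (!nzchar(sequence)) stop("empty helix sequence")
  axis_direction <- as.numeric(axis_direction)
  nrm <- sqrt(sum(axis_direction^2))
  if (abs(nrm - 1) > 1e-8) stop("axis_direction must have unit norm")
  structure(list(sequence = toupper(sequence),
                 axis_origin = as.numeric(axis_origin),
                 axis_direction = axis_direction, phase = phase),
            class = "helix_spec")
}

#' Default toy voltage-sensor helix specifications
#'
#' Four ideal helices (S1-S4) on a ~12 A square with vertical (membrane-normal)
#' axes, +z extracellular. S4 descends from the extracellular side and carries
#' the voltage-sensing basic residues R1, R2, R3, K4 at positions 3, 6, 9, 12.
#' The countercharge ladder mirrors a real voltage sensor: S2 carries the
#' uppermost glutamate E1 (the R1 partner of the deactivated state) and a
#' deeper E2, S3 an aspartate D1. E1 sits 10.5 A (two helical turns) below
#' R1's starting CA level, so in the default 21-step deactivation the
#' descending basics engage E1 sequentially (R3, then R2, then R1) and the
#' R1-E1 approach completes at the final step, while E2/D1 take over R2/R3.
#' The mutant variant replaces R1 by glutamate.
#'
#' @param variant `"WT"` or `"R1E"`.
#' @return Named list of `helix_spec` objects (S1-S4).
#' @export
toy_vsd_specs <- function(variant = c("WT", "R1E")) {
  variant <- match.arg(variant)
  s4_seq <- if (variant == "WT") "AARAARAARAAKAA" else "AAEAARAARAAKAA"
  list(
    S1 = helix_spec("AAAAAAAAAAAAAA", c(0, 0, 0),    c(0, 0, 1), phase = 0),
    # E1 at index 9 (CA z = 12) faces S4 (azimuth 0 deg); E2 at index 6
    # (CA z = 7.5, the R2 level after the full downshift) at azimuth 60 deg
    S2 = helix_spec("AAAAAEAAEAAAAA", c(0, 12, 0),   c(0, 0, 1), phase = -800),
    # D1 at index 3 (CA z = 3, the final R3 level) faces S4 (azimuth 90 deg)
    S3 = helix_spec("AADAAAAAAAAAAA", c(12, 0, 0),   c(0, 0, 1), phase = -110),
    # descending helix: residue 1 extracellular at z = 25.5; R1 (index 3) at
    # z = 22.5, facing S2 (azimuth(3) = 180 deg about the S4 axis)
    S4 = helix_spec(s4_seq, c(12, 12, 25.5), c(0, 0, -1), phase = -20)
  )
}

build_ideal_helix <- function(spec, chain, rise = 1.5, twist = 100, radius = 2.3) {
  seq1 <- strsplit(spec$sequence, "")[[1]]
  n <- length(seq1)
  a <- spec$axis_direction
  # orthonormal frame (u, v) perpendicular to the axis
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3], a[1] * u[2] - a[2] * u[1])
  th <- (spec$phase + (seq_len(n) - 1) * twist) * pi / 180
  axis_pt <- t(vapply(seq_len(n), function(i) spec$axis_origin + a * rise * (i - 1),
                      numeric(3)))
  radial <- t(vapply(seq_len(n), function(i) u * cos(th[i]) + v * sin(th[i]), numeric(3)))
  ca <- axis_pt + radius * radial
  resn <- unname(AA3[seq1])
  if (anyNA(resn)) stop("unknown residue letter in helix sequence: ", spec$sequence)
  at <- data.frame(name = "CA", residue_name = resn, residue_index = seq_len(n),
                   chain = chain, x = ca[, 1], y = ca[, 2], z = ca[, 3],
                   stringsAsFactors = FALSE)
  ion <- which(resn %in% names(SITE_ATOM))
  if (length(ion)) {
    site <- ca[ion, , drop = FALSE] + SITE_DIST[resn[ion]] * radial[ion, , drop = FALSE]
    at <- rbind(at, data.frame(name = unname(SITE_ATOM[resn[ion]]),
                               residue_name = resn[ion], residue_index = ion,
                               chain = chain, x = site[, 1], y = site[, 2],
                               z = site[, 3], stringsAsFactors = FALSE))
  }
  at[order(at$residue_index, at$name != "CA"), ]
}

#' Build a toy four-helix voltage-sensor domain
#'
#' Ideal alpha-helices (rise 1.5 A/residue, 100 deg/residue, CA radius 2.3 A)
#' with one side-chain interaction site per ionizable residue, placed along the
#' outward axis-to-CA radial direction (Arg 4.1, Lys 3.9, Glu 3.1, Asp 2.5 A
#' from CA). The membrane normal is z, extracellular is +z. S4 must carry four
#' basic residues spaced i, i+3, i+6, i+9 (R1, R2, R3, K4).
#'
#' @param specs named list of four `helix_spec`s (S1-S4), e.g. [toy_vsd_specs()].
#' @param variant convenience shortcut when `specs` is `NULL`.
#' @return A `vsd_structure` with helix annotations; chains A-D map to S1-S4.
#' @export
build_toy_vsd <- function(specs = NULL, variant = c("WT", "R1E")) {
  variant <- match.arg(variant)
  if (is.null(specs)) specs <- toy_vsd_specs(variant)
  if (!identical(sort(names(specs)), c("S1", "S2", "S3", "S4"))) {
    stop("specs must be a named list with exactly S1, S2, S3, S4")
  }
  s4 <- strsplit(specs$S4$sequence, "")[[1]]
  # canonical lattice: 4 voltage-sensing positions at spacing i, i+3, i+6, i+9;
  # mutant variants may substitute one of them (e.g. R1 -> E) but the lattice
  # itself must be occupied by charged residues
  charged <- which(s4 %in% c("R", "K", "E", "D"))
  lat <- NULL
  for (i in charged) {
    if (all(c(i, i + 3, i + 6, i + 9) %in% charged)) { lat <- i + c(0, 3, 6, 9); break }
  }
  if (is.null(lat) || sum(s4[lat] %in% c("R", "K")) < 3) {
    stop("S4 must carry its 4 voltage-sensing residues at spacing i, i+3, i+6, i+9 ",
         "(at most one substituted)")
  }
  chains <- c(S1 = "A", S2 = "B", S3 = "C", S4 = "D")
  at <- do.call(rbind, lapply(names(chains), function(h) {
    build_ideal_helix(specs[[h]], chains[[h]])
  }))
  rownames(at) <- NULL
  helices <- lapply(names(chains), function(h) {
    list(chain = chains[[h]],
         from = 1L, to = nchar(specs[[h]]$sequence),
         axis_origin = specs[[h]]$axis_origin,
         axis_direction = specs[[h]]$axis_direction)
  })
  names(helices) <- names(chains)
  vsd_structure(at, helices)
}

#' CA row indices of the four S4 voltage-sensing basic residues
#'
#' @param s a toy VSD built by [build_toy_vsd()] (S4 annotated, chain D).
#' @return Integer vector of 4 atom row indices (R1, R2, R3, K4 CAs).
#' @export
s4_basic_ca <- function(s) {
  if (!"S4" %in% names(s$helices)) stop("structure has no annotated S4 helix")
  ch <- s$helices$S4$chain
  a <- s$atoms
  idx <- which(a$chain == ch & a$name == "CA" &
                 a$residue_name %in% c("ARG", "LYS", "GLU"))
  # voltage-sensing positions occupy the i, i+3, i+6, i+9 lattice; take the
  # four lattice positions anchored at the first charged residue
  ri <- sort(unique(a$residue_index[idx]))
  lattice <- ri[1] + c(0, 3, 6, 9)
  out <- which(a$chain == ch & a$name == "CA" & a$residue_index %in% lattice)
  if (length(out) != 4) stop("could not locate the 4 S4 basic-residue CA atoms")
  out[order(a$residue_index[out])]
}

# ---- Kabsch superposition ---------------------------------------------------

#' Superpose two structures by paired atoms (Kabsch)
#'
#' Least-squares rigid-body superposition of `mobile` onto `reference` using
#' the paired atom selections; a proper rotation (det = +1) is enforced.
#'
#' @param mobile,reference `vsd_structure`s.
#' @param sel_mobile,sel_reference equal-length integer atom row indices
#'   (typically CA selections).
#' @return List of class `superposition`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (A, after superposition). The transform maps mobile
#'   coordinates as `x %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, sel_mobile, sel_reference = sel_mobile) {
  if (length(sel_mobile) != length(sel_reference)) stop("selections differ in length")
  if (length(sel_mobile) < 3) stop("degenerate selection: need >= 3 paired atoms")
  P <- coords(mobile)[sel_mobile, , drop = FALSE]
  Q <- coords(reference)[sel_reference, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  sv <- svd(crossprod(P0, Q0))
  if (sv$d[2] < 1e-8) stop("degenerate selection: paired atoms are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  trans <- unname(qc - as.numeric(R %*% pc))
  moved <- P %*% t(R) + matrix(trans, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to a structure
#'
#' @param s a `vsd_structure`
#' @param sp a `superposition` from [superpose()]
#' @return The transformed structure.
#' @export
apply_superposition <- function(s, sp) {
  X <- coords(s) %*% t(sp$rotation) +
    matrix(sp$translation, n_atoms(s), 3, byrow = TRUE)
  coords(s) <- X
  s
}
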