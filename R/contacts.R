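# Ionizable-pair contacts: charged sites, salt bridges, bridge-distance series
# along trajectories, and S4 rotation direction viewed from the extracellular
# side.

#' Charged interaction sites of a structure
#'
#' One site per Arg/Lys/Glu/Asp, using the representative side-chain atom
#' (Arg CZ guanidinium carbon, Lys NZ, Glu CD carboxylate carbon, Asp CG).
#' Toy structures built by [build_toy_vsd()] carry these atoms as pseudo-sites;
#' full-atom structures use the real atoms. Ionizable residues missing their
#' site atom are skipped with a warning.
#'
#' @param structure a `vsd_structure`.
#' @return data.frame: chain, residue_index, residue_name, site_atom, charge,
#'   x, y, z (one row per site).
#' @export
charged_sites <- function(structure) {
  a <- structure$atoms
  ion <- unique(a[a$residue_name %in% names(SITE_ATOM),
                  c("chain", "residue_index", "residue_name")])
  if (!nrow(ion)) {
    return(data.frame(chain = character(0), residue_index = integer(0),
                      residue_name = character(0), site_atom = character(0),
                      charge = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(ion)), function(k) {
    want <- SITE_ATOM[[ion$residue_name[k]]]
    i <- which(a$chain == ion$chain[k] & a$residue_index == ion$residue_index[k] &
                 a$name == want)
    if (length(i) != 1) {
      warning("residue ", ion$chain[k], ":", ion$residue_index[k], " (",
              ion$residue_name[k], ") lacks its site atom ", want, "; skipped")
      return(NULL)
    }
    data.frame(chain = ion$chain[k], residue_index = ion$residue_index[k],
               residue_name = ion$residue_name[k], site_atom = want,
               charge = unname(SITE_CHARGE[[ion$residue_name[k]]]),
               x = a$x[i], y = a$y[i], z = a$z[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chain = character(0), residue_index = integer(0),
                      residue_name = character(0), site_atom = character(0),
                      charge = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  rownames(out) <- NULL
  out
}

#' Salt bridges and repulsive charged pairs
#'
#' All charged-site pairs within `cutoff`: opposite charges are classified as
#' `salt_bridge`, like charges as `repulsive_pair`. Sorted by distance.
#'
#' @param structure a `vsd_structure`.
#' @param cutoff distance criterion, A (default 4.5).
#' @return data.frame: chain_a, res_a, name_a, chain_b, res_b, name_b,
#'   distance, kind.
#' @export
salt_bridges <- function(structure, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  s <- charged_sites(structure)
  out <- data.frame(chain_a = character(0), res_a = integer(0),
                    name_a = character(0), chain_b = character(0),
                    res_b = integer(0), name_b = character(0),
                    distance = numeric(0), kind = character(0))
  if (nrow(s) < 2) return(out)
  for (i in seq_len(nrow(s) - 1)) {
    for (j in (i + 1):nrow(s)) {
      d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
      if (d <= cutoff) {
        out <- rbind(out, data.frame(
          chain_a = s$chain[i], res_a = s$residue_index[i], name_a = s$residue_name[i],
          chain_b = s$chain[j], res_b = s$residue_index[j], name_b = s$residue_name[j],
          distance = d,
          kind = if (s$charge[i] * s$charge[j] < 0) "salt_bridge" else "repulsive_pair",
          stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$distance), , drop = FALSE]
}

site_xyz <- function(structure, res_id) {
  p <- strsplit(res_id, ":", fixed = TRUE)[[1]]
  s <- charged_sites(structure)
  k <- which(s$chain == p[1] & s$residue_index == as.integer(p[2]))
  if (length(k) != 1) return(NULL)
  c(s$x[k], s$y[k], s$z[k])
}

#' Charged-site distance between a residue pair along a trajectory
#'
#' @param trajectory a `vsd_trajectory`.
#' @param res_a,res_b residue ids as `"chain:residue_index"` strings.
#' @return data.frame: step, z_offset, distance (A), one row per step.
#' @export
bridge_distance_series <- function(trajectory, res_a, res_b) {
  rows <- lapply(trajectory$steps, function(st) {
    pa <- site_xyz(st$structure, res_a)
    pb <- site_xyz(st$structure, res_b)
    if (is.null(pa) || is.null(pb)) {
      stop("residue ", if (is.null(pa)) res_a else res_b,
           " has no charged site at trajectory step ", st$index)
    }
    data.frame(step = st$index, z_offset = st$z_offset,
               distance = sqrt(sum((pa - pb)^2)))
  })
  do.call(rbind, rows)
}

# Principal axis of a helix's CA atoms, oriented toward +z.
helix_axis <- function(structure, helix = "S4") {
  hh <- structure$helices[[helix]]
  if (is.null(hh)) stop("no annotated helix '", helix, "'")
  ca <- atom_index(structure, chain = hh$chain, name = "CA")
  ca <- ca[structure$atoms$residue_index[ca] >= hh$from &
             structure$atoms$residue_index[ca] <= hh$to]
  if (length(ca) < 4) stop("S4 axis degenerate: fewer than 4 CA atoms")
  X <- coords(structure)[ca, , drop = FALSE]
  c0 <- colMeans(X)
  ax <- prcomp(X, center = TRUE)$rotation[, 1]
  if (ax[3] < 0) ax <- -ax
  list(center = c0, axis = ax)
}

#' S4 rotation series along a trajectory
#'
#' Azimuth of a marker residue's CA about the per-step S4 principal axis,
#' relative to step 0 and unwrapped (no +/-180 deg jumps). Positive angles are
#' anticlockwise when viewed from the extracellular side (+z).
#'
#' @param trajectory a `vsd_trajectory`.
#' @param marker_residue `"chain:residue_index"` of an S4 residue.
#' @param helix helix name (default `"S4"`).
#' @return data.frame: step, z_offset, angle (degrees).
#' @export
s4_rotation_series <- function(trajectory, marker_residue, helix = "S4") {
  p <- strsplit(marker_residue, ":", fixed = TRUE)[[1]]
  az <- vapply(trajectory$steps, function(st) {
    s <- st$structure
    hh <- s$helices[[helix]]
    if (is.null(hh) || p[1] != hh$chain ||
        !(as.integer(p[2]) %in% hh$from:hh$to)) {
      stop("marker residue must lie on the annotated ", helix, " helix")
    }
    ax <- helix_axis(s, helix)
    i <- atom_index(s, chain = p[1], residue_index = as.integer(p[2]), name = "CA")
    v <- coords(s)[i, ] - ax$center
    v <- v - sum(v * ax$axis) * ax$axis    # project off the axis
    # basis perpendicular to the axis with anticlockwise-from-+z sign
    ref <- if (abs(ax$axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * ax$axis) * ax$axis; u <- u / sqrt(sum(u^2))
    w <- c(ax$axis[2] * u[3] - ax$axis[3] * u[2],
           ax$axis[3] * u[1] - ax$axis[1] * u[3],
           ax$axis[1] * u[2] - ax$axis[2] * u[1])
    atan2(sum(v * w), sum(v * u)) * 180 / pi
  }, numeric(1))
  rel <- az - az[1]
  # unwrap: keep successive differences within (-180, 180]
  for (k in seq_along(rel)[-1]) {
    d <- rel[k] - rel[k - 1]
    rel[k] <- rel[k - 1] + ((d + 180) %% 360) - 180
  }
  data.frame(step = vapply(trajectory$steps, function(s) s$index, numeric(1)),
             z_offset = vapply(trajectory$steps, function(s) s$z_offset, numeric(1)),
             angle = rel)
}
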