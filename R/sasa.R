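#' Van der Waals radii table for SASA
#'
#' Bondi radii for the elements that dominate protein-ligand systems, a probe
#' radius (default 1.4 Angstrom, the conventional water probe) and a default
#' radius applied, with a warning, to elements missing from the table.
#'
#' @param radii Named numeric vector of van der Waals radii in Angstrom.
#' @param probe Probe radius in Angstrom.
#' @param default Radius for unlisted elements; set to `NA` to make unknown
#'   elements an error instead.
#' @return A `radii_table` list.
#' @export
radii_table <- function(radii = c(C = 1.70, N = 1.55, O = 1.52,
                                  S = 1.80, H = 1.20, P = 1.80),
                        probe = 1.4, default = 1.70) {
  if (any(radii <= 0) || probe < 0) stop("radii must be positive")
  structure(list(radii = radii, probe = probe, default = default),
            class = "radii_table")
}

# Per-atom radii for a structure; warns once per unknown element.
atom_radii <- function(structure, table = radii_table()) {
  el <- structure$atoms$element
  r <- unname(table$radii[el])
  if (anyNA(r)) {
    unknown <- unique(el[is.na(r)])
    if (is.na(table$default))
      stop("no van der Waals radius for element(s): ",
           paste(unknown, collapse = ", "))
    warning("using default radius ", table$default, " A for element(s): ",
            paste(unknown, collapse = ", "))
    r[is.na(r)] <- table$default
  }
  r
}

# Deterministic, near-uniform unit-sphere point set (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, `n_points` test points are placed on a deterministic
#' Fibonacci lattice on the sphere of radius `r_i + probe`; a point is
#' accessible iff it lies outside every other atom's expanded sphere, and the
#' atom's SASA is `4 * pi * (r_i + probe)^2` times the accessible fraction.
#' Occluder search is restricted to atoms within `r_i + r_j + 2 * probe`.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param radii Per-atom van der Waals radii, Angstrom (length n, all > 0).
#' @param probe Probe radius, Angstrom.
#' @param n_points Lattice points per atom (>= 12; default 960).
#' @param subset Optional integer vector: compute SASA only for these atoms
#'   (all atoms still act as occluders).
#' @return Numeric vector of per-atom SASA in Angstrom^2 (length n, or
#'   `length(subset)` if `subset` is given, in `subset` order).
#' @export
shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960L,
                          subset = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1) stop("need at least one atom")
  if (length(radii) != n) stop("radii must match atom count")
  if (any(radii <= 0)) stop("radii must be positive")
  if (n_points < 12) stop("n_points must be >= 12")
  if (is.null(subset)) subset <- seq_len(n)
  pts <- fibonacci_sphere(n_points)
  expanded <- radii + probe
  out <- numeric(length(subset))
  for (k in seq_along(subset)) {
    i <- subset[k]
    Ri <- expanded[i]
    # candidate occluders: spheres that can reach atom i's expanded surface
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (radii[i] + radii + 2 * probe)^2)
    nb <- nb[nb != i]
    if (length(nb) == 0L) {
      out[k] <- 4 * pi * Ri^2
      next
    }
    P <- pts * Ri
    P <- sweep(P, 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb[order(d2[nb])]) {
      live <- which(acc)
      if (length(live) == 0L) break
      dx <- P[live, 1] - coords[j, 1]
      dy <- P[live, 2] - coords[j, 2]
      dz <- P[live, 3] - coords[j, 3]
      acc[live[dx * dx + dy * dy + dz * dz <= expanded[j]^2]] <- FALSE
    }
    out[k] <- 4 * pi * Ri^2 * sum(acc) / n_points
  }
  out
}

#' Per-residue SASA series over a trajectory
#'
#' For each frame, the SASA of the residue is the sum of its atoms' SASA
#' computed in the context of the full complex (the ligand and every other
#' atom act as occluders).  Extrema over frames are attached.
#'
#' @param traj A `pd_trajectory`.
#' @param chain,res_seq Residue identity in the topology.
#' @param table A [radii_table()].
#' @param n_points Lattice points per atom.
#' @param ignore_h If `TRUE`, hydrogens are dropped (with a warning) both as
#'   targets and occluders; by default hydrogens present in the topology are
#'   included.
#' @return An object of class `sasa_series`: `residue`, per-frame `values`
#'   (Angstrom^2), `min`, `max`, `times`.
#' @export
residue_sasa_series <- function(traj, chain, res_seq, table = radii_table(),
                                n_points = 960L, ignore_h = FALSE) {
  stopifnot(inherits(traj, "pd_trajectory"))
  topo <- traj$topology
  a <- topo$atoms
  res_idx <- which(a$chain == chain & a$res_seq == res_seq)
  if (length(res_idx) == 0L)
    stop("residue ", residue_key(chain, res_seq), " not found in topology")
  keep <- seq_len(nrow(a))
  if (ignore_h) {
    warning("ignoring ", sum(a$element == "H"), " hydrogen atoms in SASA")
    keep <- which(a$element != "H")
    res_idx <- intersect(res_idx, keep)
    if (length(res_idx) == 0L) stop("residue has no heavy atoms")
  }
  r <- atom_radii(topo, table)[keep]
  sub <- match(res_idx, keep)
  vals <- vapply(traj$frames, function(fr) {
    sum(shrake_rupley(fr[keep, , drop = FALSE], r, table$probe, n_points,
                      subset = sub))
  }, numeric(1))
  structure(list(residue = list(chain = chain, res_seq = res_seq,
                                res_name = a$res_name[res_idx[1]]),
                 values = vals, min = min(vals), max = max(vals),
                 times = traj$times),
            class = "sasa_series")
}

#' @export
print.sasa_series <- function(x, ...) {
  cat(sprintf("<sasa_series> %s: %d frames, [%.2f, %.2f] A^2\n",
              residue_key(x$residue$chain, x$residue$res_seq,
                          x$residue$res_name),
              length(x$values), x$min, x$max))
  invisible(x)
}
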