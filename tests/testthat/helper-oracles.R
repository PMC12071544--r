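# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by brute force / direct definition,
# sharing no code with the implementation paths they check.

# Direct Shrake-Rupley reference: no neighbour pruning, plain point-in-sphere
# test over every other atom, same deterministic lattice.
brute_sasa <- function(coords, radii, probe = 1.4, n_points = 960L) {
  pts <- pocketdyn:::fibonacci_sphere(n_points)
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    acc <- 0L
    for (p in seq_len(n_points)) {
      pt <- coords[i, ] + R * pts[p, ]
      buried <- FALSE
      for (j in seq_len(n)) {
        if (j == i) next
        if (sum((pt - coords[j, ])^2) <= (radii[j] + probe)^2) {
          buried <- TRUE; break
        }
      }
      if (!buried) acc <- acc + 1L
    }
    out[i] <- 4 * pi * R^2 * acc / n_points
  }
  out
}

# Brute-force minimum RMSD over a grid of Euler-angle rotations (optimal
# translation is always centroid matching).
grid_min_rmsd <- function(mobile, reference, n_angles = 24L) {
  angs <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  tilts <- seq(0, pi, length.out = n_angles %/% 2L)
  Xc <- sweep(mobile, 2, colMeans(mobile))
  Yc <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  best <- Inf
  for (a in angs) for (b in tilts) for (c in angs) {
    v <- sqrt(mean(rowSums((Xc %*% t(rot(a, b, c)) - Yc)^2)))
    if (v < best) best <- v
  }
  best
}

# Rotation by `deg` degrees about the z axis.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# Minimal structure/trajectory builders (internal constructors are the
# cleanest way to assemble hand-made geometry in tests).
make_structure <- function(names, elements, xyz, res_name = "GLY",
                           res_seq = NULL, chain = "A", hetero = FALSE) {
  n <- length(names)
  atoms <- data.frame(serial = seq_len(n), name = names, element = elements,
                      res_name = rep_len(res_name, n),
                      res_seq = if (is.null(res_seq)) rep(1L, n)
                                else rep_len(res_seq, n),
                      chain = rep_len(chain, n),
                      is_hetero = rep_len(hetero, n),
                      stringsAsFactors = FALSE)
  pocketdyn:::new_structure(atoms, xyz)
}

make_traj <- function(topology, frames, times = seq_along(frames) - 1) {
  pocketdyn:::new_trajectory(topology, frames, times)
}

# Fixed-column PDB text for a tiny 2-residue peptide (full backbone) plus an
# optional 5-atom hetero ligand.  Used for parser/selection tests.
peptide_pdb_text <- function(with_ligand = FALSE, blank_elements = FALSE) {
  atom <- function(serial, name, res, seq, x, y, z, el, het = FALSE) {
    nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het) "HETATM" else "ATOM", serial, nm, res, "A", seq,
            x, y, z, 1, 0, if (blank_elements) "" else el)
  }
  lines <- c(
    atom(1, "N",  "ALA", 1, 0.0, 0.5, 0.0, "N"),
    atom(2, "CA", "ALA", 1, 1.4, 0.0, 0.0, "C"),
    atom(3, "C",  "ALA", 1, 2.6, 0.9, 0.0, "C"),
    atom(4, "O",  "ALA", 1, 2.6, 2.1, 0.3, "O"),
    atom(5, "N",  "GLY", 2, 3.8, 0.3, 0.0, "N"),
    atom(6, "CA", "GLY", 2, 5.1, 0.9, 0.0, "C"),
    atom(7, "C",  "GLY", 2, 6.3, 0.0, 0.2, "C"),
    atom(8, "O",  "GLY", 2, 6.3, -1.2, 0.1, "O"))
  if (with_ligand)
    lines <- c(lines,
               atom(9,  "C1", "LIG", 9, 0.0, 5.0, 0.0, "C", TRUE),
               atom(10, "O1", "LIG", 9, 1.2, 5.5, 0.0, "O", TRUE),
               atom(11, "C2", "LIG", 9, 2.0, 6.0, 1.0, "C", TRUE),
               atom(12, "N1", "LIG", 9, 3.0, 6.5, 0.5, "N", TRUE),
               atom(13, "C3", "LIG", 9, 4.0, 7.0, 0.0, "C", TRUE))
  c(lines, "END")
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Study-condition specs used by the discrimination checks: a quiet,
# persistent-bond complex versus a drifting, transient-bond one.
stable_spec <- function(seed, n_frames = 25L) {
  complex_spec(residue_sigma = 0.1, ligand_sigma = 0.1, ligand_drift = 0,
               n_frames = n_frames, seed = seed)
}

unstable_spec <- function(seed, n_frames = 25L) {
  complex_spec(residue_sigma = 0.1, ligand_sigma = 0.1, ligand_drift = 0.5,
               hbond_schedule = data.frame(index = c(5L, 12L, 19L), f = 0.1,
                                           pattern = "block"),
               n_frames = n_frames, seed = seed)
}

fast_config <- function(...) descriptor_config(n_points = 240L, ...)
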