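#' Geometric hydrogen-bond criteria
#'
#' Conventional criteria: donor-acceptor distance at most `max_da_distance`
#' and, when the donor's hydrogen is known, an H-D-A angle of at most
#' `max_hda_angle` degrees.  For structures without hydrogens the distance
#' criterion alone is applied, with `heavy_atom_fallback_distance` as cutoff.
#'
#' @param max_da_distance Donor-acceptor heavy-atom cutoff, Angstrom.
#' @param max_hda_angle Maximum H-D-A angle, degrees, in (0, 180).
#' @param heavy_atom_fallback_distance Cutoff used when no hydrogens exist.
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_hda_angle = 30,
                           heavy_atom_fallback_distance = 3.5) {
  if (max_da_distance <= 0 || heavy_atom_fallback_distance <= 0)
    stop("distance cutoffs must be positive")
  if (max_hda_angle <= 0 || max_hda_angle >= 180)
    stop("max_hda_angle must lie in (0, 180)")
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle,
                 heavy_atom_fallback_distance = heavy_atom_fallback_distance),
            class = "hbond_criteria")
}

#' Type donor and acceptor atoms within a group
#'
#' Donors are N/O/S atoms with at least one covalently attached hydrogen
#' (H within 1.2 Angstrom, same group); acceptors are N/O atoms.  If the
#' structure carries no hydrogens at all, every donor-capable N/O/S atom is
#' returned with an empty hydrogen list and `fallback = TRUE`, signalling
#' that downstream detection must use the heavy-atom distance criterion.
#'
#' @param structure A `pd_structure` (reference geometry used for H
#'   attachment).
#' @param group A `pd_selection` or integer vector of atom indices.
#' @return A list: `donors` (data frame `heavy` index + list-column
#'   `hydrogens`), `acceptors` (integer vector), `fallback` (logical).
#' @export
donors_acceptors <- function(structure, group) {
  stopifnot(inherits(structure, "pd_structure"))
  group <- as.integer(group)
  if (length(group) == 0L) stop("empty group")
  a <- structure$atoms
  xyz <- structure$xyz
  has_h_anywhere <- any(a$element == "H")
  heavy <- group[a$element[group] %in% c("N", "O", "S")]
  acceptors <- group[a$element[group] %in% c("N", "O")]
  if (!has_h_anywhere) {
    donors <- data.frame(heavy = heavy)
    donors$hydrogens <- replicate(length(heavy), integer(0), simplify = FALSE)
    return(list(donors = donors, acceptors = acceptors, fallback = TRUE))
  }
  h_idx <- group[a$element[group] == "H"]
  dlist <- lapply(heavy, function(i) {
    if (length(h_idx) == 0L) return(integer(0))
    d2 <- rowSums(sweep(xyz[h_idx, , drop = FALSE], 2, xyz[i, ])^2)
    h_idx[d2 <= 1.2^2]
  })
  keep <- lengths(dlist) > 0L
  donors <- data.frame(heavy = heavy[keep])
  donors$hydrogens <- dlist[keep]
  list(donors = donors, acceptors = acceptors, fallback = FALSE)
}

# Angle at D between D->H and D->A, degrees.
.hda_angle <- function(D, H, A) {
  u <- H - D; v <- A - D
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds between a donor list and an acceptor list
#'
#' A bond is reported iff the donor-acceptor distance is within the cutoff
#' and, when the donor has hydrogens, at least one gives an H-D-A angle
#' within the angular cutoff.  Donors without hydrogens (heavy-atom-only
#' structures) are judged on the fallback distance alone.
#'
#' @param coords n x 3 frame coordinates (topology order).
#' @param donors,acceptors Output fields of [donors_acceptors()] — typically
#'   one side's donors against the other side's acceptors.
#' @param criteria An [hbond_criteria()].
#' @return Data frame with columns `donor`, `hydrogen` (NA in fallback mode),
#'   `acceptor`, `distance`, `angle` (NA in fallback mode).
#' @export
detect_hbonds <- function(coords, donors, acceptors, criteria = hbond_criteria()) {
  out <- list()
  if (nrow(donors) == 0L || length(acceptors) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  acc_xyz <- coords[acceptors, , drop = FALSE]
  for (di in seq_len(nrow(donors))) {
    D <- donors$heavy[di]
    hyd <- donors$hydrogens[[di]]
    d <- sqrt(rowSums(sweep(acc_xyz, 2, coords[D, ])^2))
    cutoff <- if (length(hyd)) criteria$max_da_distance
              else criteria$heavy_atom_fallback_distance
    cand <- which(d <= cutoff & acceptors != D)
    for (ai in cand) {
      A <- acceptors[ai]
      if (length(hyd) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          donor = D, hydrogen = NA_integer_, acceptor = A,
          distance = d[ai], angle = NA_real_)
      } else {
        ang <- vapply(hyd, function(h)
          .hda_angle(coords[D, ], coords[h, ], coords[A, ]), numeric(1))
        best <- which.min(ang)
        if (ang[best] <= criteria$max_hda_angle)
          out[[length(out) + 1L]] <- data.frame(
            donor = D, hydrogen = hyd[best], acceptor = A,
            distance = d[ai], angle = ang[best])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

# All protein-ligand H-bonds in one frame: union of both donor/acceptor
# directions, annotated with the protein-side residue.
hbonds_between <- function(structure, coords, protein_sel, ligand_sel,
                           criteria = hbond_criteria(),
                           da_protein = NULL, da_ligand = NULL) {
  if (is.null(da_protein)) da_protein <- donors_acceptors(structure, protein_sel)
  if (is.null(da_ligand)) da_ligand <- donors_acceptors(structure, ligand_sel)
  b1 <- detect_hbonds(coords, da_protein$donors, da_ligand$acceptors, criteria)
  b2 <- detect_hbonds(coords, da_ligand$donors, da_protein$acceptors, criteria)
  if (nrow(b1)) b1$protein_atom <- b1$donor
  if (nrow(b2)) b2$protein_atom <- b2$acceptor
  bonds <- rbind(b1, b2)
  if (nrow(bonds) == 0L) {
    bonds$protein_atom <- integer(0)
    bonds$chain <- character(0); bonds$res_seq <- integer(0)
    bonds$res_name <- character(0)
    return(bonds)
  }
  a <- structure$atoms
  bonds$chain <- a$chain[bonds$protein_atom]
  bonds$res_seq <- a$res_seq[bonds$protein_atom]
  bonds$res_name <- a$res_name[bonds$protein_atom]
  bonds
}

#' Optional hydrophobic-contact detector
#'
#' Apolar (carbon) heavy-atom pairs across the protein/ligand divide within
#' `cutoff` Angstrom.  Off by default in binding-residue identification; the
#' pipeline's descriptors are hydrogen-bond-centric.
#'
#' @param structure A `pd_structure`.
#' @param coords Frame coordinates.
#' @param protein_sel,ligand_sel Atom selections for the two sides.
#' @param cutoff Contact cutoff, Angstrom (default 4.0).
#' @return Data frame `protein_atom`, `ligand_atom`, `distance`, `chain`,
#'   `res_seq`, `res_name`.
#' @export
hydrophobic_contacts <- function(structure, coords, protein_sel, ligand_sel,
                                 cutoff = 4.0) {
  a <- structure$atoms
  p <- as.integer(protein_sel); l <- as.integer(ligand_sel)
  p <- p[a$element[p] == "C"]; l <- l[a$element[l] == "C"]
  if (length(p) == 0L || length(l) == 0L)
    return(data.frame(protein_atom = integer(0), ligand_atom = integer(0),
                      distance = numeric(0), chain = character(0),
                      res_seq = integer(0), res_name = character(0)))
  hits <- list()
  for (i in p) {
    d <- sqrt(rowSums(sweep(coords[l, , drop = FALSE], 2, coords[i, ])^2))
    for (k in which(d <= cutoff))
      hits[[length(hits) + 1L]] <- data.frame(
        protein_atom = i, ligand_atom = l[k], distance = d[k],
        chain = a$chain[i], res_seq = a$res_seq[i], res_name = a$res_name[i])
  }
  if (length(hits) == 0L)
    return(data.frame(protein_atom = integer(0), ligand_atom = integer(0),
                      distance = numeric(0), chain = character(0),
                      res_seq = integer(0), res_name = character(0)))
  do.call(rbind, hits)
}

#' Identify binding residues
#'
#' Protein residues with at least one detected hydrogen bond to the ligand in
#' any of the first `window` frames (default: the first frame, i.e. the
#' prepared pose; pass `window = n_frames(traj)` for a full-trajectory
#' union).  Residues are returned in deterministic (chain, res_seq) order.
#'
#' @param traj A `pd_trajectory`.
#' @param ligand_resname Ligand residue name.
#' @param criteria An [hbond_criteria()].
#' @param window Number of leading frames whose bonds are pooled.
#' @param enable_hydrophobic Also admit residues making hydrophobic contacts.
#' @return Data frame `chain`, `res_seq`, `res_name` (possibly empty, with a
#'   warning).
#' @export
identify_binding_residues <- function(traj, ligand_resname,
                                      criteria = hbond_criteria(),
                                      window = 1L,
                                      enable_hydrophobic = FALSE) {
  stopifnot(inherits(traj, "pd_trajectory"))
  topo <- traj$topology
  ligand_sel <- select_atoms(topo, "ligand", resname = ligand_resname)
  protein_sel <- select_atoms(topo, "protein")
  da_p <- donors_acceptors(topo, protein_sel)
  da_l <- donors_acceptors(topo, ligand_sel)
  window <- min(as.integer(window), n_frames(traj))
  res <- list()
  for (k in seq_len(window)) {
    bonds <- hbonds_between(topo, traj$frames[[k]], protein_sel, ligand_sel,
                            criteria, da_p, da_l)
    if (nrow(bonds))
      res[[length(res) + 1L]] <- bonds[, c("chain", "res_seq", "res_name")]
    if (enable_hydrophobic) {
      hc <- hydrophobic_contacts(topo, traj$frames[[k]], protein_sel, ligand_sel)
      if (nrow(hc))
        res[[length(res) + 1L]] <- hc[, c("chain", "res_seq", "res_name")]
    }
  }
  if (length(res) == 0L) {
    warning("no binding residues found within the identification window")
    return(data.frame(chain = character(0), res_seq = integer(0),
                      res_name = character(0)))
  }
  u <- unique(do.call(rbind, res))
  u <- u[order(u$chain, u$res_seq), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Hydrogen-bond existence matrix
#'
#' One row per donor-acceptor atom pair ever observed between the binding
#' residues and the ligand; entry `[p, f]` is `TRUE` iff pair `p` satisfies
#' the geometric criteria in frame `f`.
#'
#' @param traj A `pd_trajectory`.
#' @param binding_residues Data frame `chain`, `res_seq` (from
#'   [identify_binding_residues()]).
#' @param ligand_resname Ligand residue name.
#' @param criteria An [hbond_criteria()].
#' @return An `existence_matrix` object: `pairs` (data frame `donor`,
#'   `acceptor`, `chain`, `res_seq`, `res_name`, `label`), logical matrix
#'   `present` (pairs x frames), and `times`.
#' @export
existence_matrix <- function(traj, binding_residues, ligand_resname,
                             criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "pd_trajectory"))
  if (nrow(binding_residues) == 0L) stop("no binding residues supplied")
  topo <- traj$topology
  ligand_sel <- select_atoms(topo, "ligand", resname = ligand_resname)
  res_sel <- select_atoms(topo, "residues", residues = binding_residues)
  da_p <- donors_acceptors(topo, res_sel)
  da_l <- donors_acceptors(topo, ligand_sel)
  nf <- n_frames(traj)
  per_frame <- vector("list", nf)
  for (k in seq_len(nf)) {
    b <- hbonds_between(topo, traj$frames[[k]], res_sel, ligand_sel,
                        criteria, da_p, da_l)
    per_frame[[k]] <- b
  }
  all_bonds <- do.call(rbind, per_frame)
  if (is.null(all_bonds) || nrow(all_bonds) == 0L)
    stop("no hydrogen bond was ever observed for the supplied residues")
  pairs <- unique(all_bonds[, c("donor", "acceptor", "chain", "res_seq",
                                "res_name")])
  pairs <- pairs[order(pairs$donor, pairs$acceptor), , drop = FALSE]
  rownames(pairs) <- NULL
  a <- topo$atoms
  pairs$label <- sprintf("%s|D%d(%s)-A%d(%s)",
                         residue_key(pairs$chain, pairs$res_seq, pairs$res_name),
                         pairs$donor, a$name[pairs$donor],
                         pairs$acceptor, a$name[pairs$acceptor])
  key <- paste(pairs$donor, pairs$acceptor)
  present <- matrix(FALSE, nrow(pairs), nf,
                    dimnames = list(pairs$label, NULL))
  for (k in seq_len(nf)) {
    b <- per_frame[[k]]
    if (nrow(b)) present[match(paste(b$donor, b$acceptor), key), k] <- TRUE
  }
  structure(list(pairs = pairs, present = present, times = traj$times),
            class = "existence_matrix")
}

#' @export
print.existence_matrix <- function(x, ...) {
  cat(sprintf("<existence_matrix> %d donor-acceptor pairs x %d frames\n",
              nrow(x$present), ncol(x$present)))
  invisible(x)
}

# Time per frame; 1 for a single-frame run.
.frame_dt <- function(times) {
  if (length(times) < 2L) 1 else stats::median(diff(times))
}

#' Hydrogen-bond occupancy of one residue
#'
#' A residue is occupied in a frame iff ANY of its donor-acceptor pairs is
#' present (the union over pairs, not the best single pair).  The existence
#' time is the number of occupied frames times the frame duration; the
#' fraction is occupied frames over total frames.
#'
#' @param matrix An [existence_matrix()].
#' @param chain,res_seq Residue identity.
#' @return An `occupancy_record` list: `residue`, `existence_time`,
#'   `fraction`, `cluster`.
#' @export
residue_occupancy <- function(matrix, chain, res_seq) {
  stopifnot(inherits(matrix, "existence_matrix"))
  rows <- which(matrix$pairs$chain == chain & matrix$pairs$res_seq == res_seq)
  if (length(rows) == 0L)
    stop("residue ", residue_key(chain, res_seq),
         " owns no pair in the existence matrix")
  any_on <- colSums(matrix$present[rows, , drop = FALSE]) > 0
  frac <- mean(any_on)
  dt <- .frame_dt(matrix$times)
  structure(list(residue = list(chain = chain, res_seq = res_seq,
                                res_name = matrix$pairs$res_name[rows[1]]),
                 existence_time = sum(any_on) * dt,
                 fraction = frac,
                 cluster = classify_occupancy(frac)),
            class = "occupancy_record")
}

#' Classify an occupancy fraction into the three clusters
#'
#' Low for fractions up to 0.30, moderate above 0.30 up to 0.70, high above
#' 0.70 (boundaries lower-inclusive).  On a 100-frame ~ 100 ns run this
#' reproduces the 0-30 / 31-70 / 71-100 ns bins.
#'
#' @param fraction Numeric vector of fractions in `[0, 1]`.
#' @return Character vector with values `"low"`, `"moderate"`, `"high"`.
#' @export
classify_occupancy <- function(fraction) {
  if (any(fraction < 0 | fraction > 1 | is.na(fraction)))
    stop("occupancy fraction must lie in [0, 1]")
  ifelse(fraction <= 0.30, "low",
         ifelse(fraction <= 0.70, "moderate", "high"))
}

#' Occupancy table for every residue in an existence matrix
#'
#' @param matrix An [existence_matrix()].
#' @return Data frame `chain`, `res_seq`, `res_name`, `existence_time`,
#'   `fraction`, `cluster`, one row per residue owning at least one pair.
#' @export
occupancy_table <- function(matrix) {
  stopifnot(inherits(matrix, "existence_matrix"))
  u <- unique(matrix$pairs[, c("chain", "res_seq", "res_name")])
  u <- u[order(u$chain, u$res_seq), , drop = FALSE]
  recs <- lapply(seq_len(nrow(u)), function(i)
    residue_occupancy(matrix, u$chain[i], u$res_seq[i]))
  data.frame(chain = u$chain, res_seq = u$res_seq, res_name = u$res_name,
             existence_time = vapply(recs, `[[`, numeric(1), "existence_time"),
             fraction = vapply(recs, `[[`, numeric(1), "fraction"),
             cluster = vapply(recs, `[[`, character(1), "cluster"),
             row.names = NULL)
}
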