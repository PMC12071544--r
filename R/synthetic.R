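.aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")

#' Specification of a synthetic protein-ligand MD complex
#'
#' Describes a pseudo-complex with known ground truth: a backbone-complete
#' polypeptide laid on an open arc, pocket residues carrying one
#' donor-capable side-chain hydroxyl pseudo-atom pointing at the ligand,
#' and a ligand made of one acceptor oxygen per pocket residue plus apolar
#' scaffold carbons.  Hydrogen-bond geometry is scheduled per pocket residue
#' so that the bond exists in exactly a target fraction of frames.
#'
#' @param n_residues Number of protein residues (>= 4).
#' @param pocket Data frame `index` (residue index), `res_name`; defaults to
#'   three charged residues typical of real pockets.
#' @param residue_sigma Per-atom Gaussian jitter of protein atoms, Angstrom
#'   (scalar or per-residue vector).
#' @param ligand_atoms Total ligand atoms (>= number of pocket residues).
#' @param ligand_sigma Jitter of ligand atoms, Angstrom.
#' @param ligand_drift Cumulative ligand displacement per frame, Angstrom
#'   (0 = stable pose; positive values emulate a ligand leaving the pocket).
#' @param hbond_schedule Data frame `index`, `f` (target occupancy fraction
#'   in `[0, 1]`), `pattern` (`"block"`, `"periodic"` or `"random"`); default
#'   `f = 0.9`, block, for every pocket residue.
#' @param n_frames Number of trajectory frames (>= 1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `complex_spec` list.
#' @export
complex_spec <- function(n_residues = 30L,
                         pocket = data.frame(index = c(5L, 12L, 19L),
                                             res_name = c("ASP", "HIS", "ARG")),
                         residue_sigma = 0.25,
                         ligand_atoms = nrow(pocket) + 2L,
                         ligand_sigma = 0.15,
                         ligand_drift = 0,
                         hbond_schedule = data.frame(index = pocket$index,
                                                     f = 0.9,
                                                     pattern = "block"),
                         n_frames = 100L,
                         seed = 1L) {
  if (n_residues < 4L) stop("need at least 4 residues")
  if (any(pocket$index < 1L | pocket$index > n_residues))
    stop("pocket residue indices out of range")
  if (anyDuplicated(pocket$index)) stop("duplicate pocket residue indices")
  if (ligand_atoms < nrow(pocket))
    stop("infeasible geometry: pocket residue count exceeds ligand capacity")
  if (any(hbond_schedule$f < 0 | hbond_schedule$f > 1))
    stop("scheduled occupancy fractions must lie in [0, 1]")
  if (!all(hbond_schedule$index %in% pocket$index))
    stop("hbond_schedule refers to non-pocket residues")
  if (!all(hbond_schedule$pattern %in% c("block", "periodic", "random")))
    stop("pattern must be block, periodic or random")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(n_residues = as.integer(n_residues), pocket = pocket,
                 residue_sigma = residue_sigma,
                 ligand_atoms = as.integer(ligand_atoms),
                 ligand_sigma = ligand_sigma, ligand_drift = ligand_drift,
                 hbond_schedule = hbond_schedule,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "complex_spec")
}

# Frames (1-based) in which a scheduled bond exists.
.schedule_frames <- function(f, pattern, nf) {
  n_on <- round(f * nf)
  if (n_on == 0L) return(integer(0))
  switch(pattern,
         block = seq_len(n_on),
         periodic = {
           fr <- n_on / nf
           which(diff(floor((0:nf) * fr)) == 1)
         },
         random = sort(sample.int(nf, n_on)))
}

#' Generate a synthetic complex with known ground truth
#'
#' Builds the reference structure described in [complex_spec()], then frames
#' as reference plus per-atom Gaussian jitter (and cumulative ligand drift
#' along z if configured).  Schedule-critical atoms are placed after jitter:
#' the pocket side-chain donor is jittered (sigma capped at 0.2 Angstrom),
#' its ligand partner is then set at exactly 2.8 Angstrom along the pocket
#' axis in bonded frames (6.0 Angstrom, or its drifted free position if
#' farther, in unbonded frames), and the donor hydrogen sits on the
#' donor-acceptor axis — so the realised occupancy of every scheduled
#' residue matches its schedule exactly, which the recovery tests rely on.
#'
#' @param spec A [complex_spec()].
#' @return A list `structure` (`pd_structure` reference), `trajectory`
#'   (`pd_trajectory`), `truth` (data frame per pocket residue: `chain`,
#'   `res_seq`, `res_name`, `f_target`, `f_actual`, `cluster`, `sigma`;
#'   attribute `ligand_label` is `"stable"` or `"unstable"`).
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  nf <- spec$n_frames
  sig <- rep_len(spec$residue_sigma, n)

  # open-arc backbone, 3.8 A CA spacing
  Rc <- max(25, n * 3.8 / (1.5 * pi))
  theta <- (seq_len(n) - 1) * 3.8 / Rc
  ca <- cbind(Rc * cos(theta), Rc * sin(theta), 0)
  tv <- cbind(-sin(theta), cos(theta), 0)        # tangent
  nin <- cbind(-cos(theta), -sin(theta), 0)      # inward normal
  zv <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)

  pocket_idx <- spec$pocket$index
  is_pocket <- seq_len(n) %in% pocket_idx
  res_names <- rep_len(.aa20, n)
  res_names[pocket_idx] <- spec$pocket$res_name

  atoms <- list(); xyz <- list(); res_of_atom <- integer(0)
  og_atom <- hg_atom <- stats::setNames(integer(length(pocket_idx)),
                                        as.character(pocket_idx))
  serial <- 0L
  add <- function(name, element, rn, rs, chain, het, coord) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(serial = serial, name = name,
                                   element = element, res_name = rn,
                                   res_seq = rs, chain = chain,
                                   is_hetero = het)
    xyz[[serial]] <<- coord
    serial
  }
  for (i in seq_len(n)) {
    add("N", "N", res_names[i], i, "A", FALSE, ca[i, ] - 1.2 * tv[i, ] + 0.5 * zv[i, ])
    add("CA", "C", res_names[i], i, "A", FALSE, ca[i, ])
    add("C", "C", res_names[i], i, "A", FALSE, ca[i, ] + 1.2 * tv[i, ] + 0.5 * zv[i, ])
    add("O", "O", res_names[i], i, "A", FALSE, ca[i, ] + 1.2 * tv[i, ] + 0.5 * zv[i, ] + 1.23 * zv[i, ])
    if (is_pocket[i]) {
      # one donor-capable side-chain pseudo-atom (hydroxyl) per pocket
      # residue, pointing at the ligand
      k <- as.character(i)
      og_atom[k] <- add("OG", "O", res_names[i], i, "A", FALSE,
                        ca[i, ] + 3.5 * nin[i, ])
      hg_atom[k] <- add("HG", "H", res_names[i], i, "A", FALSE,
                        ca[i, ] + (3.5 + 0.96) * nin[i, ])
    }
  }
  partner_atom <- stats::setNames(integer(length(pocket_idx)),
                                  as.character(pocket_idx))
  for (j in seq_along(pocket_idx)) {
    i <- pocket_idx[j]
    partner_atom[as.character(i)] <-
      add(sprintf("O%d", j), "O", "LIG", 1L, "L", TRUE, ca[i, ] + 6.3 * nin[i, ])
  }
  n_extra <- spec$ligand_atoms - length(pocket_idx)
  if (n_extra > 0L) {
    centroid <- colMeans(do.call(rbind, xyz[partner_atom]))
    for (j in seq_len(n_extra)) {
      ang <- 2 * pi * (j - 1) / n_extra
      add(sprintf("C%d", j), "C", "LIG", 1L, "L", TRUE,
          centroid + c(2 * cos(ang), 2 * sin(ang), 3.5))
    }
  }
  atoms <- do.call(rbind, atoms)
  ref_xyz <- do.call(rbind, xyz)
  topo <- new_structure(atoms, ref_xyz)

  # per-residue bond schedules
  sched <- spec$hbond_schedule
  on_frames <- list(); f_actual <- stats::setNames(numeric(0), character(0))
  for (i in pocket_idx) {
    row <- sched[sched$index == i, ]
    if (nrow(row) == 0L) {
      on_frames[[as.character(i)]] <- integer(0)
      f_actual[as.character(i)] <- 0
    } else {
      fr <- .schedule_frames(row$f[1], row$pattern[1], nf)
      on_frames[[as.character(i)]] <- fr
      f_actual[as.character(i)] <- length(fr) / nf
    }
  }

  lig_mask <- atoms$is_hetero
  sigma_atom <- ifelse(lig_mask, spec$ligand_sigma, sig[pmin(atoms$res_seq, n)])
  sigma_atom[og_atom] <- pmin(sigma_atom[og_atom], 0.2)

  frames <- vector("list", nf)
  for (fidx in seq_len(nf)) {
    jit <- matrix(stats::rnorm(length(sigma_atom) * 3), ncol = 3) * sigma_atom
    fx <- ref_xyz + jit
    drift <- c(0, 0, spec$ligand_drift * (fidx - 1))
    fx[lig_mask, ] <- sweep(fx[lig_mask, , drop = FALSE], 2, drift, "+")
    for (i in pocket_idx) {
      k <- as.character(i)
      og <- fx[og_atom[k], ]
      u <- nin[i, ]
      if (fidx %in% on_frames[[k]]) {
        fx[partner_atom[k], ] <- og + 2.8 * u
        fx[hg_atom[k], ] <- og + 0.96 * u
      } else {
        cand <- fx[partner_atom[k], ]         # jittered + drifted free position
        if (sqrt(sum((cand - og)^2)) < 3.6) cand <- og + 6.0 * u
        fx[partner_atom[k], ] <- cand
        v <- cand - og
        fx[hg_atom[k], ] <- og + 0.96 * v / sqrt(sum(v * v))
      }
    }
    frames[[fidx]] <- fx
  }
  traj <- new_trajectory(topo, frames, seq_len(nf) - 1)

  truth <- data.frame(chain = "A", res_seq = pocket_idx,
                      res_name = res_names[pocket_idx],
                      f_target = vapply(as.character(pocket_idx), function(k) {
                        row <- sched[sched$index == as.integer(k), ]
                        if (nrow(row)) row$f[1] else 0
                      }, numeric(1)),
                      f_actual = unname(f_actual[as.character(pocket_idx)]),
                      sigma = sig[pocket_idx],
                      row.names = NULL)
  truth$cluster <- classify_occupancy(truth$f_actual)
  attr(truth, "ligand_label") <- if (spec$ligand_drift > 0) "unstable" else "stable"
  list(structure = topo, trajectory = traj, truth = truth)
}

#' Generate a reproducible cohort of synthetic complexes
#'
#' Each complex gets its own seed derived from the cohort seed and its index
#' (a counter-based scheme), so cohorts are reproducible and individual
#' complexes can be regenerated independently of generation order.
#'
#' @param n_complexes Number of complexes (>= 1).
#' @param spec_sampler Either a fixed [complex_spec()] (complexes then differ
#'   only by jitter realisation) or a `function(i)` returning the spec for
#'   complex `i` (its `seed` field is overridden by the derived seed).
#' @param seed Cohort seed.
#' @return List of `generate_complex()` results.
#' @export
generate_cohort <- function(n_complexes, spec_sampler, seed = 1L) {
  if (n_complexes < 1L) stop("n_complexes must be >= 1")
  lapply(seq_len(n_complexes), function(i) {
    spec <- if (is.function(spec_sampler)) spec_sampler(i) else spec_sampler
    spec$seed <- as.integer((as.numeric(seed) * 1000003 + i * 9973) %% 2147483629)
    generate_complex(spec)
  })
}
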