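#' Configuration for per-complex descriptor computation
#'
#' @param criteria Hydrogen-bond criteria ([hbond_criteria()]).
#' @param radii SASA radii table ([radii_table()]).
#' @param n_points SASA lattice points per atom.
#' @param id_window Leading frames pooled for binding-residue identification.
#' @param reference_frame Reference frame (1-based) for RMSD fitting.
#' @param enable_hydrophobic Admit hydrophobic contacts when identifying
#'   binding residues.
#' @param ignore_h Drop hydrogens in SASA.
#' @return A `descriptor_config` list.
#' @export
descriptor_config <- function(criteria = hbond_criteria(),
                              radii = radii_table(),
                              n_points = 960L,
                              id_window = 1L,
                              reference_frame = 1L,
                              enable_hydrophobic = FALSE,
                              ignore_h = FALSE) {
  structure(list(criteria = criteria, radii = radii, n_points = n_points,
                 id_window = id_window, reference_frame = reference_frame,
                 enable_hydrophobic = enable_hydrophobic,
                 ignore_h = ignore_h),
            class = "descriptor_config")
}

#' Full per-complex descriptor set
#'
#' Orchestrates the analysis of one complex: binding-residue identification,
#' backbone / per-binding-residue-backbone / ligand RMSD series (all measured
#' in the frame defined by the protein-backbone fit), per-residue fluctuation
#' ranges, per-residue SASA extrema, and the hydrogen-bond existence matrix
#' with per-residue occupancy classification.
#'
#' @param traj A `pd_trajectory`.
#' @param ligand_resname Ligand residue name.
#' @param config A [descriptor_config()].
#' @param complex_id Identifier carried into reports.
#' @return A `complex_descriptors` object: `complex_id`, `backbone_rmsd` and
#'   `ligand_rmsd` (`rmsd_series` + `fluctuation_range`), `residues` (one row
#'   per binding residue: RMSD min/max/range/median, SASA min/max, occupancy
#'   fraction/time/cluster), `existence` (the matrix), `residue_series`
#'   (per-residue `rmsd_series` and `sasa_series`), `pocket_sasa` (the
#'   binding-residue group's per-frame SASA with its extrema — the
#'   solvent-exposure readout of the pocket as a whole), and a
#'   `no_binding_residues` flag.
#' @export
complex_descriptors <- function(traj, ligand_resname,
                                config = descriptor_config(),
                                complex_id = "complex") {
  stopifnot(inherits(traj, "pd_trajectory"))
  topo <- traj$topology
  backbone <- select_atoms(topo, "backbone")
  ligand <- select_atoms(topo, "ligand", resname = ligand_resname)

  binding <- identify_binding_residues(traj, ligand_resname, config$criteria,
                                       window = config$id_window,
                                       enable_hydrophobic = config$enable_hydrophobic)

  bb_series <- rmsd_series(traj, backbone, backbone, config$reference_frame)
  lig_series <- rmsd_series(traj, backbone, ligand, config$reference_frame)

  out <- list(complex_id = complex_id,
              backbone_rmsd = list(series = bb_series,
                                   fluctuation = fluctuation_range(bb_series)),
              ligand_rmsd = list(series = lig_series,
                                 fluctuation = fluctuation_range(lig_series)),
              residues = data.frame(),
              residue_series = list(),
              existence = NULL,
              no_binding_residues = nrow(binding) == 0L)

  if (nrow(binding) == 0L) {
    class(out) <- "complex_descriptors"
    return(out)
  }

  emat <- existence_matrix(traj, binding, ligand_resname, config$criteria)
  occ <- occupancy_table(emat)

  rows <- vector("list", nrow(binding))
  series <- vector("list", nrow(binding))
  for (i in seq_len(nrow(binding))) {
    res <- binding[i, ]
    rb <- select_atoms(topo, "residue_backbone", residues = res)
    rs <- rmsd_series(traj, backbone, rb, config$reference_frame)
    fr <- fluctuation_range(rs)
    ss <- residue_sasa_series(traj, res$chain, res$res_seq, config$radii,
                              config$n_points, config$ignore_h)
    o <- occ[occ$chain == res$chain & occ$res_seq == res$res_seq, ]
    rows[[i]] <- data.frame(
      chain = res$chain, res_seq = res$res_seq, res_name = res$res_name,
      rmsd_min = fr$min, rmsd_max = fr$max, rmsd_range = fr$range,
      rmsd_median = stats::median(rs$values),
      sasa_min = ss$min, sasa_max = ss$max,
      occupancy_fraction = if (nrow(o)) o$fraction else 0,
      existence_time = if (nrow(o)) o$existence_time else 0,
      cluster = if (nrow(o)) o$cluster else "low")
    series[[i]] <- list(rmsd = rs, sasa = ss)
  }
  out$residues <- do.call(rbind, rows)
  out$residue_series <- series
  out$existence <- emat
  # SASA is per-atom additive, so the binding-residue group's per-frame SASA
  # is the sum of the residue series; its extrema are the complex's pocket
  # solvent-exposure descriptor (the quantity a trajectory tool reports for
  # a binding-residue index group)
  group <- Reduce(`+`, lapply(series, function(s) s$sasa$values))
  out$pocket_sasa <- list(values = group, min = min(group), max = max(group))
  class(out) <- "complex_descriptors"
  out
}

#' @export
print.complex_descriptors <- function(x, ...) {
  cat(sprintf("<complex_descriptors> %s: %d binding residues\n",
              x$complex_id, nrow(x$residues)))
  cat(sprintf("  backbone RMSD median %.3f A; ligand RMSD median %.3f A\n",
              stats::median(x$backbone_rmsd$series$values),
              stats::median(x$ligand_rmsd$series$values)))
  if (nrow(x$residues))
    cat(sprintf("  occupancy clusters: %s\n",
                paste(names(table(x$residues$cluster)),
                      table(x$residues$cluster), sep = "=", collapse = " ")))
  invisible(x)
}

#' Box-plot summary statistics
#'
#' Quartiles by linear interpolation of the sorted sample at positions
#' `(n - 1) * p` (the type-7 rule, R's default).  Outliers are values outside
#' the Tukey whiskers `[q1 - 1.5 IQR, q3 + 1.5 IQR]`.  The semi-interquartile
#' distances are `siqr_l = median - q1` and `siqr_r = q3 - median`.
#'
#' @param values Numeric vector, n >= 1.
#' @return A `box_stats` list: `median`, `q1`, `q3`, `iqr`, `siqr_l`,
#'   `siqr_r`, `outliers`, `n`.
#' @export
box_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(is.na(values)))
    stop("box_stats needs a non-empty numeric sample without NAs")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 siqr_l = q[2] - q[1], siqr_r = q[3] - q[2],
                 outliers = values[values < q[1] - 1.5 * iqr |
                                     values > q[3] + 1.5 * iqr],
                 n = length(values)),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("<box_stats> n=%d  median %.3f  Q1 %.3f  Q3 %.3f  IQR %.3f  (%d outliers)\n",
              x$n, x$median, x$q1, x$q3, x$iqr, length(x$outliers)))
  invisible(x)
}

#' Pooled binding-pocket residue composition
#'
#' Counts each residue identity once per complex (regardless of how many
#' hydrogen bonds it makes) and pools counts over the cohort by 3-letter
#' residue name.
#'
#' @param binding_residue_sets List of data frames (`chain`, `res_seq`,
#'   `res_name`), one per complex.
#' @return A `composition_table`: `counts` and `fractions` named by residue.
#' @export
pocket_composition <- function(binding_residue_sets) {
  if (length(binding_residue_sets) == 0L ||
      all(vapply(binding_residue_sets, nrow, 1L) == 0L))
    stop("no non-empty binding-residue set supplied")
  pooled <- do.call(rbind, lapply(binding_residue_sets, function(s)
    unique(s[, c("chain", "res_seq", "res_name")])))
  counts <- table(pooled$res_name)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, fractions = counts / sum(counts)),
            class = "composition_table")
}

#' Whole-protein background residue composition
#'
#' Counts every protein residue (hetero records and waters excluded) once,
#' pooled across the cohort's structures.
#'
#' @param structures List of `pd_structure` objects.
#' @return A `composition_table`.
#' @export
background_composition <- function(structures) {
  if (length(structures) == 0L) stop("no structures supplied")
  pooled <- lapply(structures, function(s) {
    r <- protein_residues(s)
    if (nrow(r) == 0L) stop("structure with no protein residues")
    r
  })
  pooled <- do.call(rbind, pooled)
  counts <- table(pooled$res_name)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, fractions = counts / sum(counts)),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  o <- order(-x$fractions)
  cat("<composition_table>",
      paste(sprintf("%s %.1f%%", names(x$fractions)[o],
                    100 * x$fractions[o]), collapse = "  "), "\n")
  invisible(x)
}

#' Physicochemical classes of the 20 standard amino acids
#'
#' Charged (including histidine), polar uncharged, and non-polar; the split
#' is configurable by passing a modified copy to [enrichment()].
#'
#' @return Named list of character vectors.
#' @export
default_class_map <- function() {
  list(charged = c("ASP", "GLU", "LYS", "ARG", "HIS"),
       polar_uncharged = c("SER", "THR", "ASN", "GLN", "CYS", "TYR"),
       non_polar = c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
                     "MET", "TRP"))
}

#' Pocket-versus-background residue enrichment
#'
#' Descriptive ratios (pocket fraction over background fraction) for every
#' residue name, with an exact two-sided binomial test of the pocket count
#' against the background fraction and Benjamini-Hochberg adjustment across
#' the tested residues.  Class fractions pool pocket counts via `class_map`.
#' The tests are an addition on top of the descriptive comparison and are
#' labelled as such in reports.
#'
#' @param pocket,background [pocket_composition()] /
#'   [background_composition()] tables; the background must cover every
#'   pocket residue name.
#' @param class_map Named list of residue-name vectors
#'   ([default_class_map()]).
#' @return An `enrichment_result`: data frame `table` (`res_name`,
#'   `pocket_count`, `pocket_fraction`, `background_fraction`, `ratio`,
#'   `p_value`, `p_adjusted`) and `class_fractions`.
#' @export
enrichment <- function(pocket, background, class_map = default_class_map()) {
  stopifnot(inherits(pocket, "composition_table"),
            inherits(background, "composition_table"))
  missing_bg <- setdiff(names(pocket$counts), names(background$fractions))
  if (length(missing_bg))
    stop("residue(s) absent from background composition: ",
         paste(missing_bg, collapse = ", "))
  tested <- sort(names(background$fractions))
  total <- sum(pocket$counts)
  cnt <- stats::setNames(rep(0L, length(tested)), tested)
  cnt[names(pocket$counts)] <- pocket$counts
  pf <- cnt / total
  bf <- background$fractions[tested]
  pv <- vapply(tested, function(r)
    stats::binom.test(cnt[[r]], total, p = bf[[r]],
                      alternative = "two.sided")$p.value, numeric(1))
  tab <- data.frame(res_name = tested,
                    pocket_count = as.integer(cnt),
                    pocket_fraction = as.numeric(pf),
                    background_fraction = as.numeric(bf),
                    ratio = as.numeric(pf / bf),
                    p_value = as.numeric(pv),
                    p_adjusted = as.numeric(stats::p.adjust(pv, "BH")),
                    row.names = NULL)
  cls <- vapply(class_map, function(members)
    sum(cnt[intersect(members, tested)]), numeric(1))
  classified <- sum(cls)
  structure(list(table = tab,
                 class_fractions = if (classified > 0) cls / classified
                                   else cls),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  top <- x$table[order(-x$table$ratio), ][1:min(5, nrow(x$table)), ]
  cat("<enrichment_result> top ratios:",
      paste(sprintf("%s %.2f", top$res_name, top$ratio), collapse = "  "), "\n")
  cat("  class fractions:",
      paste(sprintf("%s %.1f%%", names(x$class_fractions),
                    100 * x$class_fractions), collapse = "  "),
      "(binomial/BH tests are descriptive extras)\n")
  invisible(x)
}
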