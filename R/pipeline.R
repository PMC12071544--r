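#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `structure_path`+`trajectory_path` or `spec` must be
#' given: either analyse files on disk (reference PDB plus multi-model PDB or
#' XYZ-table trajectory) or a synthetic complex generated in memory.
#'
#' @param structure_path,trajectory_path Input files (or `NULL`).
#' @param spec A [complex_spec()] (or `NULL`).
#' @param ligand_resname Ligand residue name (default `"LIG"`).
#' @param config A [descriptor_config()].
#' @param reference A `benchmark_reference` (default [default_reference()]).
#' @param sasa_factor SASA unit conversion for [assess()].
#' @param stride Time per trajectory frame (see [read_trajectory()]).
#' @param outdir Output directory for reports (`NULL` = write nothing).
#' @param complex_id Identifier used in file names and reports.
#' @param seed Seed recorded in the manifest (and used by `spec` if set).
#' @return A `run_config` list.
#' @export
run_config <- function(structure_path = NULL, trajectory_path = NULL,
                       spec = NULL, ligand_resname = "LIG",
                       config = descriptor_config(),
                       reference = default_reference(), sasa_factor = 100,
                       stride = 1, outdir = NULL, complex_id = "complex",
                       seed = 1L) {
  from_files <- !is.null(structure_path) || !is.null(trajectory_path)
  if (from_files == !is.null(spec))
    stop("exactly one of {structure_path+trajectory_path, spec} must be given")
  if (from_files && (is.null(structure_path) || is.null(trajectory_path)))
    stop("both structure_path and trajectory_path are required for file input")
  structure(list(structure_path = structure_path,
                 trajectory_path = trajectory_path, spec = spec,
                 ligand_resname = ligand_resname, config = config,
                 reference = reference, sasa_factor = sasa_factor,
                 stride = stride, outdir = outdir, complex_id = complex_id,
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.load_complex <- function(rc) {
  if (!is.null(rc$spec)) {
    rc$spec$seed <- rc$seed
    g <- .stage("simulate", generate_complex(rc$spec))
    list(traj = g$trajectory, truth = g$truth)
  } else {
    topo <- .stage("read_structure", read_structure(rc$structure_path))
    traj <- .stage("read_trajectory",
                   read_trajectory(rc$trajectory_path, topo, rc$stride))
    list(traj = traj, truth = NULL)
  }
}

.write_manifest <- function(rc, outdir, extra = character(0)) {
  cfg <- rc$config
  writeLines(c(
    sprintf("pocketdyn_version = %s",
            as.character(utils::packageVersion("pocketdyn"))),
    sprintf("complex_id = %s", rc$complex_id),
    sprintf("seed = %d", rc$seed),
    sprintf("ligand_resname = %s", rc$ligand_resname),
    sprintf("da_cutoff_A = %g", cfg$criteria$max_da_distance),
    sprintf("hda_angle_deg = %g", cfg$criteria$max_hda_angle),
    sprintf("sasa_probe_A = %g", cfg$radii$probe),
    sprintf("sasa_n_points = %d", as.integer(cfg$n_points)),
    sprintf("id_window_frames = %d", as.integer(cfg$id_window)),
    sprintf("reference_frame = %d", as.integer(cfg$reference_frame)),
    sprintf("hydrophobic_contacts = %s", cfg$enable_hydrophobic),
    extra),
    file.path(outdir, paste0(rc$complex_id, "_manifest.txt")))
}

#' Analyse one complex end-to-end
#'
#' Loads (or generates) the complex, computes [complex_descriptors()], and —
#' if `outdir` is set — writes TSV reports: the backbone/ligand RMSD series,
#' the per-residue SASA series, the 0/1 existence matrix, the occupancy
#' table, the per-residue descriptor table, and a run manifest listing every
#' effective parameter.  Errors from any stage are re-raised with the failing
#' stage named.
#'
#' @param rc A [run_config()].
#' @return The `complex_descriptors` object (invisibly carries `truth` as an
#'   attribute for synthetic inputs).
#' @export
run_analyze <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  lc <- .load_complex(rc)
  desc <- .stage("descriptors",
                 complex_descriptors(lc$traj, rc$ligand_resname, rc$config,
                                     rc$complex_id))
  if (!is.null(rc$outdir)) {
    dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
    .stage("reports", {
      pre <- file.path(rc$outdir, rc$complex_id)
      write_table(data.frame(frame = seq_along(lc$traj$times),
                             time = lc$traj$times,
                             backbone_rmsd = desc$backbone_rmsd$series$values,
                             ligand_rmsd = desc$ligand_rmsd$series$values),
                  paste0(pre, "_rmsd_series.tsv"))
      if (nrow(desc$residues)) {
        sasa_long <- do.call(rbind, lapply(desc$residue_series, function(s)
          data.frame(residue = residue_key(s$sasa$residue$chain,
                                           s$sasa$residue$res_seq,
                                           s$sasa$residue$res_name),
                     frame = seq_along(s$sasa$values),
                     time = s$sasa$times,
                     sasa = s$sasa$values,
                     rmsd = s$rmsd$values)))
        write_table(sasa_long, paste0(pre, "_residue_series.tsv"))
        em <- desc$existence
        emdf <- data.frame(pair = em$pairs$label,
                           as.data.frame(em$present + 0L))
        names(emdf) <- c("pair", sprintf("f%d", seq_len(ncol(em$present))))
        write_table(emdf, paste0(pre, "_existence_matrix.tsv"))
        write_table(occupancy_table(em), paste0(pre, "_occupancy.tsv"))
        write_table(desc$residues, paste0(pre, "_descriptors.tsv"))
      }
      .write_manifest(rc, rc$outdir)
    })
  }
  attr(desc, "truth") <- lc$truth
  desc
}

#' Aggregate descriptors over a cohort
#'
#' Pools the per-residue RMSD fluctuation ranges, the per-complex ligand
#' RMSD fluctuation ranges, and the per-complex pocket-group SASA minima and
#' maxima over the cohort into [box_stats()];
#' computes the occupancy-cluster shares; and, when the cohort's structures
#' are supplied, the pocket composition, whole-protein background and
#' enrichment.
#'
#' @param descriptor_list List of `complex_descriptors`.
#' @param structures Optional list of `pd_structure` (for composition /
#'   enrichment; same order as `descriptor_list`).
#' @param class_map Residue class map (see [default_class_map()]).
#' @param outdir Optional output directory for TSV reports.
#' @return A `cohort_summary`: box stats (`residue_rmsd_range`,
#'   `ligand_rmsd_range`, `sasa_min`, `sasa_max`), `cluster_shares`
#'   (fractions of low/moderate/high over all pooled binding residues),
#'   `n_residues`, and optionally `pocket`, `background`, `enrichment`.
#' @export
run_aggregate <- function(descriptor_list, structures = NULL,
                          class_map = default_class_map(), outdir = NULL) {
  if (length(descriptor_list) == 0L) stop("empty cohort")
  res <- do.call(rbind, lapply(descriptor_list, function(d) d$residues))
  if (is.null(res) || nrow(res) == 0L)
    stop("no binding residues anywhere in the cohort")
  lig_ranges <- vapply(descriptor_list, function(d)
    d$ligand_rmsd$fluctuation$range, numeric(1))
  with_pocket <- Filter(function(d) !d$no_binding_residues, descriptor_list)
  pocket_min <- vapply(with_pocket, function(d) d$pocket_sasa$min, numeric(1))
  pocket_max <- vapply(with_pocket, function(d) d$pocket_sasa$max, numeric(1))
  shares <- c(low = mean(res$cluster == "low"),
              moderate = mean(res$cluster == "moderate"),
              high = mean(res$cluster == "high"))
  out <- list(residue_rmsd_range = box_stats(res$rmsd_range),
              ligand_rmsd_range = box_stats(lig_ranges),
              sasa_min = box_stats(pocket_min),
              sasa_max = box_stats(pocket_max),
              cluster_shares = shares,
              n_residues = nrow(res),
              n_complexes = length(descriptor_list))
  if (!is.null(structures)) {
    pockets <- lapply(descriptor_list, function(d)
      d$residues[, c("chain", "res_seq", "res_name")])
    out$pocket <- pocket_composition(pockets)
    out$background <- background_composition(structures)
    out$enrichment <- enrichment(out$pocket, out$background, class_map)
  }
  class(out) <- "cohort_summary"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    bs <- function(b, name) data.frame(descriptor = name, median = b$median,
                                       q1 = b$q1, q3 = b$q3, iqr = b$iqr,
                                       siqr_l = b$siqr_l, siqr_r = b$siqr_r,
                                       n = b$n, n_outliers = length(b$outliers))
    write_table(rbind(bs(out$residue_rmsd_range, "residue_rmsd_range"),
                      bs(out$ligand_rmsd_range, "ligand_rmsd_range"),
                      bs(out$sasa_min, "sasa_min"),
                      bs(out$sasa_max, "sasa_max")),
                file.path(outdir, "cohort_boxstats.tsv"))
    write_table(data.frame(cluster = names(shares),
                           share = as.numeric(shares),
                           percent = 100 * as.numeric(shares)),
                file.path(outdir, "cohort_cluster_shares.tsv"))
    if (!is.null(out$enrichment))
      write_table(out$enrichment$table,
                  file.path(outdir, "cohort_enrichment.tsv"))
  }
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d complexes, %d pooled binding residues\n",
              x$n_complexes, x$n_residues))
  cat(sprintf("  cluster shares: low %.1f%%, moderate %.1f%%, high %.1f%%\n",
              100 * x$cluster_shares["low"], 100 * x$cluster_shares["moderate"],
              100 * x$cluster_shares["high"]))
  cat("  residue RMSD range "); print(x$residue_rmsd_range)
  cat("  ligand  RMSD range "); print(x$ligand_rmsd_range)
  cat("  SASA min "); print(x$sasa_min)
  cat("  SASA max "); print(x$sasa_max)
  invisible(x)
}

#' Benchmark one complex against the reference ranges
#'
#' Runs [run_analyze()] then [assess()]; if `outdir` is set, writes the
#' verdict table as TSV plus a human-readable report.
#'
#' @param rc A [run_config()].
#' @return A `benchmark_report`.
#' @export
run_benchmark <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  desc <- run_analyze(rc)
  report <- .stage("assess", assess(desc, rc$reference, rc$sasa_factor))
  if (!is.null(rc$outdir)) {
    pre <- file.path(rc$outdir, rc$complex_id)
    write_table(report$verdicts, paste0(pre, "_benchmark.tsv"))
    con <- file(paste0(pre, "_benchmark.txt"), "wt")
    sink(con); print(report); sink(); close(con)
  }
  report
}
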