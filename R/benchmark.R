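#' Published cohort reference ranges for pose assessment
#'
#' The reference constants distilled from a 100-complex, 100-ns-per-complex
#' MD cohort: quartile blocks for the ligand RMSD, binding-residue backbone
#' RMSD and per-residue SASA extrema, the overall SASA range, the backbone
#' RMSD stability band, and the cohort share of high-occupancy binding
#' residues.  SASA blocks are stored verbatim in the source's printed units
#' (`sasa_unit = "paper-units"`): the printed 1.9-3.92 range is physically
#' implausible as Angstrom^2 for amino-acid residues and matches an nm^2
#' output convention, so comparisons apply a configurable conversion factor
#' (default 100, i.e. nm^2 to Angstrom^2) — see [assess()].
#'
#' @return A `benchmark_reference` list.
#' @export
default_reference <- function() {
  ref <- list(
    ligand_rmsd  = list(median = 1.6,  q1 = 1.0,  q3 = 2.0),   # Angstrom
    residue_rmsd = list(median = 1.2,  q1 = 0.7,  q3 = 1.5),   # Angstrom
    sasa_min     = list(median = 2.68, q1 = 2.29, q3 = 2.72),  # paper-units
    sasa_max     = list(median = 3.2,  q1 = 3.03, q3 = 3.62),  # paper-units
    sasa_overall = c(1.9, 3.92),                               # paper-units
    backbone_rmsd_band = c(1.5, 4.0),                          # Angstrom
    high_occupancy_threshold = 0.70,
    high_occupancy_cohort_share = 0.865,
    sasa_unit = "paper-units (presumed nm^2)"
  )
  for (b in c("ligand_rmsd", "residue_rmsd", "sasa_min", "sasa_max"))
    stopifnot(ref[[b]]$q1 <= ref[[b]]$median, ref[[b]]$median <= ref[[b]]$q3)
  structure(ref, class = "benchmark_reference")
}

#' Write / read a benchmark reference as a plain-text key-value config
#'
#' @param ref A `benchmark_reference`.
#' @param path File path.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns a `benchmark_reference`.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "benchmark_reference"))
  ln <- character(0)
  for (b in c("ligand_rmsd", "residue_rmsd", "sasa_min", "sasa_max"))
    ln <- c(ln, sprintf("%s.%s = %g", b, names(ref[[b]]), unlist(ref[[b]])))
  ln <- c(ln,
          sprintf("sasa_overall = %g %g", ref$sasa_overall[1], ref$sasa_overall[2]),
          sprintf("backbone_rmsd_band = %g %g", ref$backbone_rmsd_band[1],
                  ref$backbone_rmsd_band[2]),
          sprintf("high_occupancy_threshold = %g", ref$high_occupancy_threshold),
          sprintf("high_occupancy_cohort_share = %g",
                  ref$high_occupancy_cohort_share),
          sprintf("sasa_unit = %s", ref$sasa_unit))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
  kv <- strsplit(ln, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  ref <- default_reference()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    if (grepl("\\.", k)) {
      parts <- strsplit(k, "\\.")[[1]]
      ref[[parts[1]]][[parts[2]]] <- as.numeric(v)
    } else if (k == "sasa_unit") {
      ref$sasa_unit <- v
    } else {
      ref[[k]] <- as.numeric(strsplit(v, "\\s+")[[1]])
    }
  }
  class(ref) <- "benchmark_reference"
  ref
}

# Verdict for a value against a quartile block.
.band_status <- function(value, block) {
  iqr <- block$q3 - block$q1
  if (value >= block$q1 && value <= block$q3) "within_iqr"
  else if (value >= block$q1 - 1.5 * iqr && value <= block$q3 + 1.5 * iqr)
    "within_whiskers"
  else "outside"
}

#' Assess a complex's descriptors against the reference ranges
#'
#' Compares the ligand median RMSD, the median over binding residues of the
#' per-residue median RMSD, and the minimum and maximum over frames of the
#' binding-residue group SASA (after unit conversion by `sasa_factor`;
#' the reference SASA quantiles describe the solvent exposure of the pocket
#' as a whole, the quantity a trajectory tool reports for a binding-residue
#' index group) against the reference
#' quartile blocks: `within_iqr` inside `[q1, q3]`, `within_whiskers` inside
#' the Tukey whiskers, `outside` beyond.  The backbone median RMSD is checked
#' against the stability band; values below the band's lower edge indicate
#' more, not less, stability and count as within.  The share of binding
#' residues in the high-occupancy cluster is compared with the cohort share.
#'
#' Overall flag: `consistent` iff no descriptor is `outside` and the
#' high-occupancy share is at least 0.70; `inconsistent` iff at least two
#' descriptors are `outside` or the share is below 0.30; `borderline`
#' otherwise.  The rule is a scoring convention of this package (the source
#' cohort publishes the ranges, not a decision rule) and is printed in the
#' report header.
#'
#' @param descriptors A [complex_descriptors()] result with at least one
#'   binding residue.
#' @param ref A [default_reference()] (or one loaded via [read_reference()]).
#' @param sasa_factor Multiplier taking the reference's printed SASA units to
#'   Angstrom^2 (default 100, reading them as nm^2).  Set to `NA` to refuse
#'   any conversion (error), or 1 if your descriptors are already in the
#'   reference's units.
#' @return A `benchmark_report`: data frame `verdicts` (`descriptor`,
#'   `value`, `lower`, `upper`, `status`), `high_occupancy_share`, `flag`,
#'   `rule`, `sasa_assumption`.
#' @export
assess <- function(descriptors, ref = default_reference(), sasa_factor = 100) {
  stopifnot(inherits(descriptors, "complex_descriptors"),
            inherits(ref, "benchmark_reference"))
  if (descriptors$no_binding_residues || nrow(descriptors$residues) == 0L)
    stop("cannot assess a complex with no binding residues")
  if (is.na(sasa_factor))
    stop("SASA unit mismatch: descriptors are in Angstrom^2 but the reference is in ",
         ref$sasa_unit, " and no conversion factor is configured")
  rd <- descriptors$residues
  lig <- stats::median(descriptors$ligand_rmsd$series$values)
  res <- stats::median(rd$rmsd_median)
  sasa_min_med <- descriptors$pocket_sasa$min
  sasa_max_med <- descriptors$pocket_sasa$max
  bb <- stats::median(descriptors$backbone_rmsd$series$values)

  scale_block <- function(b) list(median = b$median * sasa_factor,
                                  q1 = b$q1 * sasa_factor,
                                  q3 = b$q3 * sasa_factor)
  smin <- scale_block(ref$sasa_min); smax <- scale_block(ref$sasa_max)

  v <- rbind(
    data.frame(descriptor = "ligand_rmsd_median", value = lig,
               lower = ref$ligand_rmsd$q1, upper = ref$ligand_rmsd$q3,
               status = .band_status(lig, ref$ligand_rmsd)),
    data.frame(descriptor = "residue_rmsd_median", value = res,
               lower = ref$residue_rmsd$q1, upper = ref$residue_rmsd$q3,
               status = .band_status(res, ref$residue_rmsd)),
    data.frame(descriptor = "pocket_sasa_min", value = sasa_min_med,
               lower = smin$q1, upper = smin$q3,
               status = .band_status(sasa_min_med, smin)),
    data.frame(descriptor = "pocket_sasa_max", value = sasa_max_med,
               lower = smax$q1, upper = smax$q3,
               status = .band_status(sasa_max_med, smax)),
    data.frame(descriptor = "backbone_rmsd_median", value = bb,
               lower = ref$backbone_rmsd_band[1],
               upper = ref$backbone_rmsd_band[2],
               status = if (bb > ref$backbone_rmsd_band[2]) "outside"
                        else if (bb >= ref$backbone_rmsd_band[1]) "within_iqr"
                        else "within_whiskers")
  )
  share <- mean(rd$cluster == "high")
  n_outside <- sum(v$status == "outside")
  flag <- if (n_outside >= 2 || share < 0.30) "inconsistent"
          else if (n_outside == 0 && share >= 0.70) "consistent"
          else "borderline"
  structure(list(
    verdicts = v,
    high_occupancy_share = share,
    high_occupancy_reference = ref$high_occupancy_cohort_share,
    flag = flag,
    rule = paste("consistent: no descriptor outside whiskers and high-occupancy",
                 "share >= 0.70; inconsistent: >= 2 descriptors outside or",
                 "share < 0.30; otherwise borderline"),
    sasa_assumption = sprintf(
      "reference SASA stored in %s; compared after multiplying by %g",
      ref$sasa_unit, sasa_factor)),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> flag:", x$flag, "\n")
  cat("  rule:", x$rule, "\n")
  cat("  ", x$sasa_assumption, "\n", sep = "")
  for (i in seq_len(nrow(x$verdicts)))
    cat(sprintf("  %-22s %8.3f  band [%8.3f, %8.3f]  %s\n",
                x$verdicts$descriptor[i], x$verdicts$value[i],
                x$verdicts$lower[i], x$verdicts$upper[i],
                x$verdicts$status[i]))
  cat(sprintf("  high-occupancy share %.3f (cohort reference %.3f)\n",
              x$high_occupancy_share, x$high_occupancy_reference))
  invisible(x)
}
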