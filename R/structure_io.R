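# Internal constructor for the atom-table + coordinate representation used
# throughout the package.  `atoms` carries identity, `xyz` carries geometry;
# the row order of `atoms` defines the column order of every trajectory frame.
new_structure <- function(atoms, xyz, frame_time = 0) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(atoms) == nrow(xyz))
  if (nrow(atoms) < 1L) stop("a structure must contain at least one atom")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure")
  if (any(is.na(atoms$element) | !nzchar(atoms$element)))
    stop("every atom must carry a non-empty element symbol")
  structure(list(atoms = atoms, xyz = xyz, frame_time = frame_time),
            class = "pd_structure")
}

#' Number of atoms in a structure
#' @param x A `pd_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "pd_structure"))
  nrow(x$atoms)
}

#' @export
print.pd_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pd_structure> %d atoms, %d residues (%d hetero atoms)\n",
              nrow(a), nrow(unique(a[, c("chain", "res_seq")])),
              sum(a$is_hetero)))
  invisible(x)
}

# PDB fixed-column layout (v3.3 coordinate section)
.pdb_num <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(trimws(txt)))
  if (any(is.na(v))) {
    bad <- lineno[which(is.na(v))[1]]
    stop(sprintf("malformed %s field at line %d", what, bad))
  }
  v
}

# Element symbol from the atom-name column when columns 77-78 are blank.
# First alphabetic character of the name after stripping leading digits;
# adequate for organic/biological atoms (C/N/O/S/P/H and their variants).
.element_from_name <- function(name) {
  nm <- sub("^[0-9 ]+", "", name)
  ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
  out <- toupper(vapply(ch, function(z) if (length(z)) z else "", ""))
  out[!nzchar(out)] <- NA_character_
  out
}

#' Read a structure from a PDB file
#'
#' Parses `ATOM`/`HETATM` records in fixed-column PDB format.  Alternate
#' locations other than blank or `A` are dropped; insertion codes are not
#' supported and raise an error.  The element is taken from columns 77-78,
#' falling back to a heuristic on the atom name when blank.  If the file is a
#' multi-model PDB only the first model is read (use [read_trajectory()] for
#' the frames).
#'
#' @param path Path to a PDB file.
#' @return A `pd_structure`: a list with an `atoms` data frame (`serial`,
#'   `name`, `element`, `res_name`, `res_seq`, `chain`, `is_hetero`) and an
#'   `xyz` n x 3 coordinate matrix in Angstrom.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  first_end <- grep("^(ENDMDL|END$|END )", lines)
  first_model <- grep("^MODEL", lines)
  if (length(first_model) >= 1L && length(first_end) >= 1L) {
    lines <- lines[seq_len(first_end[1] - 1L)]
  }
  keep <- which(grepl("^(ATOM  |HETATM)", lines))
  if (length(keep) == 0L) stop("no ATOM/HETATM records in ", path)
  ln <- lines[keep]
  lineno <- keep
  altloc <- substr(ln, 17, 17)
  ok <- altloc %in% c(" ", "", "A")
  ln <- ln[ok]; lineno <- lineno[ok]
  if (length(ln) == 0L) stop("all records dropped by altLoc filter in ", path)
  icode <- trimws(substr(ln, 27, 27))
  if (any(nzchar(icode)))
    stop(sprintf("insertion codes are not supported (line %d)",
                 lineno[which(nzchar(icode))[1]]))
  atoms <- data.frame(
    serial   = as.integer(.pdb_num(substr(ln, 7, 11), lineno, "serial")),
    name     = trimws(substr(ln, 13, 16)),
    element  = trimws(substr(ln, 77, 78)),
    res_name = trimws(substr(ln, 18, 20)),
    res_seq  = as.integer(.pdb_num(substr(ln, 23, 26), lineno, "residue number")),
    chain    = substr(ln, 22, 22),
    is_hetero = grepl("^HETATM", ln),
    stringsAsFactors = FALSE
  )
  xyz <- cbind(.pdb_num(substr(ln, 31, 38), lineno, "coordinate"),
               .pdb_num(substr(ln, 39, 46), lineno, "coordinate"),
               .pdb_num(substr(ln, 47, 54), lineno, "coordinate"))
  blank <- !nzchar(atoms$element)
  if (any(blank)) {
    guess <- .element_from_name(atoms$name[blank])
    if (any(is.na(guess)))
      stop(sprintf("cannot infer element for atom name '%s' (line %d)",
                   atoms$name[blank][which(is.na(guess))[1]],
                   lineno[blank][which(is.na(guess))[1]]))
    atoms$element[blank] <- guess
  }
  atoms$element <- toupper(atoms$element)
  new_structure(atoms, xyz)
}

# One fixed-column PDB line per atom.  Names of <4 characters start in
# column 14 (the PDB convention for one-letter elements).
.format_pdb_lines <- function(atoms, xyz, serial_offset = 0L) {
  nm <- atoms$name
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$is_hetero, "HETATM", "ATOM"),
          (seq_len(nrow(atoms)) + serial_offset) %% 100000L,
          nm4, " ", atoms$res_name, atoms$chain, atoms$res_seq, " ",
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          toupper(atoms$element))
}

#' Write a structure to a PDB file
#'
#' @param structure A `pd_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "pd_structure"))
  lines <- c(.format_pdb_lines(structure$atoms, structure$xyz), "END")
  writeLines(lines, path)
  invisible(path)
}

new_trajectory <- function(topology, frames, times) {
  stopifnot(inherits(topology, "pd_structure"), is.list(frames))
  n <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3 || nrow(f) != n)
      stop(sprintf("frame %d: expected %d atoms, got %d", i, n,
                   if (is.matrix(f)) nrow(f) else NA_integer_))
  }
  if (length(times) != length(frames))
    stop("times and frames must have equal length")
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "pd_trajectory")
}

#' @export
print.pd_trajectory <- function(x, ...) {
  cat(sprintf("<pd_trajectory> %d frames x %d atoms, t = [%g, %g]\n",
              length(x$frames), n_atoms(x$topology),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "pd_trajectory"))
  length(traj$frames)
}

#' Read a trajectory
#'
#' Two plain-text formats are supported: a multi-model PDB (`MODEL`/`ENDMDL`
#' blocks sharing the topology's atom order) and a whitespace-delimited XYZ
#' table with either three columns (`x y z`, consecutive blocks of
#' `n_atoms` rows per frame) or four columns (`frame x y z`).
#'
#' @param path Path to the trajectory file.
#' @param topology A `pd_structure` defining atom identity and order; every
#'   frame must contain exactly this many atoms.
#' @param stride Time per frame in the output `times` (default 1, i.e. frame
#'   units; set to e.g. 0.1 for a 0.1 ns frame spacing).  Frame `i` gets time
#'   `(i - 1) * stride`.
#' @return A `pd_trajectory`: `topology`, a list of n x 3 `frames`, and
#'   strictly increasing `times`.
#' @export
read_trajectory <- function(path, topology, stride = 1) {
  stopifnot(inherits(topology, "pd_structure"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trajectory file: ", path)
  n <- n_atoms(topology)
  is_pdb <- grepl("^(MODEL|ATOM  |HETATM)", lines[1])
  frames <- list()
  if (is_pdb) {
    model_id <- cumsum(grepl("^MODEL", lines))
    if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
    atom_mask <- grepl("^(ATOM  |HETATM)", lines)
    split_idx <- split(which(atom_mask), model_id[atom_mask])
    for (k in seq_along(split_idx)) {
      ln <- lines[split_idx[[k]]]
      altloc <- substr(ln, 17, 17)
      ln <- ln[altloc %in% c(" ", "", "A")]
      if (length(ln) != n)
        stop(sprintf("frame %d: expected %d atoms, got %d", k, n, length(ln)))
      frames[[k]] <- cbind(.pdb_num(substr(ln, 31, 38), split_idx[[k]], "x"),
                           .pdb_num(substr(ln, 39, 46), split_idx[[k]], "y"),
                           .pdb_num(substr(ln, 47, 54), split_idx[[k]], "z"))
    }
  } else {
    tab <- utils::read.table(text = lines, header = FALSE)
    if (ncol(tab) == 4L) {
      fid <- tab[[1]]
      for (k in seq_along(unique(fid))) {
        block <- as.matrix(tab[fid == unique(fid)[k], 2:4])
        if (nrow(block) != n)
          stop(sprintf("frame %d: expected %d atoms, got %d", k, n, nrow(block)))
        dimnames(block) <- NULL
        frames[[k]] <- block
      }
    } else if (ncol(tab) == 3L) {
      if (nrow(tab) %% n != 0L)
        stop(sprintf("frame %d: expected %d atoms, got %d",
                     nrow(tab) %/% n + 1L, n, nrow(tab) %% n))
      nf <- nrow(tab) %/% n
      m <- as.matrix(tab); dimnames(m) <- NULL
      for (k in seq_len(nf)) frames[[k]] <- m[((k - 1) * n + 1):(k * n), , drop = FALSE]
    } else {
      stop("XYZ trajectory table must have 3 (x y z) or 4 (frame x y z) columns")
    }
  }
  new_trajectory(topology, frames, (seq_along(frames) - 1) * stride)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A `pd_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pd_trajectory"))
  out <- character(0)
  for (k in seq_along(traj$frames)) {
    out <- c(out, sprintf("MODEL     %4d", k),
             .format_pdb_lines(traj$topology$atoms, traj$frames[[k]]),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

.water_names <- c("HOH", "WAT", "SOL")

#' Select atoms from a structure
#'
#' Selectors: `"backbone"` (protein N, CA, C, O; hetero atoms excluded),
#' `"protein"` (all non-hetero, non-water atoms), `"ligand"` (hetero atoms of
#' residue `resname`; waters always excluded), `"residue"` (all atoms of one
#' residue given `chain` and `res_seq`), `"residues"` (all atoms of the
#' residues in the data frame `residues` with columns `chain`, `res_seq`) and
#' `"residue_backbone"` (backbone atoms of those residues).  Selections are
#' returned in topology order and an empty match is always an error.
#'
#' @param structure A `pd_structure`.
#' @param selector One of the selector keywords above.
#' @param resname Ligand residue name (for `"ligand"`).
#' @param chain,res_seq Residue identity (for `"residue"`).
#' @param residues Data frame with `chain` and `res_seq` columns (for
#'   `"residues"` / `"residue_backbone"`).
#' @return An integer vector of atom indices with class `pd_selection`.
#' @export
select_atoms <- function(structure, selector, resname = NULL,
                         chain = NULL, res_seq = NULL, residues = NULL) {
  stopifnot(inherits(structure, "pd_structure"))
  a <- structure$atoms
  not_water <- !(a$res_name %in% .water_names)
  idx <- switch(selector,
    backbone = which(!a$is_hetero & not_water &
                       a$name %in% c("N", "CA", "C", "O")),
    protein = which(!a$is_hetero & not_water),
    ligand = {
      if (is.null(resname)) stop("selector 'ligand' needs a resname")
      if (resname %in% .water_names) stop("waters cannot be selected as ligand")
      which(a$is_hetero & a$res_name == resname)
    },
    residue = {
      if (is.null(chain) || is.null(res_seq))
        stop("selector 'residue' needs chain and res_seq")
      which(a$chain == chain & a$res_seq == res_seq)
    },
    residues = ,
    residue_backbone = {
      if (is.null(residues)) stop("selector needs a residues data frame")
      key <- paste(a$chain, a$res_seq)
      hit <- key %in% paste(residues$chain, residues$res_seq)
      if (selector == "residue_backbone")
        hit <- hit & a$name %in% c("N", "CA", "C", "O") & !a$is_hetero
      which(hit)
    },
    stop("unknown selector: ", selector)
  )
  if (length(idx) == 0L)
    stop("selection '", selector, "' matched no atoms")
  structure(as.integer(idx), class = "pd_selection", selector = selector)
}

#' Write a tab-separated report table
#'
#' Writes a header row plus one row per record; numeric columns are rendered
#' with 4 decimals so files are byte-stable across runs.
#'
#' @param rows A data frame (possibly with zero rows).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.4f", fmt[[j]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = "\t"), con)
  if (nrow(fmt) > 0L) {
    body <- do.call(paste, c(lapply(fmt, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

# Residue identity key used in tables and matrix row labels.
residue_key <- function(chain, res_seq, res_name = NULL) {
  if (is.null(res_name)) paste(chain, res_seq, sep = ":")
  else paste(chain, res_seq, res_name, sep = ":")
}

# Unique protein residues of a structure, in (chain, res_seq) order.
protein_residues <- function(structure) {
  a <- structure$atoms
  p <- a[!a$is_hetero & !(a$res_name %in% .water_names),
         c("chain", "res_seq", "res_name")]
  u <- unique(p)
  u[order(u$chain, u$res_seq), , drop = FALSE]
}
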