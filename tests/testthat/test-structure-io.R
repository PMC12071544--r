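test_that("PDB fields are parsed from their fixed columns", {
  f <- write_tmp_pdb(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"))
  s <- read_structure(f)
  expect_equal(n_atoms(s), 1L)
  expect_equal(unname(s$xyz[1, ]), c(1, 2, 3))
  expect_equal(s$atoms$name, "CA")
  expect_equal(s$atoms$res_name, "ALA")
  expect_equal(s$atoms$chain, "A")
  expect_false(s$atoms$is_hetero)
})

test_that("HETATM records are flagged hetero and elements fall back to the name heuristic", {
  f <- write_tmp_pdb(peptide_pdb_text(with_ligand = TRUE, blank_elements = TRUE))
  s <- read_structure(f)
  expect_true(all(s$atoms$is_hetero[s$atoms$res_name == "LIG"]))
  expect_false(any(s$atoms$is_hetero[s$atoms$res_name != "LIG"]))
  # heuristic element assignment from atom names
  expect_equal(s$atoms$element[s$atoms$name == "O1"], "O")
  expect_equal(s$atoms$element[s$atoms$name == "N1"], "N")
  expect_equal(s$atoms$element[s$atoms$name == "CA"][1], "C")
})

test_that("altLoc B records are dropped, insertion codes and bad fields error with line numbers", {
  f <- write_tmp_pdb(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "END"))
  s <- read_structure(f)
  expect_equal(n_atoms(s), 1L)
  expect_equal(s$xyz[1, 1], 1)

  f2 <- write_tmp_pdb(c(
    "ATOM      1  CA  ALA A   1A      1.000   0.000   0.000  1.00  0.00           C",
    "END"))
  expect_error(read_structure(f2), "insertion code")

  f3 <- write_tmp_pdb(c(
    "ATOM      1  CA  ALA A   1       1.000   x.000   0.000  1.00  0.00           C",
    "END"))
  expect_error(read_structure(f3), "line 1")

  f4 <- write_tmp_pdb(character(0))
  expect_error(read_structure(f4), "empty")
})

test_that("write_structure / read_structure round-trips atom identity and coordinates", {
  g <- generate_complex(complex_spec(n_residues = 6L,
                                     pocket = data.frame(index = 3L,
                                                         res_name = "ASP"),
                                     hbond_schedule = data.frame(index = 3L,
                                                                 f = 1,
                                                                 pattern = "block"),
                                     n_frames = 1L, seed = 11L))
  f <- tempfile(fileext = ".pdb")
  write_structure(g$structure, f)
  s2 <- read_structure(f)
  for (col in c("name", "res_name", "res_seq", "chain", "is_hetero", "element"))
    expect_equal(s2$atoms[[col]], g$structure$atoms[[col]])
  expect_equal(s2$xyz, g$structure$xyz, tolerance = 1e-3)
})

test_that("multi-model PDB trajectories round-trip with frame-unit times", {
  g <- generate_complex(complex_spec(n_frames = 101L, seed = 5L,
                                     residue_sigma = 0.1))
  f <- tempfile(fileext = ".pdb")
  write_trajectory(g$trajectory, f)
  tr <- read_trajectory(f, g$structure)
  expect_equal(n_frames(tr), 101L)
  expect_equal(tr$times, 0:100)
  expect_equal(tr$frames[[50]], g$trajectory$frames[[50]], tolerance = 1e-3)
  # a stride rescales times
  tr2 <- read_trajectory(f, g$structure, stride = 0.5)
  expect_equal(tr2$times, (0:100) * 0.5)
})

test_that("duplicated models give identical frames and short frames name the frame index", {
  pep <- peptide_pdb_text()
  body <- pep[pep != "END"]
  f <- write_tmp_pdb(c("MODEL     1", body, "ENDMDL",
                       "MODEL     2", body, "ENDMDL", "END"))
  topo <- read_structure(f)
  tr <- read_trajectory(f, topo)
  expect_equal(n_frames(tr), 2L)
  expect_equal(tr$frames[[1]], tr$frames[[2]])

  f2 <- write_tmp_pdb(c("MODEL     1", body, "ENDMDL",
                        "MODEL     2", body[-3], "ENDMDL", "END"))
  expect_error(read_trajectory(f2, topo), "frame 2: expected 8 atoms")
})

test_that("whitespace XYZ tables are accepted in 3- and 4-column form", {
  pep <- write_tmp_pdb(peptide_pdb_text())
  topo <- read_structure(pep)
  xyz <- topo$xyz
  f3 <- tempfile()
  write.table(rbind(xyz, xyz + 1), f3, row.names = FALSE, col.names = FALSE)
  tr3 <- read_trajectory(f3, topo)
  expect_equal(n_frames(tr3), 2L)
  expect_equal(tr3$frames[[2]], unname(xyz) + 1, tolerance = 1e-6)

  f4 <- tempfile()
  write.table(cbind(rep(1:2, each = 8), rbind(xyz, xyz)), f4,
              row.names = FALSE, col.names = FALSE)
  tr4 <- read_trajectory(f4, topo)
  expect_equal(n_frames(tr4), 2L)
})

test_that("selections are deterministic, typed and never silently empty", {
  f <- write_tmp_pdb(peptide_pdb_text(with_ligand = TRUE))
  s <- read_structure(f)
  bb <- select_atoms(s, "backbone")
  expect_length(bb, 8L)                       # 2 residues x N,CA,C,O
  expect_equal(as.integer(bb), 1:8)           # topology order
  lig <- select_atoms(s, "ligand", resname = "LIG")
  expect_length(lig, 5L)
  expect_error(select_atoms(s, "residue", chain = "A", res_seq = 999L),
               "matched no atoms")
  # idempotent / stable under re-reading
  s2 <- read_structure(f)
  expect_equal(as.integer(select_atoms(s2, "backbone")), as.integer(bb))
  # backbone excludes the hetero ligand even though it has N/C/O atoms
  expect_false(any(as.integer(bb) %in% as.integer(lig)))
})

test_that("write_table emits a header, 4-decimal floats and round-trips values", {
  f <- tempfile(fileext = ".tsv")
  write_table(data.frame(a = numeric(0), b = character(0)), f)
  expect_equal(readLines(f), "a\tb")

  df <- data.frame(res = c("A:1", "A:2", "A:3"),
                   value = c(1.23456789, 2, 0.00009))
  write_table(df, f)
  expect_length(readLines(f), 4L)
  back <- read.delim(f)
  expect_equal(back$value, round(df$value, 4))
})
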