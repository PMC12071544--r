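test_that("donor/acceptor typing follows element and attached-hydrogen rules", {
  # hydroxyl: O with H at 0.96 A -> donor and acceptor; C is neither
  s <- make_structure(c("OG", "HG", "CB"), c("O", "H", "C"),
                      rbind(c(0, 0, 0), c(0.96, 0, 0), c(5, 5, 5)))
  da <- donors_acceptors(s, 1:3)
  expect_false(da$fallback)
  expect_equal(da$donors$heavy, 1L)
  expect_equal(da$donors$hydrogens[[1]], 2L)
  expect_true(1L %in% da$acceptors)
  expect_false(3L %in% da$acceptors)

  # heavy-atom-only structure: every N/O/S flagged for fallback mode
  s2 <- make_structure(c("N", "O", "CA"), c("N", "O", "C"),
                       rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  da2 <- donors_acceptors(s2, 1:3)
  expect_true(da2$fallback)
  expect_equal(da2$donors$heavy, c(1L, 2L))
  expect_true(all(lengths(da2$donors$hydrogens) == 0L))
})

test_that("hydrogen-bond geometry criteria are applied exactly", {
  # D at origin, H on the D->A axis, A at 3.3 A: distance ok, angle 0
  s <- make_structure(c("OD", "HD", "OA"), c("O", "H", "O"),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(3.3, 0, 0)),
                      res_seq = c(1L, 1L, 2L))
  donors <- data.frame(heavy = 1L); donors$hydrogens <- list(2L)
  hits <- detect_hbonds(s$xyz, donors, 3L, hbond_criteria())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 3.3)
  expect_equal(hits$angle, 0)

  # beyond the distance cutoff
  far <- s$xyz; far[3, 1] <- 5.0
  expect_equal(nrow(detect_hbonds(far, donors, 3L, hbond_criteria())), 0L)

  # within distance but H-D-A angle 90 degrees
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3, 0))
  expect_equal(nrow(detect_hbonds(bent, donors, 3L, hbond_criteria())), 0L)

  # fallback donors (no hydrogens) use the distance criterion alone
  donors_h0 <- data.frame(heavy = 1L); donors_h0$hydrogens <- list(integer(0))
  expect_equal(nrow(detect_hbonds(bent, donors_h0, 3L, hbond_criteria())), 1L)

  expect_error(hbond_criteria(max_hda_angle = 200), "0, 180")
  expect_error(hbond_criteria(max_da_distance = 0), "positive")
})

test_that("both donor/acceptor directions across the divide are unioned", {
  # protein donor -> ligand acceptor AND ligand donor -> protein acceptor
  s <- make_structure(c("OG", "HG", "O1", "O2", "H2", "OD1"),
                      c("O", "H", "O", "O", "H", "O"),
                      rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.9, 0, 0),
                            c(20, 0, 0), c(19.04, 0, 0), c(17.1, 0, 0)),
                      res_name = c("SER", "SER", "LIG", "LIG", "LIG", "ASP"),
                      res_seq = c(1L, 1L, 9L, 9L, 9L, 2L),
                      hetero = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  bonds <- pocketdyn:::hbonds_between(s, s$xyz, c(1L, 2L, 6L), c(3L, 4L, 5L))
  expect_equal(nrow(bonds), 2L)
  expect_setequal(bonds$res_seq, c(1L, 2L))
})

test_that("binding residues are identified over the chosen frame window", {
  g <- generate_complex(complex_spec(
    n_residues = 35L,
    pocket = data.frame(index = c(5L, 12L, 30L),
                        res_name = c("ASP", "HIS", "SER")),
    hbond_schedule = data.frame(index = c(5L, 12L, 30L), f = 1,
                                pattern = "block"),
    n_frames = 5L, seed = 2L))
  br <- identify_binding_residues(g$trajectory, "LIG")
  expect_equal(br$res_seq, c(5L, 12L, 30L))
  expect_equal(br$res_name, c("ASP", "HIS", "SER"))

  # a residue that bonds only later is caught by a full-trajectory window
  g2 <- generate_complex(complex_spec(
    n_residues = 35L,
    pocket = data.frame(index = c(5L, 12L), res_name = c("ASP", "HIS")),
    hbond_schedule = data.frame(index = c(5L, 12L), f = c(1, 0.5),
                                pattern = c("block", "periodic")),
    n_frames = 20L, seed = 2L))
  expect_equal(identify_binding_residues(g2$trajectory, "LIG")$res_seq, 5L)
  full <- identify_binding_residues(g2$trajectory, "LIG",
                                    window = n_frames(g2$trajectory))
  expect_equal(full$res_seq, c(5L, 12L))
})

test_that("a ligand far from the protein yields an explicit empty warning", {
  s <- make_structure(c("OG", "HG", "O1"), c("O", "H", "O"),
                      rbind(c(0, 0, 0), c(0.96, 0, 0), c(50, 0, 0)),
                      res_name = c("SER", "SER", "LIG"),
                      res_seq = c(1L, 1L, 9L),
                      hetero = c(FALSE, FALSE, TRUE))
  tr <- make_traj(s, list(s$xyz))
  expect_warning(br <- identify_binding_residues(tr, "LIG"),
                 "no binding residues")
  expect_equal(nrow(br), 0L)
})

test_that("the existence matrix reflects scheduled bond patterns exactly", {
  mk <- function(f, pattern, nf) {
    g <- generate_complex(complex_spec(
      n_residues = 10L, pocket = data.frame(index = 5L, res_name = "ASP"),
      residue_sigma = 0, ligand_sigma = 0,
      hbond_schedule = data.frame(index = 5L, f = f, pattern = pattern),
      n_frames = nf, seed = 3L))
    binding <- data.frame(chain = "A", res_seq = 5L, res_name = "ASP")
    existence_matrix(g$trajectory, binding, "LIG")
  }
  em_all <- mk(1, "block", 6L)
  expect_equal(nrow(em_all$present), 1L)
  expect_true(all(em_all$present))

  em_first <- mk(1 / 6, "block", 6L)
  expect_equal(unname(em_first$present[1, ]),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))

  em_alt <- mk(0.5, "periodic", 6L)
  expect_equal(unname(em_alt$present[1, ]),
               c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("residue occupancy is the any-pair union and is order/addition monotone", {
  base <- data.frame(donor = c(1L, 2L), acceptor = c(10L, 11L),
                     chain = "A", res_seq = 5L, res_name = "ASP",
                     label = c("p1", "p2"))
  present <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                   c(FALSE, FALSE, TRUE, TRUE))
  em <- structure(list(pairs = base, present = present, times = 0:3),
                  class = "existence_matrix")
  occ <- residue_occupancy(em, "A", 5L)
  expect_equal(occ$fraction, 1.0)            # disjoint halves union to full
  expect_equal(occ$existence_time, 4)

  # re-ordering pairs leaves the fraction unchanged
  em_rev <- structure(list(pairs = base[2:1, ], present = present[2:1, ],
                           times = 0:3), class = "existence_matrix")
  expect_equal(residue_occupancy(em_rev, "A", 5L)$fraction, 1.0)

  # dropping a pair can only lower the fraction
  em_one <- structure(list(pairs = base[1, ], present = present[1, , drop = FALSE],
                           times = 0:3), class = "existence_matrix")
  expect_lte(residue_occupancy(em_one, "A", 5L)$fraction, occ$fraction)

  expect_error(residue_occupancy(em, "A", 99L), "owns no pair")
})

test_that("occupancy fractions follow the frame count and cluster bins", {
  present <- matrix(c(rep(TRUE, 50), rep(FALSE, 50)), 1)
  em <- structure(list(pairs = data.frame(donor = 1L, acceptor = 2L,
                                          chain = "A", res_seq = 1L,
                                          res_name = "SER", label = "p"),
                       present = present, times = 0:99),
                  class = "existence_matrix")
  expect_equal(residue_occupancy(em, "A", 1L)$fraction, 0.5)
  expect_equal(residue_occupancy(em, "A", 1L)$cluster, "moderate")

  expect_equal(classify_occupancy(0.25), "low")
  expect_equal(classify_occupancy(0.86), "high")
  expect_equal(classify_occupancy(0.30), "low")      # boundary convention
  expect_equal(classify_occupancy(0.70), "moderate")
  expect_equal(classify_occupancy(c(0, 1)), c("low", "high"))
  expect_error(classify_occupancy(1.2), "\\[0, 1\\]")
})

test_that("hydrophobic contacts are apolar carbon pairs within the cutoff", {
  s <- make_structure(c("CB", "CA", "C1", "O1"), c("C", "C", "C", "O"),
                      rbind(c(0, 0, 0), c(10, 0, 0), c(3.5, 0, 0), c(0, 3, 0)),
                      res_name = c("LEU", "LEU", "LIG", "LIG"),
                      res_seq = c(1L, 1L, 9L, 9L),
                      hetero = c(FALSE, FALSE, TRUE, TRUE))
  hc <- hydrophobic_contacts(s, s$xyz, 1:2, 3:4)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$protein_atom, 1L)
  expect_equal(hc$ligand_atom, 3L)
})
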