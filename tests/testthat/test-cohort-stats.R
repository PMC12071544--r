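test_that("box_stats uses type-7 quantiles and Tukey outliers", {
  b <- box_stats(1:9)
  expect_equal(b$q1, 3); expect_equal(b$median, 5); expect_equal(b$q3, 7)
  expect_equal(b$iqr, 4)
  expect_equal(b$siqr_l, 2); expect_equal(b$siqr_r, 2)

  bc <- box_stats(c(2, 2, 2, 2))
  expect_equal(bc$median, 2); expect_equal(bc$iqr, 0)
  expect_length(bc$outliers, 0L)

  # sample engineered to the printed residue-RMSD quartiles: IQR 0.8
  b2 <- box_stats(c(0.2, 0.7, 1.2, 1.5, 2.0))
  expect_equal(b2$q1, 0.7); expect_equal(b2$q3, 1.5)
  expect_equal(b2$iqr, 0.8, tolerance = 1e-12)

  bo <- box_stats(c(1, 2, 3, 4, 100))
  expect_equal(bo$outliers, 100)
  expect_error(box_stats(numeric(0)), "non-empty")
})

test_that("box_stats identities hold and match a brute-force interpolation oracle", {
  set.seed(5)
  for (n in c(1L, 2L, 7L, 30L)) {
    x <- rnorm(n)
    b <- box_stats(x)
    expect_equal(b$iqr, b$q3 - b$q1)
    expect_equal(b$siqr_l, b$median - b$q1)
    expect_equal(b$siqr_r, b$q3 - b$median)
    expect_true(b$q1 <= b$median && b$median <= b$q3)
    # independent sort-and-interpolate at positions (n-1)p
    s <- sort(x)
    interp <- function(p) {
      h <- (n - 1) * p
      lo <- floor(h) + 1
      if (lo >= n) s[n] else s[lo] + (h - floor(h)) * (s[lo + 1] - s[lo])
    }
    expect_equal(b$q1, interp(0.25), tolerance = 1e-12)
    expect_equal(b$median, interp(0.5), tolerance = 1e-12)
    expect_equal(b$q3, interp(0.75), tolerance = 1e-12)
  }
})

test_that("pocket composition pools unique residues per complex", {
  mk <- function(...) {
    rn <- c(...)
    data.frame(chain = "A", res_seq = seq_along(rn), res_name = rn)
  }
  ct <- pocket_composition(list(mk("ASP", "HIS"), mk("ASP", "ARG")))
  expect_equal(ct$fractions[["ASP"]], 0.5)
  expect_equal(ct$fractions[["HIS"]], 0.25)
  expect_equal(ct$fractions[["ARG"]], 0.25)
  expect_equal(sum(ct$fractions), 1, tolerance = 1e-9)

  expect_equal(pocket_composition(list(mk("GLY")))$fractions[["GLY"]], 1)

  # the same residue identity twice within one complex counts once
  dup <- data.frame(chain = "A", res_seq = c(5L, 5L), res_name = "ASP")
  expect_equal(pocket_composition(list(dup))$counts[["ASP"]], 1L)

  expect_error(pocket_composition(list(mk("GLY")[0, ])), "non-empty")
})

test_that("background composition counts protein residues only", {
  f <- write_tmp_pdb(peptide_pdb_text(with_ligand = TRUE))
  s <- read_structure(f)
  bg <- background_composition(list(s))
  expect_setequal(names(bg$counts), c("ALA", "GLY"))   # LIG never counted
  expect_equal(unname(bg$fractions[c("ALA", "GLY")]), c(0.5, 0.5))

  # pooled across structures: [ALA x3] + [ASP x1]
  mk1 <- make_structure(rep("CA", 3), rep("C", 3),
                        matrix(rnorm(9), 3, 3), res_name = "ALA",
                        res_seq = 1:3)
  mk2 <- make_structure("CA", "C", matrix(0, 1, 3), res_name = "ASP")
  bg2 <- background_composition(list(mk1, mk2))
  expect_equal(bg2$fractions[["ALA"]], 0.75)
  expect_equal(bg2$fractions[["ASP"]], 0.25)

  lig_only <- make_structure("C1", "C", matrix(0, 1, 3),
                             res_name = "LIG", hetero = TRUE)
  expect_error(background_composition(list(lig_only)), "no protein residues")
})

test_that("enrichment ratios, binomial p-values and class fractions are correct", {
  uniform_bg <- structure(list(
    counts = stats::setNames(rep(50L, 20), pocketdyn:::.aa20),
    fractions = stats::setNames(rep(0.05, 20), pocketdyn:::.aa20)),
    class = "composition_table")

  mk_pocket <- function(rn) {
    pocket_composition(list(
      data.frame(chain = "A", res_seq = seq_along(rn), res_name = rn)))
  }

  # null: pocket identical to background -> ratios 1, nothing significant
  nullp <- mk_pocket(rep(pocketdyn:::.aa20, 5))
  en0 <- enrichment(nullp, uniform_bg)
  expect_true(all(abs(en0$table$ratio - 1) < 1e-12))
  expect_false(any(en0$table$p_adjusted < 0.05))

  # strong enrichment: ASP x90 + GLY x10 against a uniform background
  en <- enrichment(mk_pocket(c(rep("ASP", 90), rep("GLY", 10))), uniform_bg)
  asp <- en$table[en$table$res_name == "ASP", ]
  expect_equal(asp$ratio, 18)
  expect_lt(asp$p_adjusted, 1e-10)
  # cross-check the raw p-value against the binomial tail oracle
  oracle_p <- stats::binom.test(90, 100, 0.05)$p.value
  expect_equal(asp$p_value, oracle_p, tolerance = 1e-12)

  # class fractions: ASP/HIS/ARG charged, ALA non-polar
  en2 <- enrichment(mk_pocket(c("ASP", "HIS", "ARG", "ALA")), uniform_bg)
  expect_equal(unname(en2$class_fractions["charged"]), 0.75)
  expect_equal(unname(en2$class_fractions["non_polar"]), 0.25)
  expect_equal(sum(en2$class_fractions), 1, tolerance = 1e-9)

  # pocket residue missing from the background is an explicit error
  tiny_bg <- structure(list(counts = c(GLY = 10L), fractions = c(GLY = 1)),
                       class = "composition_table")
  expect_error(enrichment(mk_pocket("ASP"), tiny_bg), "ASP")
})

test_that("under the null the BH-adjusted discovery rate stays controlled", {
  set.seed(17)
  uniform_bg <- structure(list(
    counts = stats::setNames(rep(50L, 20), pocketdyn:::.aa20),
    fractions = stats::setNames(rep(0.05, 20), pocketdyn:::.aa20)),
    class = "composition_table")
  n_sig <- 0L; n_tests <- 0L
  for (i in 1:40) {
    draw <- sample(pocketdyn:::.aa20, 60, replace = TRUE)
    pocket <- pocket_composition(list(
      data.frame(chain = "A", res_seq = seq_along(draw), res_name = draw)))
    en <- enrichment(pocket, uniform_bg)
    n_sig <- n_sig + sum(en$table$p_adjusted < 0.05)
    n_tests <- n_tests + nrow(en$table)
  }
  expect_lte(n_sig / n_tests, 0.05)
})
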