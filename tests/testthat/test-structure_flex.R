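# Hand-built minimal ATOM line with controllable fields (fixed PDB columns).
atom_line <- function(serial, resseq, b, altloc = " ", occ = 1, name = " CA ",
                      chain = "A", record = "ATOM  ") {
  paste0(record, sprintf("%5d", serial), " ", name, altloc, "ALA ", chain,
         sprintf("%4d", resseq), "    ",
         sprintf("%8.3f%8.3f%8.3f", resseq * 3.8, 0, 0),
         sprintf("%6.2f%6.2f", occ, b), "           C")
}

test_that("CA B-factors round-trip through a synthetic structure", {
  b <- c(10.0, 25.0, 30.0, 15.0, 22.0)
  txt <- synth_pdb(5, flexible_sites = stats::setNames(b, 1:5))
  rec <- read_calpha_bfactors(txt)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$b_factor, b)
  expect_equal(rec$resseq, 1:5)
  expect_true(all(rec$aa == "A"))
  expect_true(all(rec$ss == "unknown"))
})

test_that("alternate locations resolve to the highest-occupancy CA, tie -> first", {
  for (first_occ in list(c(0.4, 0.6), c(0.6, 0.4))) {
    lines <- c(atom_line(1, 1, 11.0, altloc = "A", occ = first_occ[1]),
               atom_line(2, 1, 22.0, altloc = "B", occ = first_occ[2]),
               "END")
    rec <- read_calpha_bfactors(paste(lines, collapse = "\n"))
    # oracle: scan for max occupancy, first encountered wins ties
    expect_equal(rec$b_factor, c(11.0, 22.0)[which.max(first_occ)])
  }
  # exact tie: the first altloc wins
  lines <- c(atom_line(1, 1, 11.0, altloc = "A", occ = 0.5),
             atom_line(2, 1, 22.0, altloc = "B", occ = 0.5), "END")
  expect_equal(read_calpha_bfactors(paste(lines, collapse = "\n"))$b_factor,
               11.0)
})

test_that("only the first MODEL is read and HETATM is ignored", {
  lines <- c("MODEL        1",
             atom_line(1, 1, 10.0), atom_line(2, 2, 20.0),
             atom_line(3, 3, 99.0, record = "HETATM"),
             "ENDMDL",
             "MODEL        2",
             atom_line(4, 1, 77.0), atom_line(5, 2, 88.0),
             "ENDMDL", "END")
  rec <- read_calpha_bfactors(paste(lines, collapse = "\n"))
  expect_equal(rec$b_factor, c(10.0, 20.0))
})

test_that("secondary structure labels come from HELIX/SHEET ranges", {
  txt <- synth_pdb(10, helix_ranges = list(c(2, 4)), sheet_ranges = list(c(7, 8)))
  rec <- read_calpha_bfactors(txt)
  expect_equal(rec$ss, c("coil", "helix", "helix", "helix", "coil", "coil",
                         "sheet", "sheet", "coil", "coil"))
})

test_that("parse failures are reported with context", {
  expect_error(read_calpha_bfactors("REMARK nothing here\nEND"),
               "no ATOM records")
  bad <- atom_line(1, 1, 10.0)
  substr(bad, 61, 66) <- "badval"
  expect_error(read_calpha_bfactors(paste(c(atom_line(1, 1, 1), bad, "END"),
                                          collapse = "\n")),
               "malformed ATOM record at line 2")
  # structure with atoms but no CA
  noca <- atom_line(1, 1, 10.0, name = " CB ")
  expect_error(read_calpha_bfactors(noca), "no ATOM records with a CA")
})

test_that("agrees with bio3d on a synthetic structure", {
  skip_if_not_installed("bio3d")
  txt <- synth_pdb(40, flexible_sites = c(`7` = 33.25, `21` = 28.5), seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, path)
  rec <- read_calpha_bfactors(path)
  ref <- bio3d::read.pdb(path)
  ca <- ref$atom[ref$atom$elety == "CA", ]
  expect_equal(rec$b_factor, ca$b)
  expect_equal(rec$resseq, ca$resno)
})

test_that("nomination selects strictly above the threshold with exclusions", {
  b <- c(10.0, 25.0, 30.0, 15.0, 22.0)
  rec <- read_calpha_bfactors(synth_pdb(5, stats::setNames(b, 1:5)))
  nom <- nominate_flexible_sites(rec, threshold = 21)
  expect_equal(nom$resseq[nom$selected], c(2L, 3L, 5L))
  expect_false(1L %in% nom$resseq)  # below threshold: absent, not excluded

  nom2 <- nominate_flexible_sites(rec, threshold = 21, exclude = 5)
  expect_equal(nom2$resseq[nom2$selected], c(2L, 3L))
  expect_match(nom2$exclusion_reason[nom2$resseq == 5], "exclusion list")
  # selected implies empty reason and b > threshold
  expect_true(all(nom2$exclusion_reason[nom2$selected] == ""))
  expect_true(all(nom2$b_factor > 21))
})

test_that("coil and terminus exclusion predicates fire", {
  txt <- synth_pdb(20, flexible_sites = c(`2` = 30, `10` = 30, `19` = 30),
                   baseline_mean = 10, baseline_sd = 0.5, seed = 2,
                   helix_ranges = list(c(9, 11), c(18, 20)))
  rec <- read_calpha_bfactors(txt)
  nom <- nominate_flexible_sites(rec, exclude_coil = TRUE, terminus_margin = 3)
  expect_equal(nom$resseq[nom$selected], 10L)
  expect_match(nom$exclusion_reason[nom$resseq == 2], "coil")
  expect_match(nom$exclusion_reason[nom$resseq == 19], "terminus")
})

test_that("nomination equals a brute-force scan on a random 200-residue fixture", {
  set.seed(11)
  rec <- read_calpha_bfactors(synth_pdb(200, baseline_mean = 20,
                                        baseline_sd = 4, seed = 11))
  nom <- nominate_flexible_sites(rec, threshold = 21)
  brute <- rec$resseq[rec$b_factor > 21.0]  # independent full scan
  expect_equal(nom$resseq[nom$selected], brute)
})

test_that("nomination is idempotent and monotone in the threshold", {
  rec <- read_calpha_bfactors(synth_pdb(80, baseline_mean = 21,
                                        baseline_sd = 3, seed = 3))
  nom <- nominate_flexible_sites(rec, threshold = 21)
  sel <- nom[nom$selected, c("chain", "resseq", "aa", "b_factor", "ss")]
  again <- nominate_flexible_sites(sel, threshold = 21)
  expect_true(all(again$selected))
  expect_equal(again$resseq, sel$resseq)

  for (thr in c(18, 21, 24, 27)) {
    lo <- nominate_flexible_sites(rec, threshold = thr)
    hi <- nominate_flexible_sites(rec, threshold = thr + 2)
    expect_true(all(hi$resseq[hi$selected] %in% lo$resseq[lo$selected]))
  }
  expect_error(nominate_flexible_sites(rec, threshold = -1),
               "invalid parameter")
})
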