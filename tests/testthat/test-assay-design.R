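# In-silico digestion, filtering, uniqueness, mass arithmetic, panel.

test_that("tryptic digestion follows the K/R rule with proline exception", {
  expect_equal(digest_protein("MKDSSFNSAYNLPIPRVLPESVSRK")$sequence,
               c("MK", "DSSFNSAYNLPIPR", "VLPESVSR", "K"))
  # K before P: no cleavage
  expect_equal(digest_protein("AAAKPGGGR")$sequence, "AAAKPGGGR")
  # no internal site: missed-cleavage setting is a no-op
  expect_equal(digest_protein("GGGGGGR", missed_cleavages = 1)$sequence,
               "GGGGGGR")
  expect_error(digest_protein(""), "non-empty")
  expect_error(digest_protein("ABCZ"), "non-canonical")
})

test_that("digestion positions are 1-based inclusive and masses positive", {
  d <- digest_protein(list(accession = "T", sequence = "MKDSSFNSAYNLPIPRVLPESVSRK"))
  expect_equal(d$end - d$start + 1L, nchar(d$sequence))
  expect_equal(d$parent_accession, rep("T", 4))
  expect_true(all(d$monoisotopic_mass > 0))
})

test_that("missed-cleavage enumeration joins adjacent fragments", {
  d <- digest_protein("AAKGGKVVK", missed_cleavages = 2)
  expect_setequal(d$sequence[d$missed_cleavages == 0], c("AAK", "GGK", "VVK"))
  expect_setequal(d$sequence[d$missed_cleavages == 1], c("AAKGGK", "GGKVVK"))
  expect_equal(d$sequence[d$missed_cleavages == 2], "AAKGGKVVK")
})

test_that("digestion partitions the sequence (property)", {
  set.seed(11)
  res <- names(AA_MONO_MASS)
  for (i in 1:25) {
    s <- paste(sample(res, sample(5:120, 1), replace = TRUE), collapse = "")
    d <- digest_protein(s)
    expect_identical(paste(d$sequence, collapse = ""), s)
    expect_equal(d$start[1], 1L)
    expect_equal(d$end[nrow(d)], nchar(s))
  }
})

test_that("candidate filtering applies every rule and lists all violations", {
  prot <- toy_proteome()
  cand <- rbind(digest_protein(prot[3, ]),
                data.frame(sequence = c("MKAAAA", "ASASAASAETLSHR"),
                           parent_accession = "X", start = 1,
                           end = c(6, 14), missed_cleavages = 0,
                           monoisotopic_mass = 1))
  out <- filter_candidates(cand, prot)
  expect_true("ISPNSPVAR" %in% out$kept$sequence)
  r1 <- out$rejected[out$rejected$sequence == "MKAAAA", "rejection_reasons"]
  expect_match(r1, "length<7")
  expect_match(r1, "contains-M")
  # histidine-bearing peptide from the published panel fails the strict
  # criteria (it entered the real panel via the shotgun carry-over route)
  r2 <- out$rejected[out$rejected$sequence == "ASASAASAETLSHR",
                     "rejection_reasons"]
  expect_match(r2, "contains-H")
  # kept + rejected partition the input; filtering the kept set again is a
  # no-op (idempotence)
  expect_equal(nrow(out$kept) + nrow(out$rejected), nrow(cand))
  again <- filter_candidates(out$kept, prot)
  expect_equal(nrow(again$rejected), 0)
  expect_equal(again$kept$sequence, out$kept$sequence)
})

test_that("filtering an empty candidate set returns empty outputs", {
  cand <- digest_protein("GGGGGGR")[0, ]
  out <- filter_candidates(cand, toy_proteome())
  expect_equal(nrow(out$kept), 0)
  expect_equal(nrow(out$rejected), 0)
})

test_that("uniqueness distinguishes unique, shared and absent peptides", {
  prot <- toy_proteome()
  u <- check_uniqueness("ISPNSPVAR", prot)
  expect_true(u$unique)
  expect_equal(u$matches, "T3")
  s <- check_uniqueness("VLPESVSR", prot)
  expect_false(s$unique)
  expect_equal(sort(s$matches), c("T1", "T2"))
  a <- check_uniqueness("WWWWWWW", prot)
  expect_false(a$unique)
  expect_length(a$matches, 0)
  expect_error(check_uniqueness("", prot), "at least 1 residue")
})

test_that("uniqueness agrees with the Biostrings oracle on random peptides", {
  prot <- demo_proteome(n_decoys = 10, seed = 3)
  subj <- Biostrings::AAStringSet(prot$sequence)
  set.seed(7)
  res <- setdiff(names(AA_MONO_MASS), c("U"))
  for (i in 1:100) {
    if (i <= 50) {  # half drawn from real entries so matches do occur
      row <- sample(nrow(prot), 1)
      n <- nchar(prot$sequence[row])
      a <- sample(n - 8, 1)
      pep <- substr(prot$sequence[row], a, a + sample(5:8, 1))
    } else {
      pep <- paste(sample(res, 8, replace = TRUE), collapse = "")
    }
    got <- check_uniqueness(pep, prot)
    oracle <- sum(Biostrings::vcountPattern(pep, subj) > 0)
    expect_identical(got$unique, oracle == 1L)
    expect_length(got$matches, oracle)
  }
})

test_that("I/L collapse mode treats isobaric peptides as shared", {
  prot <- data.frame(accession = c("A", "B"),
                     sequence = c("KKKLISPNSPVARKKK", "KKKIISPNSPVARKKK"))
  expect_true(check_uniqueness("LISPNSPVAR", prot)$unique)
  expect_false(check_uniqueness("LISPNSPVAR", prot, collapse_il = TRUE)$unique)
})

test_that("peptide masses match frozen monoisotopic values", {
  expect_equal(peptide_mass("ISPNSPVAR"), 939.5138, tolerance = 1e-4)
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 1e-4)
  expect_equal(peptide_mass("EGNVSISAFVAK", heavy = TRUE) -
                 peptide_mass("EGNVSISAFVAK"), 8.014199, tolerance = 1e-6)
  expect_equal(peptide_mass("ISPNSPVAR", heavy = TRUE) -
                 peptide_mass("ISPNSPVAR"), 10.008269, tolerance = 1e-6)
  expect_error(peptide_mass("ISPNSPVAX"), "non-canonical")
  expect_error(peptide_mass("GGGG", heavy = TRUE), "C-terminal K or R")
})

test_that("modifications add their deltas, capped at three per peptide", {
  expect_equal(peptide_mass("CCK", "carbamidomethyl-C") -
                 peptide_mass("CCK"), 57.021464, tolerance = 1e-6)
  expect_equal(
    peptide_mass("MCK", c("oxidation-M", "carbamidomethyl-C", "acetyl-Nterm")) -
      peptide_mass("MCK"),
    15.994915 + 57.021464 + 42.010565, tolerance = 1e-6)
  expect_error(peptide_mass("MMMMCK", rep("oxidation-M", 4)), "at most 3")
  expect_error(peptide_mass("GGK", "phospho-S"), "unknown modification")
})

test_that("precursor m/z follows the protonation formula", {
  expect_equal(precursor_mz(peptide_mass("ISPNSPVAR"), 2), 470.7642)
  expect_equal(precursor_mz(peptide_mass("VPLLHLSNFTNDWAELSTR"), 3), 738.3832)
  # zero-mass limit guards the proton constant
  expect_equal(precursor_mz(0, 2), round(PROTON_MASS, 4))
  expect_error(precursor_mz(100, 0), "positive")
})

test_that("fragment m/z covers y/b series and the heavy shift", {
  expect_equal(fragment_mz("ISPNSPVAR", "y", 1), 175.1190, tolerance = 1e-4)
  expect_equal(fragment_mz("GGAAK", "b", 2), 115.0502, tolerance = 1e-4)
  y5h <- fragment_mz("ISPNSPVAR", "y", 5, heavy = TRUE)
  y5l <- fragment_mz("ISPNSPVAR", "y", 5)
  expect_equal(y5h - y5l, 10.0083, tolerance = 1e-4)
  # doubly charged fragment halves the shift
  expect_equal(fragment_mz("ISPNSPVAR", "y", 5, charge = 2, heavy = TRUE) -
                 fragment_mz("ISPNSPVAR", "y", 5, charge = 2),
               10.008269 / 2, tolerance = 1e-4)
  expect_error(fragment_mz("ISPNSPVAR", "y", 9), "ordinal")
})

test_that("product-ion strings parse and reject garbage", {
  p <- parse_product_ions("y7+;y6+;b2+;y8++;p")
  expect_equal(p$ion_type, c("y", "y", "b", "y", "p"))
  expect_equal(p$ordinal, c(7L, 6L, 2L, 8L, NA))
  expect_equal(p$charge, c(1L, 1L, 1L, 2L, 1L))
  expect_error(parse_product_ions("z5+"), "unparseable")
})

test_that("panel round-trip reproduces every fixture precursor to 1e-3", {
  panel <- fixture_panel()
  v <- validate_panel_mz(panel)
  expect_true(all(v$dev_light <= 1e-3))
  expect_true(all(v$dev_heavy <= 1e-3))
})

test_that("heavy-light m/z gap equals label delta over charge (property)", {
  panel <- fixture_panel()
  cterm <- substr(panel$peptide, nchar(panel$peptide), nchar(panel$peptide))
  expected <- HEAVY_LABEL_DELTA[cterm] / panel$charge
  expect_true(all(abs((panel$heavy_mz - panel$light_mz) - expected) <= 1e-4))
})

test_that("panel construction from targets works end to end", {
  targets <- toy_proteome()[c(1, 3), ]
  prot <- toy_proteome()
  panel <- build_assay_panel(targets, prot,
                             spike_amounts = c(DSSFNSAYNLPIPR = 15,
                                               ISPNSPVAR = 10))
  # VLPESVSR is shared between T1 and T2, so only the unique peptides stay
  expect_setequal(panel$peptide, c("DSSFNSAYNLPIPR", "ISPNSPVAR"))
  expect_equal(nrow(panel), 2)
  expect_equal(panel$light_mz[panel$peptide == "ISPNSPVAR"], 470.7642)
  expect_equal(panel$heavy_mz[panel$peptide == "ISPNSPVAR"], 475.7683)
  expect_equal(panel$spike_fmol[panel$peptide == "ISPNSPVAR"], 10)
  # 2 rows x light/heavy = 4 scheduled precursors
  expect_equal(2L * nrow(panel), 4L)
  # extra peptides bypass the filters but must exist in a target
  p2 <- build_assay_panel(targets, prot, extra_peptides = "VLPESVSR")
  expect_true("VLPESVSR" %in% p2$peptide)
  expect_error(build_assay_panel(targets, prot, extra_peptides = "WWWWK"),
               "WWWWK")
  expect_equal(nrow(build_assay_panel(targets[0, ], prot)), 0)
})

test_that("panel CSV and transition list round-trip", {
  panel <- fixture_panel()
  tmp <- tempfile(fileext = ".csv")
  write_panel(panel, tmp)
  back <- read_panel(tmp)
  expect_equal(as.data.frame(back), as.data.frame(panel))
  tl <- export_transition_list(panel[1:2, ])
  expect_setequal(unique(tl$isotope), c("light", "heavy"))
  # the heavy label shifts y ions by the full label delta at charge 1
  y7 <- tl[tl$fragment == "y7" & tl$product_charge == 1 &
             tl$peptide == "ISPNSPVAR", ]
  expect_equal(abs(diff(y7$product_mz)), 10.0083, tolerance = 1e-3)
})

test_that("FASTA io round-trips and parses headers", {
  prot <- toy_proteome()
  tmp <- tempfile(fileext = ".fasta")
  write_fasta(prot, tmp)
  back <- read_fasta(tmp)
  expect_equal(back$accession, prot$accession)
  expect_equal(back$sequence, prot$sequence)
  expect_equal(back$description, prot$description)
  suppressWarnings(expect_error(read_fasta(tempfile()), "cannot open"))
})
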