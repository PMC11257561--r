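# Sequence electrostatics: molecular weight, Henderson-Hasselbalch net
# charge, pI, fusion arithmetic, FASTA I/O.

test_that("molecular weight sums average residue masses plus one water", {
  # glycine: 57.05 residue + 18.02 water = 75.07 Da
  expect_equal(molecular_weight("G"), 0.07507, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"),
               (2 * 57.0519 + 18.01528) / 1000, tolerance = 1e-9)
  expect_error(molecular_weight(""), "empty")
  expect_error(protein_species("GXZ"), "non-standard")
  expect_message(sp <- protein_species("GXG", permissive = TRUE), "skipping")
  expect_equal(sp$length, 2L)
})

test_that("bundled fixtures give the known vimentin and GFAP masses", {
  vim <- read_fasta(vimentin_fasta)[[1]]
  gf <- read_fasta(gfap_fasta)[[1]]
  expect_equal(nchar(vim), 466L)
  expect_equal(nchar(gf), 432L)
  expect_equal(molecular_weight(vim), 54, tolerance = 0.02)   # "54 kDa protein"
  expect_equal(molecular_weight(gf), 49.9, tolerance = 0.002)
})

test_that("Henderson-Hasselbalch midpoints and limits are exact", {
  pka <- pka_set("protcalc")
  # a lone Asp side chain at its own pKa contributes exactly -0.5
  expect_equal(net_charge("D", pH = pka[["D"]], pka = "protcalc",
                          termini = "none"), -0.5)
  # "DD" at pH 14: two side chains + C-terminus fully deprotonated
  expect_equal(net_charge("DD", 14, pka = "protcalc"), -3, tolerance = 0.01)
  # limiting charges at the pH extremes match the residue counts; all pKas
  # sit >= 2 units inside [0, 14], so each group is within 0.01 of its limit
  seqs <- c("ACDEFGHIKLMNPQRSTVWY", "DDKKHHCCYY", "KRKRE")
  for (sq in seqs) {
    sp <- protein_species(sq)
    z_acid <- -(sp$counts[["D"]] + sp$counts[["E"]] + sp$counts[["C"]] +
                  sp$counts[["Y"]] + 1)
    z_base <- sp$counts[["K"]] + sp$counts[["R"]] + sp$counts[["H"]] + 1
    expect_lt(abs(net_charge(sq, 0, pka = "protcalc") - z_base), 0.05)
    expect_lt(abs(net_charge(sq, 14, pka = "protcalc") - z_acid), 0.05)
  }
  expect_error(net_charge("D", pH = 15), "pH")
})

test_that("charge curves are strictly decreasing with a well-defined pI", {
  vim <- read_fasta(vimentin_fasta)[[1]]
  for (sq in list(vim, "ACDEFGHIKLMNPQRSTVWY", "KKKDDD")) {
    for (preset in c("protcalc", "emboss")) {
      cc <- charge_curve(sq, pH_lo = 1, pH_hi = 13.5, step = 0.05,
                         pka = preset)
      expect_true(all(diff(cc$curve$Z) < 0))
      expect_true(cc$pI_defined)
      expect_lt(abs(net_charge(sq, cc$pI, pka = preset)), 1e-3)
    }
  }
  # pI invariant under grid resolution (bisection does not use the grid)
  vim_coarse <- charge_curve(vim, step = 0.5)$pI
  vim_fine <- charge_curve(vim, step = 0.01)$pI
  expect_equal(vim_coarse, vim_fine, tolerance = 1e-6)
  # no ionizable groups -> pI undefined, not an error
  gly <- charge_curve("GGGG", pka = "protcalc")
  expect_true(gly$pI_defined)  # termini alone still titrate
})

test_that("fusion charge is additive and respects single-chain termini", {
  vim <- read_fasta(vimentin_fasta)[[1]]
  # identity: one component == net_charge
  expect_equal(fusion_charge(list(vim), 7.3), net_charge(vim, 7.3))
  # fixed-charge tags pass through: -18 + (-5) + 0 = -23
  expect_equal(fusion_charge(list(-18, -5, 0)), -23)
  # concatenation additivity is exact in single-chain mode
  a <- substr(vim, 1, 200); b <- substr(vim, 201, 466)
  expect_equal(fusion_charge(list(a, b), 7.3), net_charge(vim, 7.3),
               tolerance = 1e-12)
  expect_error(fusion_charge(list()), "non-empty")
  expect_error(fusion_charge(list(TRUE)), "sequences")
})

test_that("charged 11-aa linkers shift the construct charge as designed", {
  # 6 Asp in an 11-aa internal linker ~ -6 at pH 7.3; 6 Lys ~ +6
  expect_equal(net_charge("DDDDDGGGGGD", 7.3, termini = "none"), -6,
               tolerance = 0.01)
  expect_equal(net_charge("KKKKKGGGGGK", 7.3, termini = "none"), 6,
               tolerance = 0.06)
  # inserted into a fusion, the shift carries through
  vim <- read_fasta(vimentin_fasta)[[1]]
  base <- fusion_charge(list(vim, "GGGGGGGGGGG", vim), 7.3)
  neg <- fusion_charge(list(vim, "DDDDDGGGGGD", vim), 7.3)
  expect_equal(neg - base, -6, tolerance = 0.01)
})

test_that("FASTA reader handles multi-record files and rejects non-FASTA", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1 first record", "ACDE", "FGHI",
               ">seq2", "KLMN"), p)
  got <- read_fasta(p)
  expect_identical(got, c(seq1 = "ACDEFGHI", seq2 = "KLMN"))
  bad <- tempfile()
  writeLines("ACDE", bad)
  expect_error(read_fasta(bad), "not a FASTA")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("custom pKa sets are validated and honored", {
  custom <- pka_set("emboss")
  custom[["D"]] <- 5.0
  expect_equal(net_charge("D", 5.0, pka = custom, termini = "none"), -0.5)
  expect_error(pka_set(c(D = 4)), "must name")
  expect_error(pka_set("nonsense"), "unknown")
})
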