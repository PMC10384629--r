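test_that("the shipped codon table is well-formed", {
  tab <- loadCodonTable()
  expect_true(all(c(AA20, "*") %in% tab$aa))
  sums <- tapply(tab$fraction, tab$aa, sum)
  expect_true(all(abs(sums - 1) <= 0.01))
})

test_that("reverse translation round-trips through the genetic code", {
  expect_equal(reverseTranslate("M"), "ATG")
  set.seed(22)
  for (i in 1:100) {
    p <- randomPeptide(30)
    expect_equal(oracleTranslate(reverseTranslate(p)), p)
  }
})

test_that("site avoidance removes forbidden sequences, or errors honestly", {
  hind <- "AAGCTT"; xho <- "CTCGAG"
  set.seed(23)
  for (i in 1:30) {
    p <- randomPeptide(40)
    dna <- reverseTranslate(p, forbidden = c(hind, xho))
    expect_length(oracleFindSites(dna, hind), 0)
    expect_length(oracleFindSites(dna, xho), 0)
    expect_equal(oracleTranslate(dna), p)
  }
  # RSF encodes AGA|AGC|TTC = ..AAGCTT.. under top-ranked codons
  naive <- reverseTranslate("RSF")
  expect_gt(length(oracleFindSites(naive, hind)), 0)
  fixed <- reverseTranslate("RSF", forbidden = hind)
  expect_length(oracleFindSites(fixed, hind), 0)
  expect_equal(oracleTranslate(fixed), "RSF")
  # methionine has a single codon: forbidding ATG is unavoidable
  expect_error(reverseTranslate("M", forbidden = "ATG"), "exhausted")
})

test_that("restriction-site search reports overlapping hits in order", {
  hits <- findRestrictionSites("GGAAGCTTCC", "HindIII")
  expect_equal(hits$position, 3)
  expect_equal(findRestrictionSites("GGGG", c("HindIII", "XhoI"))$position,
               integer(0))
  # overlapping palindromic repeats vs the naive scan oracle
  dna <- "GGTACCGGTACCGGTACC"
  custom <- data.frame(name = "rep8", recognition = "CCGGTACC")
  got <- findRestrictionSites(dna, custom)
  expect_equal(got$position, oracleFindSites(dna, "CCGGTACC"))
  expect_error(findRestrictionSites("GGXX", "HindIII"), "outside ACGT")
})

test_that("expression inserts carry flanks once and translate back", {
  set.seed(24)
  p <- SeqRecord("p10", randomPeptide(10))
  con <- assembleExpressionInsert(p)
  dna <- constructDna(con)
  # 6 nt flank + ATG + 30 nt + stop + 6 nt flank (initiator M added)
  expect_equal(nchar(dna), 6 + 3 + 30 + 3 + 6)
  expect_equal((con@orfEnd - con@orfStart + 1) %% 3, 0)
  orf <- substr(dna, con@orfStart, con@orfEnd)
  expect_equal(oracleTranslate(orf), paste0("M", seqStr(p)))
  expect_equal(oracleFindSites(dna, "AAGCTT"), 1)
  expect_equal(oracleFindSites(dna, "CTCGAG"), nchar(dna) - 5)
  # adversarial: RSF would naively embed a HindIII site inside the ORF
  con2 <- assembleExpressionInsert(SeqRecord("adv", "MRSFRSFRSF"))
  expect_equal(oracleFindSites(constructDna(con2), "AAGCTT"), 1)
})

test_that("strain probes fuse FRB-reporter-FKBP with in-frame junctions", {
  set.seed(25)
  frb <- SeqRecord("FRB", paste0("M", randomPeptide(92)))
  fkbp <- SeqRecord("FKBP", randomPeptide(107))
  reporter <- SeqRecord("aluc", randomPeptide(194))
  res <- assembleStrainProbe(frb, reporter, fkbp)
  expect_s4_class(res$layout, "ProbeLayout")
  expect_equal(names(res$layout@parts),
               c("partner_n", "reporter", "partner_c"))
  con <- res$construct
  orf <- substr(constructDna(con), con@orfStart, con@orfEnd)
  prot <- oracleTranslate(orf)
  # junctions GT (KpnI) and GS (BamHI) add 2 residues each
  expect_equal(nchar(prot), 93 + 194 + 107 + 4)
  expect_equal(prot, paste0(seqStr(frb), "GT", seqStr(reporter), "GS",
                            seqStr(fkbp)))
  # each cloning site occurs exactly once
  for (site in c("AAGCTT", "GGTACC", "GGATCC", "CTCGAG"))
    expect_length(oracleFindSites(constructDna(con), site), 1)
})

test_that("strain probes refuse reporters that still carry an SP", {
  set.seed(26)
  rep_sp <- SeqRecord("aluc", randomPeptide(211),
                      annotations = data.frame(label = "SP", start = 1,
                                               end = 17))
  frb <- SeqRecord("FRB", randomPeptide(93))
  fkbp <- SeqRecord("FKBP", randomPeptide(107))
  expect_error(assembleStrainProbe(frb, rep_sp, fkbp), "SP annotation")
  # stripping first resolves it
  res <- assembleStrainProbe(frb, stripSignalPeptide(rep_sp), fkbp)
  expect_s4_class(res$construct, "NucleotideConstruct")
})

test_that("dissection sites sit at midpoints of helix-flanked coils", {
  rec11 <- SeqRecord("x", "MKTAYIAKQRQ")
  sites <- proposeDissectionSites(rec11, "HHHHCCCHHHH")
  expect_equal(sites$after_residue, 6)
  expect_equal(sites$c_frag_len, 5)
  expect_equal(nrow(proposeDissectionSites(rec11, strrep("H", 11))), 0)
  rec16 <- SeqRecord("y", "MKTAYIAKQRQWEDFH")
  sites2 <- proposeDissectionSites(rec16, "CCHHHHCCCCHHHHCC")
  expect_equal(nrow(sites2), 1)
  expect_equal(sites2$after_residue, 8)
  expect_error(proposeDissectionSites(rec11, "HHH"), "length")
  expect_error(proposeDissectionSites(rec11, "HHHHXCCHHHH"), "H/E/C")
})

test_that("PCA probes record fragment lengths and reconstitute intact", {
  set.seed(27)
  rep201 <- SeqRecord("aluc60", paste0("M", randomPeptide(200)))
  res <- assemblePcaProbe(rep201, 157,
                          insert = SeqRecord("erlbd", randomPeptide(30)))
  expect_equal(pcaFragmentLengths(res$layout),
               c(n_frag_len = 157, c_frag_len = 44))
  con <- res$construct
  expect_equal((con@orfEnd - con@orfStart + 1) %% 3, 0)
  orf <- substr(constructDna(con), con@orfStart, con@orfEnd)
  expect_equal(oracleTranslate(orf),
               paste0(substr(seqStr(rep201), 1, 157), "GT",
                      seqStr(res$layout@parts$insert), "GS",
                      substr(seqStr(rep201), 158, 201)))
  # empty insert without junctions reconstitutes the reporter exactly
  res0 <- assemblePcaProbe(rep201, 157, junctions = FALSE)
  orf0 <- substr(constructDna(res0$construct), res0$construct@orfStart,
                 res0$construct@orfEnd)
  expect_equal(oracleTranslate(orf0), seqStr(rep201))
  # the shorter reporter dissection leaves the same 44-residue C fragment
  rep194 <- SeqRecord("aluc65", paste0("M", randomPeptide(193)))
  res65 <- assemblePcaProbe(rep194, 150)
  expect_equal(pcaFragmentLengths(res65$layout)[["c_frag_len"]], 44)
  expect_error(assemblePcaProbe(rep201, 201), "out of range")
})
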