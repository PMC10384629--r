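test_that("flexible-residue splitting reproduces the canonical sub-blocks", {
  expect_equal(splitAtFlexible(GROUP1_DONOR, explicit_cuts = c(8, 15)),
               c("GRCHSYEG", "DKDTGQG", "GIGEPI"))
  expect_equal(splitAtFlexible(GROUP2_DONOR, explicit_cuts = c(7, 14)),
               c("DRCASFA", "DKIQKEV", "DYIKGLAG"))
  # no flexible residues: single fragment
  expect_equal(splitAtFlexible("DDDDDD"), "DDDDDD")
  # direct-scan candidate positions (G/I/A/V residues)
  expect_equal(flexibleCutCandidates(GROUP1_DONOR),
               c(1, 8, 13, 15, 16, 17, 18, 21))
  expect_error(splitAtFlexible(GROUP1_DONOR, explicit_cuts = c(9)),
               "not after a flexible residue")
  expect_error(splitAtFlexible(""), "empty")
})

test_that("fragment concatenation is lossless for greedy cuts", {
  set.seed(14)
  for (i in 1:20) {
    block <- randomPeptide(sample(6:30, 1))
    frags <- splitAtFlexible(block)
    expect_equal(paste(frags, collapse = ""), block)
  }
})

test_that("derived blocks nest cumulatively at the vacancy anchor", {
  v <- new("VacantRegion", targetRow = 1L, colStart = 51L, colEnd = 71L,
           anchorResidue = 50L,
           donors = c(row1 = "", row2 = GROUP1_DONOR,
                      row3 = GROUP2_DONOR))
  b1 <- deriveBlocks(v, donor_row = 2, cuts = c(8, 15))
  expect_equal(vapply(b1, function(b) nchar(b@seq), 1L), c(8L, 15L, 21L))
  expect_true(all(vapply(b1, function(b) b@anchor, 1L) == 51L))
  expect_equal(b1[[3]]@seq, GROUP1_DONOR)
  b2 <- deriveBlocks(v, donor_row = 3, cuts = c(7, 14))
  expect_equal(vapply(b2, function(b) nchar(b@seq), 1L), c(7L, 14L, 22L))
  # a donor with no internal cut yields one block equal to the donor
  v2 <- new("VacantRegion", targetRow = 1L, colStart = 10L, colEnd = 15L,
            anchorResidue = 9L,
            donors = c(row1 = "", row2 = "DDDDDD", row3 = ""))
  b3 <- deriveBlocks(v2, donor_row = 2)
  expect_length(b3, 1)
  expect_equal(b3[[1]]@seq, "DDDDDD")
  expect_error(deriveBlocks(v2, donor_row = 3), "empty")
})

test_that("insertion variants have the superscript-coordinate lengths", {
  set.seed(15)
  tmpl <- SeqRecord("tpl", randomPeptide(194))
  ser <- generateVariantSeries(tmpl, group1Blocks(),
                               naming = c("v8", "v15", "v21"))
  tab <- variantTable(ser)
  # 194 + block + 4-residue tag
  expect_equal(tab$length, 194 + c(8, 15, 21) + 4)
  spans <- lapply(variants(ser), function(v) v@insertedSpan)
  expect_equal(vapply(spans, `[`, 1L, 1), rep(51L, 3))
  expect_equal(vapply(spans, `[`, 1L, 2), c(58L, 65L, 71L))
  # inserted_span end = anchor + block length - 1
  for (v in variants(ser))
    expect_equal(v@insertedSpan[2],
                 v@insertedSpan[1] + nchar(v@edits[[1]]$payload) - 1L)
})

test_that("substitution variants keep length and change only the span", {
  set.seed(16)
  tmpl <- SeqRecord("tpl", randomPeptide(194))
  ser <- generateVariantSeries(tmpl, substitutions = list(
    editSubstitution(47, 50, "KWLP")), naming = "sub", tag = "")
  v <- getVariant(ser, "sub")
  expect_equal(nchar(v@seq), 194)
  diffs <- which(strsplit(v@seq, "")[[1]] !=
                   strsplit(seqStr(tmpl), "")[[1]])
  expect_true(all(diffs %in% 47:50))
  expect_equal(substr(v@seq, 47, 50), "KWLP")
  expect_error(editSubstitution(47, 50, "KWL"), "length differs")
})

test_that("an empty design yields only the tagged template", {
  tmpl <- SeqRecord("tpl", "MAGTR")
  ser <- generateVariantSeries(tmpl, naming = "only")
  expect_length(variants(ser), 1)
  expect_equal(getVariant(ser, "only")@seq, "MAGTRKDEL")
})

test_that("the full compensation scheme yields ten reversible variants", {
  set.seed(17)
  tmpl <- SeqRecord("tpl", randomPeptide(194))
  ser <- buildSiblingVariants(tmpl, group1Blocks(), group2Blocks(),
                              editSubstitution(47, 50, "KWLP"))
  expect_length(variants(ser), 10)
  expect_equal(variantNames(ser),
               c("ALuc55", "ALuc56", "ALuc57", "ALuc60", "ALuc61",
                 "ALuc62", "ALuc65", "ALuc66", "ALuc67", "ALuc68"))
  expect_equal(getVariant(ser, "ALuc57")@insertedSpan[2], 71L)
  expect_equal(getVariant(ser, "ALuc62")@insertedSpan[2], 72L)
  # every variant reverts to the template exactly
  for (v in variants(ser))
    expect_equal(revertVariant(v), seqStr(tmpl), info = v@name)
  # all variants end with the retention tag
  expect_true(all(endsWith(vapply(variants(ser), function(v) v@seq, ""),
                           "KDEL")))
  expect_error(
    generateVariantSeries(tmpl, group1Blocks(),
                          naming = c("a", "a", "b")), "duplicate")
})

test_that("compensation raises the consensus score of the self-alignment", {
  # plant the canonical donor inside the domain so the vacancy donor is
  # the printed block, then compensate the N-region with it
  set.seed(18)
  domain <- randomPeptide(90)
  domain <- paste0(substr(domain, 1, 50), GROUP1_DONOR,
                   substr(domain, 72, 90))
  rec <- generateSyntheticFamily(
    familyRecipe(seed = 18, sp_len = 0, domain_len = 90,
                 vacancy = c(50, 21), n_mut_rate = 0,
                 domain_seq = domain), id = "syn")
  expect_equal(attr(rec, "planted_block"), GROUP1_DONOR)
  pr <- partitionRepeats(rec)
  aln0 <- stackRegions(pr)
  before <- consensusScore(aln0)
  vac <- detectVacantRegions(aln0)[[1]]
  blocks <- deriveBlocks(vac, donor_row = 2, cuts = c(8, 15))
  ser <- generateVariantSeries(rec, blocks[3],
                               naming = "comp", tag = "")
  comp <- getVariant(ser, "comp")@seq
  b <- pr$boundaries
  aln1 <- stackRegions(list(
    n_region = substr(comp, 1, b[1] + 21),
    domain1 = substr(comp, b[1] + 22, b[2] + 21),
    domain2 = substr(comp, b[2] + 22, nchar(comp))))
  expect_gte(consensusScore(aln1), before)
})

test_that("series export writes FASTA and a JSON manifest", {
  set.seed(19)
  tmpl <- SeqRecord("tpl", randomPeptide(60))
  ser <- generateVariantSeries(tmpl, group1Blocks(anchor = 21),
                               naming = c("a", "b", "c"))
  fa <- tempfile(fileext = ".fasta")
  js <- tempfile(fileext = ".json")
  exportSeries(ser, fa, js)
  back <- readFasta(fa)
  expect_equal(vapply(back, recordId, ""), c("a", "b", "c"))
  man <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(man$name, c("a", "b", "c"))
  expect_equal(man$length, 60 + c(8, 15, 21) + 4)
})
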