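test_that("self-alignment is gapless with the diagonal score", {
  s <- "GRCHSYEG"
  aln <- globalAlign(s, s)
  expect_equal(aln@rowA, s)
  expect_equal(aln@rowB, s)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  chars <- strsplit(s, "")[[1]]
  expect_equal(aln@score, sum(diag(e$BLOSUM62[chars, chars])))
})

test_that("aligning against an empty sequence costs one affine gap run", {
  aln <- globalAlign("GRCH", "")
  expect_equal(aln@rowA, "GRCH")
  expect_equal(aln@rowB, "----")
  expect_equal(aln@score, -(10 + 4 * 0.5))
  expect_error(globalAlign("", ""), "both sequences empty")
})

test_that("optimal scores match the exhaustive-enumeration oracle", {
  scheme <- defaultScheme()
  seqs <- unlist(lapply(1:2, function(L)
    apply(expand.grid(rep(list(c("G", "A", "V")), L)), 1, paste,
          collapse = "")))
  for (a in seqs) for (b in seqs)
    expect_equal(globalAlign(a, b, scheme)@score,
                 oracleAlignScore(a, b, scheme),
                 info = paste(a, b))
  # a handful of longer random pairs
  set.seed(5)
  for (i in 1:10) {
    a <- randomPeptide(sample(2:5, 1))
    b <- randomPeptide(sample(2:5, 1))
    expect_equal(globalAlign(a, b, scheme)@score,
                 oracleAlignScore(a, b, scheme), info = paste(a, b))
  }
})

test_that("alignment score is symmetric and rows ungap to the inputs", {
  set.seed(6)
  for (i in 1:10) {
    a <- randomPeptide(sample(5:40, 1))
    b <- randomPeptide(sample(5:40, 1))
    f <- globalAlign(a, b)
    r <- globalAlign(b, a)
    expect_equal(f@score, r@score)
    expect_equal(gsub("-", "", f@rowA), a)
    expect_equal(gsub("-", "", f@rowB), b)
    ca <- strsplit(f@rowA, "")[[1]]
    cb <- strsplit(f@rowB, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
})

test_that("repeat partitioning finds exact-copy boundaries", {
  set.seed(7)
  a <- randomPeptide(30)
  b <- randomPeptide(80)
  rec <- SeqRecord("syn", paste0(a, b, b))
  pr <- partitionRepeats(rec)
  expect_equal(pr$boundaries, c(30, 110))
  expect_equal(pr$identity, 1)
  expect_equal(seqStr(pr$n_region), a)
  expect_equal(seqStr(pr$domain1), b)
  expect_equal(seqStr(pr$domain2), b)
})

test_that("partitioning tolerates domain divergence within a few residues", {
  set.seed(8)
  ok <- 0L
  for (i in 1:5) {
    a <- randomPeptide(30)
    b <- randomPeptide(80)
    chars <- strsplit(b, "")[[1]]
    hit <- runif(80) < 0.1
    for (j in which(hit)) chars[j] <- sample(setdiff(AA20, chars[j]), 1)
    rec <- SeqRecord("syn", paste0(a, b, paste(chars, collapse = "")))
    pr <- partitionRepeats(rec)
    if (max(abs(pr$boundaries - c(30, 110))) <= 3) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("explicit boundaries are honoured verbatim", {
  set.seed(9)
  rec <- SeqRecord("syn", randomPeptide(120))
  pr <- partitionRepeats(rec, boundaries = c(33, 77))
  expect_equal(pr$boundaries, c(33, 77))
  expect_equal(seqLength(pr$n_region), 33)
  expect_equal(seqLength(pr$domain1), 44)
  expect_error(partitionRepeats(rec, boundaries = c(77, 33)), "boundaries")
  expect_error(partitionRepeats(SeqRecord("s", randomPeptide(20))),
               "too short")
})

test_that("stacking identical regions produces a gapless alignment", {
  set.seed(10)
  b <- randomPeptide(60)
  aln <- stackRegions(list(n_region = b, domain1 = b, domain2 = b))
  expect_equal(alnWidth(aln), 60)
  expect_false(any(grepl("-", alnRows(aln))))
  expect_equal(consensusScore(aln), 1)
})

test_that("a deleted block in the N-region shows as an all-gap run", {
  set.seed(12)
  b <- randomPeptide(70)
  nreg <- paste0(substr(b, 1, 30), substr(b, 39, 70))  # drop 8 residues
  aln <- stackRegions(list(n_region = nreg, domain1 = b, domain2 = b))
  expect_gte(alnWidth(aln), 70)
  runs <- rle(strsplit(alnRows(aln)[1], "")[[1]] == "-")
  expect_gte(max(runs$lengths[runs$values]), 8)
  # ungapping recovers each source region
  expect_equal(gsub("-", "", alnRows(aln)[1]), nreg)
  expect_equal(gsub("-", "", alnRows(aln)[2]), b)
  expect_equal(gsub("-", "", alnRows(aln)[3]), b)
  expect_error(stackRegions(list(n_region = "", domain1 = b,
                                 domain2 = b)), "non-empty")
})

test_that("vacancy detection reports spans, anchors and donors", {
  # constructed alignment: row 1 vacant across columns 51-71
  set.seed(13)
  left <- randomPeptide(50)
  block <- randomPeptide(21)
  right <- randomPeptide(19)
  r2 <- paste0(left, block, right)
  r1 <- paste0(left, strrep("-", 21), right)
  aln <- makeAlignment(r1, r2, r2)
  vac <- detectVacantRegions(aln, target_row = 1, min_len = 5)
  expect_length(vac, 1)
  v <- vac[[1]]
  expect_equal(v@colStart, 51L)
  expect_equal(v@colEnd, 71L)
  expect_equal(v@anchorResidue, 50L)
  expect_equal(v@donors[["row2"]], block)
  expect_equal(v@donors[["row3"]], block)
  # gapless alignment: nothing to report
  expect_length(detectVacantRegions(makeAlignment(r2, r2, r2)), 0)
  # short runs are filtered by min_len
  r1s <- paste0(left, "---", substr(r2, 54, nchar(r2)))
  expect_length(detectVacantRegions(makeAlignment(r1s, r2, r2),
                                    min_len = 5), 0)
  expect_error(detectVacantRegions(aln, target_row = 4), "out of range")
})

test_that("consensus score counts majority agreement per column", {
  expect_equal(consensusScore(makeAlignment("GRCH", "GRCH", "GRCH")), 1)
  expect_equal(consensusScore(makeAlignment("----", "GRCH", "GRCH")), 0)
  # hand-enumerated 5-column case:
  # col1 G,G,A -> majority G, row1 matches
  # col2 R,K,K -> majority K, row1 does not
  # col3 -,C,C -> row1 gap, no match
  # col4 H,H,D -> majority H, match
  # col5 S,T,A -> three-way tie, row1 in majority set -> match
  aln <- makeAlignment("GR-HS", "GKCHT", "AKCDA")
  expect_equal(consensusScore(aln), 3 / 5)
})
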