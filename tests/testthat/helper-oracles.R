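# independent oracles used across test files; these deliberately avoid the
# package's own code paths

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomPeptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# exhaustive enumeration of all global alignments (no gap/gap columns);
# each maximal gap run of length L costs gapOpen + L * gapExtend
oracleAlignScore <- function(a, b, scheme = defaultScheme()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  mat <- scheme@matrix; go <- scheme@gapOpen; ge <- scheme@gapExtend
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i == n && j == m) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i < n && j < m)
      rec(i + 1L, j + 1L, score + mat[av[i + 1L], bv[j + 1L]], "M")
    if (i < n)
      rec(i + 1L, j, score - ge - if (last != "X") go else 0, "X")
    if (j < m)
      rec(i, j + 1L, score - ge - if (last != "Y") go else 0, "Y")
  }
  rec(0L, 0L, 0, "M")
  best
}

# two-stage pH grid scan: coarse 1e-3 sweep of |net charge|, then a 1e-5
# refinement around the coarse minimum
oracleGridPI <- function(seq, pka = loadPkaTable()) {
  counts <- table(strsplit(seq, "")[[1]])
  charge <- function(pH) {
    pos <- 1 / (1 + 10^(pH - pka$nterm))
    neg <- -1 / (1 + 10^(pka$cterm - pH))
    for (aa in c("K", "R", "H"))
      if (!is.na(counts[aa]))
        pos <- pos + counts[[aa]] / (1 + 10^(pH - pka$sidechain[[aa]]))
    for (aa in c("D", "E", "C", "Y"))
      if (!is.na(counts[aa]))
        neg <- neg - counts[[aa]] / (1 + 10^(pka$sidechain[[aa]] - pH))
    pos + neg
  }
  coarse <- seq(0, 14, by = 1e-3)
  i <- which.min(abs(charge(coarse)))
  fine <- seq(max(0, coarse[i] - 2e-3), min(14, coarse[i] + 2e-3),
              by = 1e-5)
  fine[which.min(abs(charge(fine)))]
}

# naive O(n*m) substring scan including overlaps
oracleFindSites <- function(dna, pattern) {
  n <- nchar(dna); m <- nchar(pattern)
  which(vapply(seq_len(n - m + 1L), function(i)
    substr(dna, i, i + m - 1L) == pattern, logical(1)))
}

# standard-genetic-code translation via Biostrings (independent of the
# package's reverse-translation path)
oracleTranslate <- function(dna)
  sub("\\*$", "",
      as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                         no.init.codon = TRUE)))

# build a three-row alignment object directly (bypasses stackRegions)
makeAlignment <- function(r1, r2, r3, id = "manual")
  new("RepeatAlignment", rows = c(r1, r2, r3), sourceId = id)

# synthetic PDB ATOM text from a data.frame(chain, resno, resid, elety,
# x, y, z)
pdbText <- function(at) {
  paste(vapply(seq_len(nrow(at)), function(i)
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, at$elety[i], at$resid[i], at$chain[i], at$resno[i],
            at$x[i], at$y[i], at$z[i]), character(1)),
    collapse = "\n")
}

# paper-style donor blocks used in design tests
GROUP1_DONOR <- "GRCHSYEGDKDTGQGGIGEPI"   # cuts after 8 and 15
GROUP2_DONOR <- "DRCASFADKIQKEVDYIKGLAG"  # cuts after 7 and 14

group1Blocks <- function(anchor = 51L)
  lapply(c(8L, 15L, 21L), function(k)
    peptideBlock(substr(GROUP1_DONOR, 1, k), anchor))

group2Blocks <- function(anchor = 51L)
  lapply(c(7L, 14L, 22L), function(k)
    peptideBlock(substr(GROUP2_DONOR, 1, k), anchor))
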