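#' Default scoring scheme (BLOSUM62, affine gaps)
#'
#' BLOSUM62 substitution scores with gap opening 10 and extension 0.5; a
#' gap run of length L costs `10 + 0.5 * L`. End gaps are penalized, so
#' scores are true global optima and reproducible bit-for-bit.
#'
#' @param matrix substitution matrix (residue dimnames); default BLOSUM62.
#' @param gapOpen,gapExtend affine gap penalties (non-negative).
#' @return a [ScoringScheme-class].
#' @export
defaultScheme <- function(matrix = NULL, gapOpen = 10, gapExtend = 0.5) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  storage.mode(matrix) <- "double"
  new("ScoringScheme", matrix = matrix, gapOpen = gapOpen,
      gapExtend = gapExtend)
}

encodeSeq <- function(s, alphabet) {
  if (!nzchar(s)) return(integer(0))
  idx <- match(strsplit(s, "")[[1]], alphabet)
  if (anyNA(idx))
    stop("residue not covered by the scoring matrix: ",
         strsplit(s, "")[[1]][which(is.na(idx))[1]])
  idx - 1L
}

decodeRow <- function(row, alphabet) {
  codes <- utf8ToInt(row)
  out <- rep("-", length(codes))
  keep <- codes != utf8ToInt("-")
  out[keep] <- alphabet[codes[keep] - utf8ToInt("A") + 1L]
  paste(out, collapse = "")
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment with end gaps penalized. The traceback
#' tie-break is fixed (diagonal > up > left) so alignments are
#' deterministic.
#'
#' @param a,b protein strings or [SeqRecord-class]; `b` may be empty,
#'   yielding an all-gap row.
#' @param scheme a [ScoringScheme-class]; see [defaultScheme()].
#' @return a [PairwiseAln-class] with `rowA`, `rowB` and `score`.
#' @examples
#' aln <- globalAlign("GRCHSYEG", "GRCHSYEG")
#' aln@score
#' @export
globalAlign <- function(a, b, scheme = defaultScheme()) {
  a <- if (is(a, "SeqRecord")) seqStr(a) else toupper(a)
  b <- if (is(b, "SeqRecord")) seqStr(b) else toupper(b)
  if (!nzchar(a) && !nzchar(b)) stop("both sequences empty")
  alph <- rownames(scheme@matrix)
  if (!nzchar(a) || !nzchar(b)) {
    n <- max(nchar(a), nchar(b))
    score <- -(scheme@gapOpen + n * scheme@gapExtend)
    rowA <- if (nzchar(a)) a else strrep("-", n)
    rowB <- if (nzchar(b)) b else strrep("-", n)
    return(new("PairwiseAln", rowA = rowA, rowB = rowB, score = score))
  }
  res <- .nw_affine(encodeSeq(a, alph), encodeSeq(b, alph), scheme@matrix,
                    scheme@gapOpen, scheme@gapExtend)
  new("PairwiseAln", rowA = decodeRow(res$row_a, alph),
      rowB = decodeRow(res$row_b, alph), score = res$score)
}

#' Fraction of identical columns in a pairwise alignment
#'
#' @param aln a [PairwiseAln-class].
#' @param denominator `"all"` counts every alignment column (default);
#'   `"ungapped"` counts only columns where both rows carry a residue.
#' @return identity fraction in \[0, 1\].
#' @export
alignmentIdentity <- function(aln, denominator = c("all", "ungapped")) {
  denominator <- match.arg(denominator)
  a <- strsplit(aln@rowA, "")[[1]]
  b <- strsplit(aln@rowB, "")[[1]]
  match_n <- sum(a == b & a != "-")
  den <- if (denominator == "all") length(a) else sum(a != "-" & b != "-")
  if (den == 0) return(0)
  match_n / den
}

#' Partition a luciferase into N-region and two repeat domains
#'
#' Copepod luciferases carry two homologous catalytic domains after a
#' flexible N-terminal region. Given two boundary positions `(b1, b2)` the
#' sequence is cut into residues `1..b1` (N-region), `b1+1..b2` (domain 1)
#' and `b2+1..end` (domain 2). Without explicit boundaries the pair
#' maximizing the domain1-domain2 global alignment score is searched: the
#' N-region length is restricted to `[20, 0.45 * length]`, the domain
#' length difference to 15% of the mean domain length, and a coarse grid
#' (step 5) is refined at step 1 within +/-5 of the best coarse point.
#'
#' @param record protein [SeqRecord-class], length >= 30.
#' @param scheme a [ScoringScheme-class].
#' @param boundaries optional integer(2) of explicit 1-based split
#'   positions (end of N-region, end of domain 1), returned verbatim.
#' @return list with `n_region`, `domain1`, `domain2` ([SeqRecord-class]),
#'   `boundaries` and the achieved `identity` between the domains.
#' @export
partitionRepeats <- function(record, scheme = defaultScheme(),
                             boundaries = NULL) {
  s <- seqStr(record)
  L <- nchar(s)
  if (L < 30L) stop("sequence too short to partition (need >= 30 residues)")
  cut3 <- function(b1, b2) list(
    n_region = SeqRecord(paste0(recordId(record), "_N"), substr(s, 1, b1)),
    domain1 = SeqRecord(paste0(recordId(record), "_D1"),
                        substr(s, b1 + 1, b2)),
    domain2 = SeqRecord(paste0(recordId(record), "_D2"),
                        substr(s, b2 + 1, L)))
  scoreOf <- function(b1, b2)
    globalAlign(substr(s, b1 + 1, b2), substr(s, b2 + 1, L), scheme)
  feasible <- function(b1, b2) {
    d1 <- b2 - b1; d2 <- L - b2
    d1 >= 1 && d2 >= 1 && abs(d1 - d2) <= 0.15 * (d1 + d2) / 2
  }
  if (!is.null(boundaries)) {
    b1 <- as.integer(boundaries[1]); b2 <- as.integer(boundaries[2])
    if (!(b1 >= 1 && b1 < b2 && b2 < L))
      stop("boundaries must be strictly increasing and inside the sequence")
    aln <- scoreOf(b1, b2)
    out <- cut3(b1, b2)
    out$boundaries <- c(b1, b2)
    out$identity <- alignmentIdentity(aln)
    return(out)
  }
  b1_max <- floor(0.45 * L)
  if (b1_max < 20L) stop("sequence too short for the N-region bounds")
  cand <- list()
  scan <- function(b1s, b2s) {
    for (b1 in b1s) for (b2 in b2s) {
      if (b2 <= b1 + 1 || b2 >= L || !feasible(b1, b2)) next
      cand[[length(cand) + 1L]] <<-
        c(b1 = b1, b2 = b2, score = scoreOf(b1, b2)@score)
    }
  }
  b1_grid <- unique(c(seq(20L, b1_max, by = 5L), b1_max))
  scan(b1_grid, unique(c(seq(21L, L - 1L, by = 5L), L - 1L)))
  if (!length(cand)) stop("no feasible boundary pair found")
  coarse <- do.call(rbind, cand)
  # refine at step 1 around the three best coarse cells; the score
  # surface has shifted-phase local optima when the N-region is close to
  # the domains, so a single-point refinement can miss the global one
  top <- coarse[order(-coarse[, "score"]), , drop = FALSE]
  top <- top[seq_len(min(8L, nrow(top))), , drop = FALSE]
  for (r in seq_len(nrow(top)))
    scan(max(20L, top[r, "b1"] - 5L):min(b1_max, top[r, "b1"] + 5L),
         max(2L, top[r, "b2"] - 5L):min(L - 1L, top[r, "b2"] + 5L))
  all <- do.call(rbind, cand)
  best <- all[which.max(all[, "score"]), ]
  aln <- scoreOf(best[["b1"]], best[["b2"]])
  out <- cut3(best[["b1"]], best[["b2"]])
  out$boundaries <- as.integer(c(best[["b1"]], best[["b2"]]))
  out$identity <- alignmentIdentity(aln)
  out
}

pairConsensus <- function(rowA, rowB) {
  a <- strsplit(rowA, "")[[1]]; b <- strsplit(rowB, "")[[1]]
  # two-row majority: agreement wins; a residue beats a gap; on a
  # disagreement the domain-1 residue is kept (deterministic)
  ifelse(a == "-", b, a)
}

#' Stack the three regions into a self-alignment
#'
#' Progressive construction mirroring the three-story alignment: the two
#' catalytic domains (highest-homology pair) are aligned first, then the
#' N-region is aligned against the column-majority consensus of that pair.
#' Columns where the N-region carries residues absent from the consensus
#' become all-gap columns in the domain rows.
#'
#' @param regions list with elements `n_region`, `domain1`, `domain2`
#'   (strings or [SeqRecord-class]), e.g. from [partitionRepeats()].
#' @param scheme a [ScoringScheme-class].
#' @param sourceId template id recorded on the alignment.
#' @return a [RepeatAlignment-class] (row order: N-region, domain 1,
#'   domain 2).
#' @export
stackRegions <- function(regions, scheme = defaultScheme(),
                         sourceId = "template") {
  get <- function(x) if (is(x, "SeqRecord")) seqStr(x) else toupper(x)
  n <- get(regions$n_region); d1 <- get(regions$domain1)
  d2 <- get(regions$domain2)
  if (!nzchar(n) || !nzchar(d1) || !nzchar(d2))
    stop("all three regions must be non-empty")
  pair <- globalAlign(d1, d2, scheme)
  cons <- pairConsensus(pair@rowA, pair@rowB)
  nAln <- globalAlign(n, paste(cons, collapse = ""), scheme)
  rn <- strsplit(nAln@rowA, "")[[1]]
  rc <- strsplit(nAln@rowB, "")[[1]]
  r2 <- strsplit(pair@rowA, "")[[1]]
  r3 <- strsplit(pair@rowB, "")[[1]]
  out2 <- character(length(rn)); out3 <- character(length(rn))
  k <- 0L
  for (i in seq_along(rn)) {
    if (rc[i] == "-") {
      out2[i] <- "-"; out3[i] <- "-"
    } else {
      k <- k + 1L
      out2[i] <- r2[k]; out3[i] <- r3[k]
    }
  }
  new("RepeatAlignment",
      rows = c(paste(rn, collapse = ""), paste(out2, collapse = ""),
               paste(out3, collapse = "")),
      sourceId = sourceId)
}

#' Full self-alignment pipeline for one record
#'
#' Convenience wrapper: partition into three regions, then stack.
#'
#' @inheritParams partitionRepeats
#' @return list with `regions` (from [partitionRepeats()]) and `alignment`
#'   (a [RepeatAlignment-class]).
#' @export
selfAlign <- function(record, scheme = defaultScheme(), boundaries = NULL) {
  regions <- partitionRepeats(record, scheme, boundaries)
  list(regions = regions,
       alignment = stackRegions(regions, scheme, recordId(record)))
}

#' Detect vacant (all-gap) spans in one alignment row
#'
#' A vacant region is a maximal run of at least `min_len` columns where
#' the target row is all-gap while at least one other row carries
#' residues; these are the spans the compensation blocks fill.
#'
#' @param aln a [RepeatAlignment-class].
#' @param target_row row index (1 = N-region).
#' @param min_len minimum run length in columns.
#' @return list of [VacantRegion-class], ordered by column.
#' @export
detectVacantRegions <- function(aln, target_row = 1L, min_len = 5L) {
  if (!target_row %in% 1:3) stop("target_row out of range")
  rows <- lapply(aln@rows, function(r) strsplit(r, "")[[1]])
  tgt <- rows[[target_row]]
  others <- setdiff(1:3, target_row)
  isGap <- tgt == "-"
  runs <- rle(isGap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < min_len) next
    span <- starts[i]:ends[i]
    donors <- vapply(rows, function(r)
      paste(r[span][r[span] != "-"], collapse = ""), character(1))
    names(donors) <- paste0("row", 1:3)
    donors[target_row] <- ""
    if (!any(nzchar(donors[others]))) next
    anchor <- sum(tgt[seq_len(starts[i] - 1L)] != "-")
    out[[length(out) + 1L]] <- new("VacantRegion",
      targetRow = as.integer(target_row), colStart = starts[i],
      colEnd = ends[i], anchorResidue = as.integer(anchor),
      donors = donors)
  }
  out
}

#' Consensus score of one row against the column majority
#'
#' Fraction of alignment columns where the target row carries the
#' column-majority residue (gaps excluded from the majority count; a
#' column whose target cell is a gap never matches). Ties for the
#' majority count as a match when the target residue is among the
#' most frequent residues.
#'
#' @param aln a [RepeatAlignment-class].
#' @param target_row row evaluated against the majority (default 1,
#'   the N-region).
#' @return fraction in \[0, 1\].
#' @export
consensusScore <- function(aln, target_row = 1L) {
  rows <- lapply(aln@rows, function(r) strsplit(r, "")[[1]])
  W <- length(rows[[1]])
  hits <- 0L
  for (j in seq_len(W)) {
    col <- vapply(rows, `[`, character(1), j)
    res <- col[col != "-"]
    if (!length(res)) next
    tab <- table(res)
    winners <- names(tab)[tab == max(tab)]
    if (col[target_row] != "-" && col[target_row] %in% winners)
      hits <- hits + 1L
  }
  hits / W
}

#' Render a RepeatAlignment as a fixed-width text block
#'
#' Three-story rows with a column ruler, wrapped at `width` columns.
#'
#' @param aln a [RepeatAlignment-class].
#' @param width columns per block.
#' @return character vector of text lines.
#' @export
renderAlignment <- function(aln, width = 60L) {
  W <- alnWidth(aln)
  lab <- c("N-region", "domain1 ", "domain2 ")
  lines <- character()
  for (start in seq(1L, W, by = width)) {
    end <- min(start + width - 1L, W)
    lines <- c(lines, sprintf("%-9s", sprintf("[%d]", start)))
    for (i in 1:3)
      lines <- c(lines, sprintf("%-9s %s", lab[i],
                                substr(aln@rows[i], start, end)))
    lines <- c(lines, "")
  }
  lines
}

#' Vacancy report as a data.frame
#'
#' @param vacancies list of [VacantRegion-class].
#' @return data.frame (target_row, col_start, col_end, anchor_residue and
#'   one donor column per row).
#' @export
vacancyReport <- function(vacancies) {
  do.call(rbind, lapply(vacancies, function(v)
    data.frame(target_row = v@targetRow, col_start = v@colStart,
               col_end = v@colEnd, anchor_residue = v@anchorResidue,
               donor_row1 = v@donors[["row1"]],
               donor_row2 = v@donors[["row2"]],
               donor_row3 = v@donors[["row3"]],
               stringsAsFactors = FALSE)))
}
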