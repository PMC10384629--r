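FLEXIBLE_RESIDUES <- c("G", "I", "A", "V")

#' Split a peptide block at flexible residues
#'
#' Compensation blocks are divided into sub-blocks near flexible residues
#' (glycine, isoleucine, alanine, valine by default). Candidate cut points
#' are the positions of flexible residues (a cut at position p splits
#' between residues p and p+1). Explicit cuts must be candidates;
#' otherwise cuts are chosen greedily from the left so fragment lengths
#' approach `target_fragment_len`.
#'
#' @param block peptide string.
#' @param flexible_set residues after which cuts are allowed.
#' @param target_fragment_len greedy target length (default 7).
#' @param explicit_cuts integer positions of the cuts, each immediately
#'   after a flexible residue.
#' @return character vector of fragments; concatenation restores `block`.
#' @examples
#' splitAtFlexible("GRCHSYEGDKDTGQGGIGEPI", explicit_cuts = c(8, 15))
#' @export
splitAtFlexible <- function(block, flexible_set = FLEXIBLE_RESIDUES,
                            target_fragment_len = 7L,
                            explicit_cuts = NULL) {
  block <- toupper(block)
  if (!nzchar(block)) stop("empty block")
  n <- nchar(block)
  chars <- strsplit(block, "")[[1]]
  candidates <- which(chars %in% flexible_set)
  if (!is.null(explicit_cuts)) {
    explicit_cuts <- sort(unique(as.integer(explicit_cuts)))
    bad <- setdiff(explicit_cuts, candidates)
    if (length(bad))
      stop("cut position ", bad[1], " is not after a flexible residue")
    cuts <- explicit_cuts[explicit_cuts < n]
  } else {
    cuts <- integer()
    last <- 0L
    repeat {
      avail <- candidates[candidates > last & candidates < n]
      if (!length(avail) || n - last <= target_fragment_len) break
      pick <- avail[which.min(abs((avail - last) - target_fragment_len))]
      cuts <- c(cuts, pick)
      last <- pick
    }
  }
  bounds <- c(0L, cuts, n)
  vapply(seq_len(length(bounds) - 1L), function(i)
    substr(block, bounds[i] + 1L, bounds[i + 1L]), character(1))
}

#' Candidate cut positions of a block
#'
#' @inheritParams splitAtFlexible
#' @return integer positions of flexible residues in the block.
#' @export
flexibleCutCandidates <- function(block,
                                  flexible_set = FLEXIBLE_RESIDUES) {
  which(strsplit(toupper(block), "")[[1]] %in% flexible_set)
}

#' Derive nested compensation blocks from a vacancy donor
#'
#' The donor string of a vacant region is split at flexible residues and
#' returned as nested cumulative blocks (fragment 1, fragments 1-2, ...),
#' all anchored immediately after the vacancy's anchor residue. This is
#' how an 8/15/21-residue (or 7/14/22-residue) sibling series arises from
#' a single donor.
#'
#' @param vacancy a [VacantRegion-class].
#' @param donor_row which alignment row supplies the donor (2 or 3).
#' @param cuts optional explicit cut positions (see [splitAtFlexible()]).
#' @param ... passed on to [splitAtFlexible()].
#' @return list of [PeptideBlock-class], shortest first.
#' @export
deriveBlocks <- function(vacancy, donor_row = 2L, cuts = NULL, ...) {
  donor <- vacancy@donors[[paste0("row", donor_row)]]
  if (is.null(donor) || !nzchar(donor)) stop("donor row is empty")
  frags <- splitAtFlexible(donor, explicit_cuts = cuts, ...)
  anchor <- vacancy@anchorResidue + 1L
  lapply(seq_along(frags), function(k)
    new("PeptideBlock",
        seq = paste(frags[seq_len(k)], collapse = ""),
        anchor = as.integer(anchor),
        source = paste0("donor_row_", donor_row)))
}

#' Build a user-supplied peptide block
#'
#' @param seq peptide string.
#' @param anchor 1-based residue position the block's first residue
#'   occupies after insertion.
#' @return a [PeptideBlock-class].
#' @export
peptideBlock <- function(seq, anchor)
  new("PeptideBlock", seq = toupper(seq), anchor = as.integer(anchor),
      source = "user")

#' Edit operations
#'
#' An insertion at anchor `a` places its payload between template residues
#' `a - 1` and `a`, so the payload occupies positions `a ...
#' a + length - 1` of the new sequence (the superscript-coordinate
#' convention). A substitution replaces the span `at_start..at_end`.
#'
#' @param anchor,payload insertion anchor and peptide.
#' @return an edit operation (list with `kind`, coordinates, `payload`).
#' @export
editInsertion <- function(anchor, payload)
  list(kind = "insertion", at_start = as.integer(anchor),
       at_end = as.integer(anchor), payload = toupper(payload))

#' @rdname editInsertion
#' @param at_start,at_end 1-based inclusive template span being replaced.
#' @param allow_length_change allow a payload whose length differs from
#'   the span (off by default).
#' @export
editSubstitution <- function(at_start, at_end, payload,
                             allow_length_change = FALSE) {
  payload <- toupper(payload)
  if (!allow_length_change &&
      nchar(payload) != at_end - at_start + 1L)
    stop("substitution payload length differs from span; ",
         "set allow_length_change = TRUE if intended")
  list(kind = "substitution", at_start = as.integer(at_start),
       at_end = as.integer(at_end), payload = payload)
}

# apply one edit to a plain sequence string; substitutions record the
# original span so variants can be reverted exactly
applyEdit <- function(s, edit) {
  n <- nchar(s)
  if (edit$kind == "insertion") {
    a <- edit$at_start
    if (a < 2L || a > n + 1L) stop("insertion anchor outside template")
    paste0(substr(s, 1L, a - 1L), edit$payload, substr(s, a, n))
  } else {
    if (edit$at_start < 1L || edit$at_end > n) stop("span outside template")
    paste0(substr(s, 1L, edit$at_start - 1L), edit$payload,
           substr(s, edit$at_end + 1L, n))
  }
}

makeVariant <- function(name, template_seq, edits, tag) {
  s <- template_seq
  span <- integer(0)
  for (k in seq_along(edits)) {
    e <- edits[[k]]
    if (e$kind == "substitution") {
      e$original <- substr(s, e$at_start, e$at_end)
      edits[[k]] <- e
    }
    s <- applyEdit(s, e)
    if (e$kind == "insertion")
      span <- c(e$at_start, e$at_start + nchar(e$payload) - 1L)
  }
  if (nzchar(tag)) {
    tagged <- appendRetentionTag(SeqRecord(name, s), tag)
    s <- seqStr(tagged)
  }
  new("DesignedVariant", name = name, seq = s, edits = edits,
      insertedSpan = span)
}

#' Generate a sibling variant series from blocks and substitutions
#'
#' Produces, in order: one insertion variant per block, one variant per
#' bare substitution, and -- when both blocks and substitutions are
#' supplied -- one variant per block applied on each substituted template.
#' Every variant is C-terminally tagged with the retention signal.
#'
#' @param template protein [SeqRecord-class] (untagged).
#' @param blocks list of [PeptideBlock-class].
#' @param substitutions list of substitution edits
#'   (see [editSubstitution()]).
#' @param naming character vector of variant names in generation order;
#'   `NULL` auto-names `var01, var02, ...`.
#' @param tag retention tag appended to every variant (default KDEL).
#' @return a [VariantSeries-class].
#' @export
generateVariantSeries <- function(template, blocks = list(),
                                  substitutions = list(), naming = NULL,
                                  tag = "KDEL") {
  tseq <- seqStr(template)
  editSets <- list()
  for (b in blocks)
    editSets[[length(editSets) + 1L]] <-
      list(editInsertion(b@anchor, b@seq))
  for (sub in substitutions)
    editSets[[length(editSets) + 1L]] <- list(sub)
  for (sub in substitutions) for (b in blocks)
    editSets[[length(editSets) + 1L]] <-
      list(sub, editInsertion(b@anchor, b@seq))
  if (!length(editSets)) editSets <- list(list())
  if (is.null(naming))
    naming <- sprintf("var%02d", seq_along(editSets))
  if (length(naming) != length(editSets))
    stop("naming covers ", length(naming), " variants but ",
         length(editSets), " are generated")
  if (anyDuplicated(naming)) stop("duplicate variant names")
  vars <- lapply(seq_along(editSets), function(i)
    makeVariant(naming[i], tseq, editSets[[i]], tag))
  new("VariantSeries", templateId = recordId(template), variants = vars)
}

#' Revert a designed variant to its template string
#'
#' Removes the retention tag, deletes the inserted span and restores
#' substituted residues, in reverse edit order.
#'
#' @param variant a [DesignedVariant-class].
#' @param tag the retention tag that was appended.
#' @return the reconstructed template string.
#' @export
revertVariant <- function(variant, tag = "KDEL") {
  s <- variant@seq
  if (nzchar(tag) && endsWith(s, tag))
    s <- substr(s, 1L, nchar(s) - nchar(tag))
  for (e in rev(variant@edits)) {
    if (e$kind == "insertion") {
      a <- e$at_start
      s <- paste0(substr(s, 1L, a - 1L),
                  substr(s, a + nchar(e$payload), nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, e$at_start - 1L), e$original,
                  substr(s, e$at_start + nchar(e$payload), nchar(s)))
    }
  }
  s
}

#' Combine variant series derived from one template
#'
#' @param ... [VariantSeries-class] objects sharing a template.
#' @return the concatenated [VariantSeries-class].
#' @export
combineSeries <- function(...) {
  parts <- list(...)
  new("VariantSeries", templateId = parts[[1]]@templateId,
      variants = do.call(c, lapply(parts, variants)))
}

#' Build the canonical ten-variant sibling series
#'
#' Runs the full compensation scheme on a template with a vacancy at the
#' given anchor: three nested insertions from the first donor block set,
#' three nested insertions from the second donor set, one four-residue
#' substitution, and the first donor set re-applied on the substituted
#' template -- ten variants in total, every one KDEL-tagged.
#'
#' @param template protein [SeqRecord-class].
#' @param donor1_blocks,donor2_blocks lists of [PeptideBlock-class]
#'   (nested, e.g. from [deriveBlocks()]).
#' @param substitution a substitution edit (see [editSubstitution()]).
#' @param naming names for the 3 + 3 + 1 + 3 variants, in that order.
#' @param tag retention tag.
#' @return a [VariantSeries-class] of length 10.
#' @export
buildSiblingVariants <- function(template, donor1_blocks, donor2_blocks,
                                 substitution,
                                 naming = c("ALuc55", "ALuc56", "ALuc57",
                                            "ALuc60", "ALuc61", "ALuc62",
                                            "ALuc65", "ALuc66", "ALuc67",
                                            "ALuc68"),
                                 tag = "KDEL") {
  stopifnot(length(naming) == length(donor1_blocks) +
              length(donor2_blocks) + 1L + length(donor1_blocks))
  n1 <- length(donor1_blocks); n2 <- length(donor2_blocks)
  s1 <- generateVariantSeries(template, donor1_blocks,
                              naming = naming[seq_len(n1)], tag = tag)
  s2 <- generateVariantSeries(template, donor2_blocks,
                              naming = naming[n1 + seq_len(n2)], tag = tag)
  # a blocks+substitution call emits [plain insertions, bare substitution,
  # cross products]; the plain insertions duplicate s1 and are dropped
  nm3 <- c(sprintf(".dup%02d", seq_len(n1)), naming[n1 + n2 + 1L],
           naming[n1 + n2 + 1L + seq_len(n1)])
  s3 <- generateVariantSeries(template, donor1_blocks, list(substitution),
                              naming = nm3, tag = tag)
  s3 <- new("VariantSeries", templateId = recordId(template),
            variants = variants(s3)[-seq_len(n1)])
  combineSeries(s1, s2, s3)
}

#' Export a variant series as FASTA plus a JSON manifest
#'
#' @param series a [VariantSeries-class].
#' @param fasta_path,manifest_path output file paths (`NULL` skips).
#' @return list with the FASTA text and the manifest list, invisibly.
#' @export
exportSeries <- function(series, fasta_path = NULL, manifest_path = NULL) {
  recs <- lapply(variants(series), function(v) SeqRecord(v@name, v@seq))
  fasta <- writeFasta(recs, fasta_path)
  manifest <- lapply(variants(series), function(v)
    list(name = v@name, length = nchar(v@seq),
         inserted_span = v@insertedSpan,
         edits = lapply(v@edits, function(e)
           e[c("kind", "at_start", "at_end", "payload")])))
  if (!is.null(manifest_path))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(list(fasta = fasta, manifest = manifest))
}
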