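#' Construct a SeqRecord
#'
#' Sequences are uppercased on ingest and validated against the strict
#' alphabet; ambiguity codes (B, Z, X, U, O) are rejected because the
#' design pipeline edits exact residues and property math is undefined for
#' ambiguous positions.
#'
#' @param id short unique identifier, no whitespace.
#' @param seq residue string.
#' @param alphabet `"protein"` (default) or `"dna"`.
#' @param annotations data.frame with columns `label`, `start`, `end`
#'   (1-based inclusive), or `NULL`.
#' @return a [SeqRecord-class] object.
#' @examples
#' rec <- SeqRecord("luc1", "magtkdel")
#' seqStr(rec)
#' @export
SeqRecord <- function(id, seq, alphabet = c("protein", "dna"),
                      annotations = NULL) {
  alphabet <- match.arg(alphabet)
  seq <- toupper(gsub("\\s", "", seq))
  if (is.null(annotations))
    annotations <- data.frame(label = character(), start = integer(),
                              end = integer())
  annotations$start <- as.integer(annotations$start)
  annotations$end <- as.integer(annotations$end)
  new("SeqRecord", id = as.character(id), seq = seq, alphabet = alphabet,
      annotations = annotations)
}

#' @describeIn SeqRecord record identifier.
#' @param x a SeqRecord.
#' @export
recordId <- function(x) x@id

#' @describeIn SeqRecord residue string.
#' @export
seqStr <- function(x) x@seq

#' @describeIn SeqRecord sequence length in residues.
#' @export
seqLength <- function(x) nchar(x@seq)

#' @describeIn SeqRecord annotation table (label, start, end).
#' @export
annotations <- function(x) x@annotations

#' Region annotation lookup
#'
#' @param x a [SeqRecord-class].
#' @param label region label (e.g. `"SP"`).
#' @return one-row data.frame, or NULL if the label is absent.
#' @export
getRegion <- function(x, label) {
  ann <- x@annotations
  hit <- ann[ann$label == label, , drop = FALSE]
  if (nrow(hit)) hit[1, , drop = FALSE] else NULL
}

setMethod("show", "SeqRecord", function(object) {
  cat(sprintf("SeqRecord '%s' (%s, %d residues)\n", object@id,
              object@alphabet, nchar(object@seq)))
  s <- object@seq
  cat(" ", if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s, "\n")
  if (nrow(object@annotations)) {
    a <- object@annotations
    cat("  regions:", paste(sprintf("%s[%d-%d]", a$label, a$start, a$end),
                            collapse = " "), "\n")
  }
})

#' @describeIn RepeatAlignment the three gapped rows.
#' @param x a RepeatAlignment.
#' @export
alnRows <- function(x) x@rows

#' @describeIn RepeatAlignment number of alignment columns.
#' @export
alnWidth <- function(x) nchar(x@rows[1])

setMethod("show", "RepeatAlignment", function(object) {
  cat(sprintf("RepeatAlignment of '%s' (%d columns)\n", object@sourceId,
              nchar(object@rows[1])))
  lab <- c("N-region", "domain 1", "domain 2")
  for (i in 1:3) {
    r <- object@rows[i]
    cat(sprintf("  %-8s %s\n", lab[i],
                if (nchar(r) > 60) paste0(substr(r, 1, 57), "...") else r))
  }
})

setMethod("show", "VacantRegion", function(object) {
  cat(sprintf(
    "VacantRegion: row %d, columns %d-%d (anchor residue %d)\n",
    object@targetRow, object@colStart, object@colEnd, object@anchorResidue))
  for (nm in names(object@donors))
    if (nzchar(object@donors[[nm]]))
      cat(sprintf("  donor %s: %s\n", nm, object@donors[[nm]]))
})

#' @describeIn VariantSeries names of the variants, in series order.
#' @param x a VariantSeries.
#' @export
variantNames <- function(x)
  vapply(x@variants, function(v) v@name, character(1))

#' @describeIn VariantSeries list of [DesignedVariant-class] objects.
#' @export
variants <- function(x) x@variants

#' Retrieve one variant by name
#' @param x a [VariantSeries-class].
#' @param name variant name.
#' @return a [DesignedVariant-class].
#' @export
getVariant <- function(x, name) {
  i <- match(name, variantNames(x))
  if (is.na(i)) stop("no variant named '", name, "'")
  x@variants[[i]]
}

#' Variant series as a summary table
#'
#' @param x a [VariantSeries-class].
#' @return data.frame with name, length, edit kind and inserted span.
#' @export
variantTable <- function(x) {
  do.call(rbind, lapply(x@variants, function(v) {
    span <- if (length(v@insertedSpan)) sprintf("%d-%d", v@insertedSpan[1],
                                                v@insertedSpan[2]) else NA
    data.frame(name = v@name, length = nchar(v@seq),
               n_edits = length(v@edits), inserted_span = span,
               stringsAsFactors = FALSE)
  }))
}

setMethod("show", "VariantSeries", function(object) {
  cat(sprintf("VariantSeries from '%s': %d variants\n", object@templateId,
              length(object@variants)))
  print(variantTable(object), row.names = FALSE)
})

setMethod("show", "EmissionSpectrum", function(object) {
  cat(sprintf("EmissionSpectrum '%s': %d points, %.0f-%.0f nm\n",
              object@label, length(object@wavelengths),
              min(object@wavelengths), max(object@wavelengths)))
})

#' @describeIn NucleotideConstruct nucleotide string.
#' @param x a NucleotideConstruct.
#' @export
constructDna <- function(x) x@dna

#' @describeIn NucleotideConstruct feature table.
#' @export
constructFeatures <- function(x) x@features

setMethod("show", "NucleotideConstruct", function(object) {
  cat(sprintf("NucleotideConstruct '%s': %d nt, ORF %d-%d\n", object@id,
              nchar(object@dna), object@orfStart, object@orfEnd))
  if (nrow(object@features))
    cat("  features:",
        paste(sprintf("%s[%d-%d]", object@features$label,
                      object@features$start, object@features$end),
              collapse = " "), "\n")
})

setMethod("show", "ProbeLayout", function(object) {
  cat(sprintf("ProbeLayout (%s): %s\n", object@kind,
              paste(names(object@parts), collapse = " - ")))
})
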