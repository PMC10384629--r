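#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib aluckit, .registration = TRUE
NULL

AA_ALPHABET_STRICT <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")
REGION_LABELS <- c("SP", "N_REGION", "DOMAIN1", "DOMAIN2", "TAG", "other")

#' SeqRecord: an identified sequence with region annotations
#'
#' A single amino-acid or nucleotide sequence with a short unique identifier
#' and optional region annotations (signal peptide, N-region, catalytic
#' domains, tags). Residue coordinates are 1-based and inclusive throughout
#' the package.
#'
#' @slot id single string, no whitespace.
#' @slot seq residue string, uppercase, strict alphabet (no ambiguity codes).
#' @slot alphabet `"protein"` or `"dna"`.
#' @slot annotations data.frame with columns `label`, `start`, `end`;
#'   regions are non-overlapping and lie inside the sequence.
#'
#' @exportClass SeqRecord
setClass("SeqRecord",
  representation(id = "character", seq = "character",
                 alphabet = "character", annotations = "data.frame"))

setValidity("SeqRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id) ||
      grepl("\\s", object@id))
    msg <- c(msg, "'id' must be one non-empty string without whitespace")
  if (length(object@seq) != 1L || !nzchar(object@seq))
    msg <- c(msg, "'seq' must be one non-empty string")
  if (!object@alphabet %in% c("protein", "dna"))
    msg <- c(msg, "'alphabet' must be 'protein' or 'dna'")
  else {
    allowed <- if (object@alphabet == "protein") AA_ALPHABET_STRICT else
      DNA_ALPHABET
    chars <- strsplit(object@seq, "")[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad))
      msg <- c(msg, sprintf(
        "invalid %s character '%s' at position %d in record '%s'",
        object@alphabet, chars[bad[1]], bad[1], object@id))
  }
  ann <- object@annotations
  if (nrow(ann)) {
    if (!all(c("label", "start", "end") %in% names(ann)))
      msg <- c(msg, "annotations need columns label, start, end")
    else {
      if (any(ann$start < 1 | ann$end > nchar(object@seq) |
              ann$start > ann$end))
        msg <- c(msg, "annotation out of sequence range")
      if (nrow(ann) > 1L) {
        o <- order(ann$start)
        if (any(ann$start[o][-1] <= ann$end[o][-nrow(ann)]))
          msg <- c(msg, "annotations overlap")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScoringScheme: substitution matrix plus affine gap penalties
#'
#' @slot matrix symmetric substitution matrix with residue dimnames.
#' @slot gapOpen non-negative gap opening penalty.
#' @slot gapExtend non-negative per-column gap extension penalty;
#'   a gap run of length L costs `gapOpen + L * gapExtend`.
#'
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "numeric",
                 gapExtend = "numeric"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("matrix must have identical row and column residue names")
  if (!isTRUE(all.equal(m, t(m)))) return("matrix must be symmetric")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap penalties must be non-negative")
  if (object@gapOpen < object@gapExtend)
    return("gapOpen must be >= gapExtend")
  TRUE
})

#' PairwiseAln: a global pairwise alignment
#'
#' @slot rowA,rowB gapped strings of equal length; no column is gap/gap.
#' @slot score alignment score in scheme units.
#'
#' @exportClass PairwiseAln
setClass("PairwiseAln",
  representation(rowA = "character", rowB = "character", score = "numeric"))

setValidity("PairwiseAln", function(object) {
  if (nchar(object@rowA) != nchar(object@rowB))
    return("rows must have equal length")
  a <- strsplit(object@rowA, "")[[1]]; b <- strsplit(object@rowB, "")[[1]]
  if (length(a) && any(a == "-" & b == "-")) return("gap/gap column")
  TRUE
})

#' RepeatAlignment: three-row self-alignment of one protein
#'
#' The three regions of a copepod-luciferase-like protein (flexible
#' N-region, catalytic domain 1, catalytic domain 2) stacked as a
#' three-story alignment so internal homology and vacant spans are visible.
#'
#' @slot rows character(3): gapped rows of equal column count, in the order
#'   N-region, domain 1, domain 2.
#' @slot sourceId id of the template record.
#'
#' @exportClass RepeatAlignment
setClass("RepeatAlignment",
  representation(rows = "character", sourceId = "character"))

setValidity("RepeatAlignment", function(object) {
  if (length(object@rows) != 3L) return("exactly 3 rows required")
  if (length(unique(nchar(object@rows))) != 1L)
    return("rows must have equal column counts")
  TRUE
})

#' VacantRegion: an all-gap span in one row of a RepeatAlignment
#'
#' @slot targetRow row index (1-3) carrying the gap run.
#' @slot colStart,colEnd 1-based inclusive alignment columns.
#' @slot anchorResidue 1-based residue position in the ungapped target
#'   region immediately before the vacancy (0 if the run starts the row).
#' @slot donors named character: per-row ungapped residue strings spanning
#'   the vacant columns.
#'
#' @exportClass VacantRegion
setClass("VacantRegion",
  representation(targetRow = "integer", colStart = "integer",
                 colEnd = "integer", anchorResidue = "integer",
                 donors = "character"))

setValidity("VacantRegion", function(object) {
  if (object@colStart > object@colEnd) return("colStart > colEnd")
  if (!any(nzchar(object@donors))) return("at least one donor must be non-empty")
  TRUE
})

#' PeptideBlock: a compensation block with its insertion anchor
#'
#' @slot seq peptide string.
#' @slot anchor 1-based residue position the block's first residue occupies
#'   after insertion (insertion goes between template residues
#'   `anchor - 1` and `anchor`).
#' @slot source `"donor_row_2"`, `"donor_row_3"` or `"user"`.
#'
#' @exportClass PeptideBlock
setClass("PeptideBlock",
  representation(seq = "character", anchor = "integer", source = "character"))

setValidity("PeptideBlock", function(object) {
  if (!nzchar(object@seq)) return("block sequence must be non-empty")
  if (object@anchor < 2L) return("anchor must be >= 2")
  if (!object@source %in% c("donor_row_2", "donor_row_3", "user"))
    return("unknown block source")
  TRUE
})

#' DesignedVariant: one edited sequence with its edit provenance
#'
#' @slot name variant name (e.g. ALuc60-style series names).
#' @slot seq the edited peptide (retention tag included).
#' @slot edits list of edit descriptions (kind, coordinates, payload).
#' @slot insertedSpan integer(2) span of the inserted block in new-sequence
#'   coordinates, or integer(0) when the variant carries no insertion.
#'
#' @exportClass DesignedVariant
setClass("DesignedVariant",
  representation(name = "character", seq = "character", edits = "list",
                 insertedSpan = "integer"))

#' VariantSeries: an ordered, named family of designed variants
#'
#' @slot templateId id of the template record the series derives from.
#' @slot variants list of [DesignedVariant-class] objects, unique names.
#'
#' @exportClass VariantSeries
setClass("VariantSeries",
  representation(templateId = "character", variants = "list"))

setValidity("VariantSeries", function(object) {
  nm <- vapply(object@variants, function(v) v@name, character(1))
  if (anyDuplicated(nm)) return("variant names must be unique")
  TRUE
})

#' ProbeLayout: protein-level assembly plan for a fusion construct
#'
#' @slot kind `"expression"`, `"strain_probe"` or `"pca_probe"`.
#' @slot parts named list of [SeqRecord-class] parts in fusion order
#'   (names are the roles, e.g. FRB / reporter / FKBP).
#' @slot junctionSites character: restriction enzymes at the flanks and
#'   between parts, in order.
#'
#' @exportClass ProbeLayout
setClass("ProbeLayout",
  representation(kind = "character", parts = "list",
                 junctionSites = "character"))

#' NucleotideConstruct: a cDNA-level assembly with feature table
#'
#' @slot id construct identifier.
#' @slot dna nucleotide string over ACGT.
#' @slot orfStart,orfEnd 1-based ORF bounds (ATG..stop inclusive).
#' @slot features data.frame with columns `label`, `start`, `end`.
#'
#' @exportClass NucleotideConstruct
setClass("NucleotideConstruct",
  representation(id = "character", dna = "character", orfStart = "integer",
                 orfEnd = "integer", features = "data.frame"))

setValidity("NucleotideConstruct", function(object) {
  if ((object@orfEnd - object@orfStart + 1L) %% 3L != 0L)
    return("ORF length must be divisible by 3")
  TRUE
})

#' EmissionSpectrum: a wavelength/intensity series
#'
#' @slot wavelengths strictly increasing grid in nm (>= 3 points).
#' @slot intensities non-negative intensities (arbitrary units), max > 0.
#' @slot label luciferase x substrate identifier.
#'
#' @exportClass EmissionSpectrum
setClass("EmissionSpectrum",
  representation(wavelengths = "numeric", intensities = "numeric",
                 label = "character"))

setValidity("EmissionSpectrum", function(object) {
  w <- object@wavelengths; y <- object@intensities
  if (length(w) < 3L) return("need at least 3 points")
  if (length(w) != length(y)) return("wavelengths/intensities length mismatch")
  if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
  if (any(y < 0)) return("intensities must be non-negative")
  if (max(y) <= 0) return("spectrum must not be all zero")
  TRUE
})

#' StructureModel: parsed ATOM coordinates of one model
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` (standard residues, heavy atoms).
#'
#' @exportClass StructureModel
setClass("StructureModel", representation(atoms = "data.frame"))
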