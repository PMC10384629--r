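# Average (not monoisotopic) residue masses in Da; MW = sum + one water.
# Average masses match the kD convention used when reporting luciferase
# sizes.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Read protein or DNA sequences from FASTA
#'
#' Accepts either a file path or FASTA text. Sequences are uppercased,
#' internal whitespace removed, and validated against the strict alphabet;
#' records violating it are reported with the offending character and
#' position.
#'
#' @param path_or_text FASTA file path, or a string containing FASTA text
#'   (recognised by a leading `>`).
#' @param alphabet `"protein"` (default) or `"dna"`.
#' @return list of [SeqRecord-class] in file order.
#' @examples
#' readFasta(">a\nGRCH\n>b\nKDEL\n")
#' @export
readFasta <- function(path_or_text, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  path <- path_or_text
  if (grepl("^\\s*>", path_or_text)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(path_or_text, path)
  } else if (!file.exists(path)) {
    stop("input is neither FASTA text (no leading '>') nor an existing file")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA input")
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup),
                                                       collapse = ", "))
  lapply(seq_along(set), function(i)
    SeqRecord(ids[i], as.character(set[[i]]), alphabet))
}

#' Write SeqRecords as wrapped FASTA text
#'
#' @param records list of [SeqRecord-class].
#' @param path optional file path; when `NULL` the FASTA text is returned.
#' @param width line width for sequence wrapping.
#' @return FASTA text (invisibly when written to a file).
#' @export
writeFasta <- function(records, path = NULL, width = 60L) {
  if (length(records) == 0L) stop("no records to write")
  stopifnot(width >= 1L)
  txt <- vapply(records, function(r) {
    s <- seqStr(r)
    starts <- seq(1L, nchar(s), by = width)
    paste0(">", recordId(r), "\n",
           paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 collapse = "\n"), "\n")
  }, character(1))
  out <- paste(txt, collapse = "")
  if (!is.null(path)) {
    cat(out, file = path)
    invisible(out)
  } else out
}

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water (18.0153 Da), so the
#' peptide-bond condensation is accounted for and MW is additive:
#' `mw(s1 || s2) = mw(s1) + mw(s2) - 18.0153`.
#'
#' @param seq protein string or [SeqRecord-class].
#' @return molecular weight in Daltons.
#' @examples
#' molecularWeight("G")  # 75.07
#' @export
molecularWeight <- function(seq) {
  s <- if (is(seq, "SeqRecord")) {
    if (seq@alphabet != "protein") stop("protein sequence required")
    seqStr(seq)
  } else toupper(seq)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "")[[1]]
  if (any(!chars %in% names(AA_AVG_MASS)))
    stop("non-standard residue: ",
         chars[which(!chars %in% names(AA_AVG_MASS))[1]])
  sum(AA_AVG_MASS[chars]) + WATER_MASS
}

#' Load the ionizable-group pKa table
#'
#' Bjellqvist-style pKa values shipped with the package
#' (`extdata/pka_bjellqvist.yaml`); a different YAML file with the same
#' keys may be supplied to change the table.
#'
#' @param path optional YAML path overriding the shipped table.
#' @return named list with `nterm`, `cterm` and `sidechain` pKa values.
#' @export
loadPkaTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pka_bjellqvist.yaml", package = "aluckit")
  yaml::read_yaml(path)
}

netCharge <- function(counts, pH, pka) {
  cnt <- function(aa) if (is.na(counts[aa])) 0L else counts[[aa]]
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  neg <- -1 / (1 + 10^(pka$cterm - pH))
  for (aa in c("K", "R", "H"))
    if (cnt(aa) > 0)
      pos <- pos + cnt(aa) / (1 + 10^(pH - pka$sidechain[[aa]]))
  for (aa in c("D", "E", "C", "Y"))
    if (cnt(aa) > 0)
      neg <- neg - cnt(aa) / (1 + 10^(pka$sidechain[[aa]] - pH))
  pos + neg
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the peptide
#' (N-terminus, C-terminus, and D/E/C/Y/H/K/R side chains) crosses zero,
#' solved by bisection on pH 0-14 to 1e-4 pH units.
#'
#' @param seq protein string or [SeqRecord-class].
#' @param pka pKa table from [loadPkaTable()].
#' @return isoelectric point in pH units.
#' @examples
#' isoelectricPoint("GGDDKK")
#' @export
isoelectricPoint <- function(seq, pka = loadPkaTable()) {
  s <- if (is(seq, "SeqRecord")) seqStr(seq) else toupper(seq)
  if (!nzchar(s)) stop("empty sequence")
  counts <- table(strsplit(s, "")[[1]])
  counts <- stats::setNames(as.integer(counts), names(counts))
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (netCharge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-record property report
#'
#' @param record a [SeqRecord-class] (protein).
#' @param pka pKa table; see [loadPkaTable()].
#' @return list with `id`, `length`, `mw` (Da), `pi` and `composition`.
#' @export
propertyReport <- function(record, pka = loadPkaTable()) {
  s <- seqStr(record)
  comp <- table(factor(strsplit(s, "")[[1]], levels = AA_ALPHABET_STRICT))
  list(id = recordId(record), length = nchar(s),
       mw = molecularWeight(record), pi = isoelectricPoint(record, pka),
       composition = stats::setNames(as.integer(comp), names(comp)))
}

#' Property table for many records
#'
#' @param records list of protein [SeqRecord-class].
#' @param pka pKa table.
#' @return data.frame with columns id, length, mw_Da, pI.
#' @export
propertyTable <- function(records, pka = loadPkaTable()) {
  do.call(rbind, lapply(records, function(r) {
    p <- propertyReport(r, pka)
    data.frame(id = p$id, length = p$length, mw_Da = p$mw, pI = p$pi,
               stringsAsFactors = FALSE)
  }))
}

#' Remove the N-terminal secretion peptide
#'
#' Secretion peptides must be removed from reporters embedded in
#' single-chain probes; the SP span is taken from the record's annotation
#' (starting at residue 1) or given explicitly. Remaining annotations are
#' shifted left accordingly.
#'
#' @param record a [SeqRecord-class].
#' @param sp_len explicit SP length overriding the annotation.
#' @return the mature [SeqRecord-class] without the SP.
#' @export
stripSignalPeptide <- function(record, sp_len = NULL) {
  if (is.null(sp_len)) {
    sp <- getRegion(record, "SP")
    if (is.null(sp)) stop("no SP annotation and no sp_len given")
    if (sp$start != 1L) stop("SP annotation must start at residue 1")
    sp_len <- sp$end
  }
  sp_len <- as.integer(sp_len)
  n <- seqLength(record)
  if (sp_len == 0L) return(record)
  if (sp_len >= n) stop("SP covers the entire sequence")
  ann <- annotations(record)
  ann <- ann[ann$label != "SP" & ann$start > sp_len, , drop = FALSE]
  ann$start <- ann$start - sp_len
  ann$end <- ann$end - sp_len
  SeqRecord(recordId(record), substr(seqStr(record), sp_len + 1L, n),
            record@alphabet, ann)
}

#' Append a C-terminal retention tag
#'
#' Appends an ER retention signal (default KDEL) and records a TAG
#' annotation. With `idempotent = TRUE` a sequence already ending in the
#' tag is returned unchanged.
#'
#' @param record a [SeqRecord-class].
#' @param tag peptide tag, default `"KDEL"`.
#' @param idempotent skip when the tag is already the suffix.
#' @return the tagged [SeqRecord-class].
#' @export
appendRetentionTag <- function(record, tag = "KDEL", idempotent = TRUE) {
  if (!nzchar(tag)) return(record)
  tag <- toupper(tag)
  s <- seqStr(record)
  if (idempotent && nchar(s) >= nchar(tag) &&
      substr(s, nchar(s) - nchar(tag) + 1L, nchar(s)) == tag)
    return(record)
  ann <- annotations(record)
  ann <- rbind(ann, data.frame(label = "TAG", start = nchar(s) + 1L,
                               end = nchar(s) + nchar(tag)))
  SeqRecord(recordId(record), paste0(s, tag), record@alphabet, ann)
}

#' Export a property table as TSV or JSON
#'
#' @param records list of protein [SeqRecord-class].
#' @param path output path (`.tsv`/`.json` decides the format).
#' @param format `"tsv"` or `"json"`; default inferred from `path`.
#' @return the table, invisibly.
#' @export
writePropertyTable <- function(records, path,
                               format = if (grepl("\\.json$", path))
                                 "json" else "tsv") {
  tab <- propertyTable(records)
  if (format == "json")
    jsonlite::write_json(tab, path, digits = NA)
  else
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
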