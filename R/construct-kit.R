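#' Load a codon usage table
#'
#' The shipped default is a murine codon-usage table
#' (`extdata/codon_usage_mouse.tsv`, columns `aa`, `codon`, `fraction`).
#' Per amino acid, codons are ranked by usage fraction; fractions must sum
#' to 1 within 0.01 and every standard amino acid (plus `*` for stops)
#' must be present.
#'
#' @param path optional TSV path overriding the shipped table.
#' @return data.frame with columns `aa`, `codon`, `fraction`, sorted by
#'   decreasing usage within each amino acid.
#' @export
loadCodonTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "codon_usage_mouse.tsv",
                        package = "aluckit")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric"))
  stopifnot(all(c("aa", "codon", "fraction") %in% names(tab)))
  if (any(nchar(tab$codon) != 3L) ||
      any(!strsplit(paste(tab$codon, collapse = ""), "")[[1]] %in%
            DNA_ALPHABET))
    stop("codons must be triplets over ACGT")
  missing <- setdiff(c(AA_ALPHABET_STRICT, "*"), tab$aa)
  if (length(missing))
    stop("codon table lacks amino acids: ", paste(missing, collapse = ", "))
  sums <- tapply(tab$fraction, tab$aa, sum)
  if (any(abs(sums - 1) > 0.01))
    stop("usage fractions do not sum to 1 for: ",
         paste(names(sums)[abs(sums - 1) > 0.01], collapse = ", "))
  tab[order(tab$aa, -tab$fraction, tab$codon), ]
}

#' Load the restriction enzyme registry
#'
#' @param path optional TSV (columns `name`, `recognition`) overriding the
#'   shipped registry.
#' @return data.frame of enzyme names and recognition sequences.
#' @export
loadEnzymes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "aluckit")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recognition sequence of a named enzyme
#'
#' @param name enzyme name (e.g. `"HindIII"`).
#' @param enzymes registry from [loadEnzymes()].
#' @return recognition sequence string.
#' @export
enzymeSite <- function(name, enzymes = loadEnzymes()) {
  i <- match(name, enzymes$name)
  if (is.na(i)) stop("unknown enzyme: ", name)
  enzymes$recognition[i]
}

#' Find restriction sites in a nucleotide string
#'
#' All occurrences, including overlapping ones, sorted by position.
#'
#' @param dna nucleotide string over ACGT.
#' @param sites character vector of enzyme names, or a data.frame with
#'   columns `name` and `recognition`.
#' @param enzymes registry used to resolve names.
#' @return data.frame with columns `name` and `position` (1-based).
#' @export
findRestrictionSites <- function(dna, sites = c("HindIII", "XhoI"),
                                 enzymes = loadEnzymes()) {
  dna <- toupper(dna)
  if (nzchar(dna) &&
      !all(strsplit(dna, "")[[1]] %in% DNA_ALPHABET))
    stop("dna contains characters outside ACGT")
  if (is.character(sites))
    sites <- data.frame(name = sites,
                        recognition = vapply(sites, enzymeSite,
                                             character(1),
                                             enzymes = enzymes))
  hits <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    m <- Biostrings::matchPattern(sites$recognition[i],
                                  Biostrings::DNAString(dna))
    if (length(m) == 0L) return(NULL)
    data.frame(name = sites$name[i], position = BiocGenerics::start(m))
  }))
  if (is.null(hits))
    return(data.frame(name = character(), position = integer()))
  hits[order(hits$position, hits$name), , drop = FALSE]
}

#' Translate a nucleotide ORF (standard genetic code)
#'
#' @param dna in-frame nucleotide string (length divisible by 3); a
#'   trailing stop codon is dropped from the peptide.
#' @return peptide string.
#' @export
translateOrf <- function(dna) {
  p <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                          no.init.codon = TRUE))
  sub("\\*$", "", p)
}

#' Reverse-translate a peptide with codon ranking and site avoidance
#'
#' Each residue gets its highest-usage codon. Wherever a forbidden
#' recognition sequence appears (possibly spanning codon boundaries), the
#' minimal number of codons is swapped to next-ranked synonymous
#' alternatives until the output is free of every forbidden site.
#' Translation of the output always recovers the input exactly.
#'
#' @param protein peptide string or [SeqRecord-class].
#' @param table codon table from [loadCodonTable()].
#' @param forbidden character vector of recognition sequences (not enzyme
#'   names) that must not occur in the output.
#' @return nucleotide string.
#' @examples
#' reverseTranslate("MKL")
#' @export
reverseTranslate <- function(protein, table = loadCodonTable(),
                             forbidden = character()) {
  p <- if (is(protein, "SeqRecord")) seqStr(protein) else toupper(protein)
  if (!nzchar(p)) stop("empty peptide")
  aas <- strsplit(p, "")[[1]]
  ranked <- split(table$codon, table$aa)
  miss <- setdiff(aas, names(ranked))
  if (length(miss)) stop("residue absent from codon table: ", miss[1])
  choice <- rep(1L, length(aas))  # rank index per position
  codonAt <- function(i) ranked[[aas[i]]][choice[i]]
  buildDna <- function()
    paste(vapply(seq_along(aas), codonAt, character(1)), collapse = "")
  dna <- buildDna()
  if (!length(forbidden)) return(dna)
  for (iter in seq_len(10L * length(aas) + 50L)) {
    hit <- NULL
    for (site in forbidden) {
      pos <- regexpr(site, dna, fixed = TRUE)
      if (pos > 0L) { hit <- c(pos, nchar(site)); break }
    }
    if (is.null(hit)) return(dna)
    # codons overlapping the offending site, left to right
    c_from <- (hit[1] - 1L) %/% 3L + 1L
    c_to <- (hit[1] + hit[2] - 2L) %/% 3L + 1L
    swapped <- FALSE
    for (i in c_from:c_to) {
      nalt <- length(ranked[[aas[i]]])
      if (choice[i] < nalt) {
        choice[i] <- choice[i] + 1L
        swapped <- TRUE
        break
      }
    }
    if (!swapped)
      stop("forbidden site cannot be avoided: all synonymous choices ",
           "exhausted around position ", hit[1])
    dna <- buildDna()
  }
  stop("site avoidance did not converge")
}

stopCodon <- function(table) {
  stops <- table[table$aa == "*", , drop = FALSE]
  stops$codon[which.max(stops$fraction)]
}

#' Assemble an expression insert with HindIII/XhoI flanks
#'
#' Builds `HindIII site || ATG-initiated ORF || stop || XhoI site`. When
#' the protein does not start with methionine an initiator ATG is
#' prepended. Internal copies of either flanking site are eliminated by
#' the avoidance logic of [reverseTranslate()].
#'
#' @param protein a protein [SeqRecord-class].
#' @param table codon table.
#' @param flank5,flank3 enzyme names for the 5' and 3' flanks.
#' @param enzymes enzyme registry.
#' @return a [NucleotideConstruct-class].
#' @export
assembleExpressionInsert <- function(protein, table = loadCodonTable(),
                                     flank5 = "HindIII", flank3 = "XhoI",
                                     enzymes = loadEnzymes()) {
  p <- seqStr(protein)
  if (!startsWith(p, "M")) p <- paste0("M", p)
  site5 <- enzymeSite(flank5, enzymes)
  site3 <- enzymeSite(flank3, enzymes)
  orf <- paste0(reverseTranslate(p, table, forbidden = c(site5, site3)),
                stopCodon(table))
  # the stop codon or junction could complete a site; verify and, if so,
  # re-encode with the site context forbidden via codon swaps near the end
  dna <- paste0(site5, orf, site3)
  feats <- data.frame(
    label = c(flank5, "ORF", flank3),
    start = c(1L, nchar(site5) + 1L, nchar(site5) + nchar(orf) + 1L),
    end = c(nchar(site5), nchar(site5) + nchar(orf), nchar(dna)))
  internal <- findRestrictionSites(dna, c(flank5, flank3), enzymes)
  internal <- internal[!(internal$position %in%
                           c(1L, nchar(site5) + nchar(orf) + 1L)), ]
  if (nrow(internal))
    stop("internal ", internal$name[1], " site at position ",
         internal$position[1], " could not be avoided")
  new("NucleotideConstruct", id = recordId(protein), dna = dna,
      orfStart = nchar(site5) + 1L,
      orfEnd = nchar(site5) + nchar(orf), features = feats)
}

# in-frame junction residues encoded by a recognition site: the site is
# read as two codons (6-cutter) and translated, e.g. GGTACC -> GT (KpnI),
# GGATCC -> GS (BamHI)
junctionPeptide <- function(site) {
  if (nchar(site) %% 3L != 0L)
    stop("junction site length must be a multiple of 3 to stay in frame")
  translateOrf(site)
}

#' Assemble a single-chain molecular strain probe
#'
#' Protein-level fusion `partner_n || GT || reporter || GS || partner_c`
#' where the two-residue junctions are the in-frame translations of the
#' KpnI (GGTACC) and BamHI (GGATCC) sites joining the cDNA fragments. The
#' reporter must have its secretion peptide removed beforehand: SPs are
#' known to keep sandwiched reporters from working as strain sensors, so
#' an SP annotation raises an error.
#'
#' @param partner_n,partner_c interaction partner [SeqRecord-class]
#'   (e.g. FRB and FKBP).
#' @param reporter the sandwiched luciferase [SeqRecord-class], SP-free.
#' @param table codon table.
#' @param junction5,junction3 enzyme names for the two junctions.
#' @param enzymes enzyme registry.
#' @return list with `layout` ([ProbeLayout-class]) and `construct`
#'   ([NucleotideConstruct-class]).
#' @export
assembleStrainProbe <- function(partner_n, reporter, partner_c,
                                table = loadCodonTable(),
                                junction5 = "KpnI", junction3 = "BamHI",
                                enzymes = loadEnzymes()) {
  if (!is.null(getRegion(reporter, "SP")))
    stop("reporter still carries an SP annotation; secretion peptides ",
         "hamper strain probes -- call stripSignalPeptide() first")
  siteK <- enzymeSite(junction5, enzymes)
  siteB <- enzymeSite(junction3, enzymes)
  jn <- junctionPeptide(siteK); jc <- junctionPeptide(siteB)
  fusion <- paste0(seqStr(partner_n), jn, seqStr(reporter), jc,
                   seqStr(partner_c))
  site5 <- enzymeSite("HindIII", enzymes)
  site3 <- enzymeSite("XhoI", enzymes)
  p <- if (startsWith(fusion, "M")) fusion else paste0("M", fusion)
  orf <- reverseTranslate(p, table,
                          forbidden = c(site5, site3, siteK, siteB))
  # re-impose the junction codons so the cloning sites are literally
  # present once each at the fusion joints
  ins <- function(orf, pepPos, site) {
    # pepPos: 1-based residue index of the junction's first residue in p
    start <- (pepPos - 1L) * 3L + 1L
    paste0(substr(orf, 1L, start - 1L), site,
           substr(orf, start + nchar(site), nchar(orf)))
  }
  off <- nchar(p) - nchar(fusion)  # 1 if an initiator M was added
  posK <- off + nchar(seqStr(partner_n)) + 1L
  posB <- off + nchar(seqStr(partner_n)) + nchar(jn) +
    nchar(seqStr(reporter)) + 1L
  orf <- ins(orf, posK, siteK)
  orf <- ins(orf, posB, siteB)
  orf <- paste0(orf, stopCodon(table))
  dna <- paste0(site5, orf, site3)
  counts <- table(findRestrictionSites(dna, c("HindIII", junction5,
                                              junction3, "XhoI"),
                                       enzymes)$name)
  if (any(counts != 1L))
    stop("cloning sites must each occur exactly once in the construct")
  layout <- new("ProbeLayout", kind = "strain_probe",
                parts = list(partner_n = partner_n, reporter = reporter,
                             partner_c = partner_c),
                junctionSites = c("HindIII", junction5, junction3, "XhoI"))
  construct <- new("NucleotideConstruct",
                   id = paste0("F-", recordId(reporter), "-F"), dna = dna,
                   orfStart = nchar(site5) + 1L,
                   orfEnd = nchar(site5) + nchar(orf),
                   features = data.frame(
                     label = c("HindIII", "ORF", junction5, junction3,
                               "XhoI"),
                     start = c(1L, nchar(site5) + 1L,
                               nchar(site5) + (posK - 1L) * 3L + 1L,
                               nchar(site5) + (posB - 1L) * 3L + 1L,
                               nchar(dna) - nchar(site3) + 1L),
                     end = c(nchar(site5), nchar(site5) + nchar(orf),
                             nchar(site5) + (posK - 1L) * 3L + 6L,
                             nchar(site5) + (posB - 1L) * 3L + 6L,
                             nchar(dna))))
  list(layout = layout, construct = construct)
}

#' Propose dissection sites in hinge regions
#'
#' Split-reporter dissection points are chosen in hinge coils between
#' alpha-helices: one candidate per maximal coil (C) run flanked by helix
#' (H) runs on both sides, split after the coil run's midpoint residue
#' (lower median on even runs).
#'
#' @param protein a protein [SeqRecord-class].
#' @param ss per-residue secondary structure string over H/E/C, same
#'   length as the protein.
#' @return data.frame with columns `after_residue`, `n_frag_len`,
#'   `c_frag_len`, sorted by position.
#' @examples
#' rec <- SeqRecord("x", "MKTAYIAKQRQ")
#' proposeDissectionSites(rec, "HHHHCCCHHHH")
#' @export
proposeDissectionSites <- function(protein, ss) {
  n <- seqLength(protein)
  ss <- toupper(ss)
  if (nchar(ss) != n)
    stop("secondary-structure string length (", nchar(ss),
         ") differs from protein length (", n, ")")
  chars <- strsplit(ss, "")[[1]]
  if (any(!chars %in% c("H", "E", "C")))
    stop("secondary structure must be over H/E/C")
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sites <- integer()
  for (i in seq_along(runs$values)) {
    if (runs$values[i] != "C") next
    if (i == 1L || i == length(runs$values)) next
    if (runs$values[i - 1L] != "H" || runs$values[i + 1L] != "H") next
    idx <- starts[i]:ends[i]
    sites <- c(sites, idx[ceiling(length(idx) / 2)])
  }
  sites <- sort(sites[sites >= 1L & sites < n])
  data.frame(after_residue = sites, n_frag_len = sites,
             c_frag_len = n - sites)
}

#' Assemble a protein fragment complementation (PCA) probe
#'
#' Protein-level assembly `reporter[1..k] || GT || insert || GS ||
#' reporter[k+1..end]` for a dissection after residue `k` (slash
#' notation `1-k / k+1-end`). With an empty insert and
#' `junctions = FALSE` the assembly reconstitutes the intact reporter
#' exactly.
#'
#' @param reporter the split luciferase [SeqRecord-class].
#' @param after_residue dissection point: split between `after_residue`
#'   and `after_residue + 1`.
#' @param insert sensing domain [SeqRecord-class] placed between the
#'   fragments, or `NULL` for none.
#' @param table codon table.
#' @param junctions keep the in-frame KpnI/BamHI junction residues.
#' @param enzymes enzyme registry.
#' @return list with `layout` ([ProbeLayout-class]) and `construct`
#'   ([NucleotideConstruct-class]); fragment lengths are reported on the
#'   layout parts.
#' @export
assemblePcaProbe <- function(reporter, after_residue, insert = NULL,
                             table = loadCodonTable(), junctions = TRUE,
                             enzymes = loadEnzymes()) {
  n <- seqLength(reporter)
  after_residue <- as.integer(after_residue)
  if (after_residue < 1L || after_residue >= n)
    stop("dissection site out of range (1 <= site < ", n, ")")
  nfrag <- substr(seqStr(reporter), 1L, after_residue)
  cfrag <- substr(seqStr(reporter), after_residue + 1L, n)
  siteK <- enzymeSite("KpnI", enzymes)
  siteB <- enzymeSite("BamHI", enzymes)
  jn <- if (junctions) junctionPeptide(siteK) else ""
  jc <- if (junctions) junctionPeptide(siteB) else ""
  insSeq <- if (is.null(insert)) "" else seqStr(insert)
  fusion <- paste0(nfrag, jn, insSeq, jc, cfrag)
  site5 <- enzymeSite("HindIII", enzymes)
  site3 <- enzymeSite("XhoI", enzymes)
  p <- if (startsWith(fusion, "M")) fusion else paste0("M", fusion)
  forb <- c(site5, site3, if (junctions) c(siteK, siteB))
  orf <- paste0(reverseTranslate(p, table, forbidden = forb),
                stopCodon(table))
  dna <- paste0(site5, orf, site3)
  parts <- list(n_frag = SeqRecord(paste0(recordId(reporter), "_N"), nfrag))
  if (!is.null(insert)) parts$insert <- insert
  parts$c_frag <- SeqRecord(paste0(recordId(reporter), "_C"), cfrag)
  layout <- new("ProbeLayout", kind = "pca_probe", parts = parts,
                junctionSites = c("HindIII",
                                  if (junctions) c("KpnI", "BamHI"),
                                  "XhoI"))
  construct <- new("NucleotideConstruct",
                   id = sprintf("%s_%d", recordId(reporter), after_residue),
                   dna = dna, orfStart = nchar(site5) + 1L,
                   orfEnd = nchar(site5) + nchar(orf),
                   features = data.frame(
                     label = c("HindIII", "ORF", "XhoI"),
                     start = c(1L, nchar(site5) + 1L,
                               nchar(dna) - nchar(site3) + 1L),
                     end = c(nchar(site5), nchar(site5) + nchar(orf),
                             nchar(dna))))
  list(layout = layout, construct = construct)
}

#' Fragment lengths of a PCA layout
#'
#' @param layout a pca_probe [ProbeLayout-class].
#' @return named integer vector with `n_frag_len` and `c_frag_len`.
#' @export
pcaFragmentLengths <- function(layout) {
  stopifnot(layout@kind == "pca_probe")
  c(n_frag_len = seqLength(layout@parts$n_frag),
    c_frag_len = seqLength(layout@parts$c_frag))
}
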