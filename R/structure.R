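STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read ATOM coordinates from PDB text or file
#'
#' Parses ATOM records (fixed columns) into a [StructureModel-class].
#' HETATM records and hydrogens are skipped, as are non-standard residues
#' (with a warning). Malformed coordinate fields raise an error naming
#' the offending line. Parsing is delegated to `bio3d::read.pdb` and the
#' result is validated and reduced to the fields the distance metrics
#' need.
#'
#' @param pdb path to a PDB file, or a string of PDB text (recognised by
#'   embedded newlines with ATOM/HETATM records).
#' @return a [StructureModel-class].
#' @export
readStructure <- function(pdb) {
  path <- pdb
  if (grepl("\n", pdb) || grepl("^(ATOM|HETATM|HEADER|REMARK)", pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(pdb, path)
  } else if (!file.exists(path)) {
    stop("input is neither PDB text nor an existing file")
  }
  raw <- readLines(path)
  atomLines <- grep("^ATOM", raw)
  if (!length(atomLines)) stop("no ATOM records")
  # fixed-column pre-check: x/y/z live in columns 31-38/39-46/47-54
  for (ln in atomLines) {
    xyz <- suppressWarnings(as.numeric(c(substr(raw[ln], 31, 38),
                                         substr(raw[ln], 39, 46),
                                         substr(raw[ln], 47, 54))))
    if (anyNA(xyz))
      stop("malformed coordinate field in ATOM record at line ", ln)
  }
  pdbObj <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse failed: ", conditionMessage(e)))
  at <- pdbObj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    bad <- which(!is.finite(at$x) | !is.finite(at$y) |
                   !is.finite(at$z))[1]
    stop("malformed coordinate field in ATOM record ", bad,
         " (line ", atomLines[min(bad, length(atomLines))], ")")
  }
  # drop hydrogens (element H/D or names starting H after any digit)
  isH <- !is.na(at$elesy) & at$elesy %in% c("H", "D")
  isH <- isH | grepl("^[0-9]*H", at$elety)
  at <- at[!isH, , drop = FALSE]
  nonstd <- !at$resid %in% STANDARD_RESIDUES
  if (any(nonstd)) {
    warning("skipping non-standard residues: ",
            paste(unique(at$resid[nonstd]), collapse = ", "))
    at <- at[!nonstd, , drop = FALSE]
  }
  if (!nrow(at)) stop("no standard-residue ATOM records")
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom: ", key[duplicated(key)][1])
  new("StructureModel", atoms = atoms)
}

residueAtoms <- function(model, chain, resno) {
  a <- model@atoms
  sel <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  if (!nrow(sel))
    stop("residue ", chain, ":", resno, " not found in model")
  sel
}

#' Minimal inter-side-chain distance between two residues
#'
#' Minimum Euclidean distance over all pairs of heavy side-chain atoms
#' (atoms from C-beta outward; backbone N/CA/C/O excluded). Glycine has
#' no side chain and falls back to its C-alpha (with a message). This is
#' the loop-proximity metric used to relate a compensated loop to the
#' substrate binding site.
#'
#' @param model a [StructureModel-class].
#' @param res_a,res_b residue selectors `list(chain, resno)` or
#'   `c(chain, resno)`.
#' @return minimal distance in Angstrom.
#' @examples
#' pdb <- paste(
#'  "ATOM      1  CB  PHE A  56       0.000   0.000   0.000  1.00  0.00",
#'  "ATOM      2  SD  MET A 143       3.000   4.000   0.000  1.00  0.00",
#'  sep = "\n")
#' sidechainMinDistance(readStructure(pdb), c("A", 56), c("A", 143))
#' @export
sidechainMinDistance <- function(model, res_a, res_b) {
  pick <- function(sel) {
    chain <- as.character(sel[[1]])
    resno <- as.integer(sel[[2]])
    at <- residueAtoms(model, chain, resno)
    sc <- at[!at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    if (!nrow(sc)) {
      message("residue ", chain, ":", resno,
              " has no side-chain atoms; falling back to CA")
      sc <- at[at$elety == "CA", , drop = FALSE]
      if (!nrow(sc)) stop("residue ", chain, ":", resno,
                          " has neither side-chain atoms nor CA")
    }
    as.matrix(sc[, c("x", "y", "z")])
  }
  A <- pick(res_a)
  B <- pick(res_b)
  dmin <- Inf
  for (i in seq_len(nrow(A))) {
    dd <- sqrt(colSums((t(B) - A[i, ])^2))
    dmin <- min(dmin, dd)
  }
  dmin
}

#' Classify loop proximity to the active site
#'
#' Three-way classification of the minimal inter-side-chain distance
#' between a loop residue and the methionine adjacent to the binding
#' site: `close` (<= 6 A), `middle` (6-8.5 A], `far` (> 8.5 A). The
#' middle/far boundary of 8.5 A places an 8.0 A contact in the middle
#' class and an 8.7 A contact in the far class; both thresholds are
#' configurable.
#'
#' @param distance distance(s) in Angstrom, non-negative.
#' @param close_max upper bound of the close class (default 6.0).
#' @param middle_max upper bound of the middle class (default 8.5).
#' @return factor with levels close/middle/far.
#' @examples
#' classifyLoopProximity(c(3.4, 8.0, 8.7))
#' @export
classifyLoopProximity <- function(distance, close_max = 6.0,
                                  middle_max = 8.5) {
  if (any(distance < 0)) stop("distances must be non-negative")
  if (!(close_max < middle_max)) stop("need close_max < middle_max")
  cls <- ifelse(distance <= close_max, "close",
                ifelse(distance <= middle_max, "middle", "far"))
  factor(cls, levels = c("close", "middle", "far"))
}

#' Distance/classification report for residue pairs
#'
#' @param model a [StructureModel-class].
#' @param pairs data.frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`.
#' @param ... thresholds passed to [classifyLoopProximity()].
#' @return data.frame with the distances and proximity classes appended.
#' @export
proximityReport <- function(model, pairs, ...) {
  d <- vapply(seq_len(nrow(pairs)), function(i)
    sidechainMinDistance(model,
                         c(pairs$chain_a[i], pairs$resno_a[i]),
                         c(pairs$chain_b[i], pairs$resno_b[i])),
    numeric(1))
  cbind(pairs, distance_A = d,
        class = as.character(classifyLoopProximity(d, ...)))
}
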