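#' Identity distance matrix from global pairwise alignments
#'
#' For every pair of records the global alignment is computed and the
#' distance is `1 - identity`, where identity is the fraction of matching
#' columns. The default denominator counts all alignment columns
#' (including gap columns); `denominator = "ungapped"` restricts to
#' columns where both rows carry residues.
#'
#' @param records list of protein [SeqRecord-class] with unique ids.
#' @param scheme a [ScoringScheme-class].
#' @param denominator see [alignmentIdentity()].
#' @return symmetric numeric matrix with zero diagonal and record ids as
#'   dimnames.
#' @export
identityDistanceMatrix <- function(records, scheme = defaultScheme(),
                                   denominator = c("all", "ungapped")) {
  denominator <- match.arg(denominator)
  if (length(records) < 2L) stop("need at least 2 records")
  ids <- vapply(records, recordId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", ids[duplicated(ids)][1])
  n <- length(records)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- globalAlign(records[[i]], records[[j]], scheme)
    d[i, j] <- d[j, i] <- 1 - alignmentIdentity(aln, denominator)
  }
  d
}

checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with the Q criterion. Ties in Q
#' are broken toward the lexicographically lowest label pair so trees are
#' bit-reproducible. Negative branch lengths are clamped to zero with a
#' warning. On additive matrices the tree reproduces the input distances
#' exactly.
#'
#' @param d symmetric distance matrix with zero diagonal and >= 3 labeled
#'   taxa.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighborJoining <- function(d) {
  checkDistanceMatrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  # active nodes carry tree-node numbers: tips 1..n0, internals appended
  # from n0+1 in creation order; every internal is created with its two
  # (or final three) children, so edges form a tree rooted at the last
  # internal
  act <- seq_len(n0)
  nodeN <- n0
  keys <- c(labels, rep("", n0))  # lexicographic keys for tie-breaking
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric()
  D <- d
  nneg <- 0L
  clamp <- function(x) {
    if (x < -1e-12) nneg <<- nneg + 1L
    max(x, 0)
  }
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(D)
    best <- NULL
    for (ii in seq_len(m - 1L)) for (jj in (ii + 1L):m) {
      q <- (m - 2) * D[ii, jj] - r[ii] - r[jj]
      pairKey <- paste(sort(c(keys[act[ii]], keys[act[jj]])),
                       collapse = "\r")
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 && pairKey < best$key))
        best <- list(q = q, i = ii, j = jj, key = pairKey)
    }
    i <- best$i; j <- best$j
    li0 <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    li <- clamp(li0)
    lj <- clamp(D[i, j] - li0)
    nodeN <- nodeN + 1L
    u <- nodeN
    keys[u] <- min(keys[act[i]], keys[act[j]])
    edges <- rbind(edges, c(u, act[i]), c(u, act[j]))
    lens <- c(lens, li, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    act <- c(act[keep], u)
  }
  # closed-form star join of the final three nodes
  b <- c(clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2),
         clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2),
         clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2))
  nodeN <- nodeN + 1L
  u <- nodeN
  edges <- rbind(edges, c(u, act[1]), c(u, act[2]), c(u, act[3]))
  lens <- c(lens, b)
  if (nneg > 0L)
    warning(nneg, " negative branch length(s) clamped to 0")
  # renumber to ape convention: tips 1..n, internals n+1..2n-2 with the
  # root (the last-created center node) as n+1
  internal <- (n0 + 1L):nodeN
  map <- integer(nodeN)
  map[seq_len(n0)] <- seq_len(n0)
  map[internal] <- n0 + rev(seq_along(internal))
  em <- cbind(map[edges[, 1]], map[edges[, 2]])
  # arrange edges in preorder (cladewise) from the center node
  kids <- split(seq_len(nrow(em)), em[, 1])
  ord <- integer(0)
  visit <- function(node) {
    for (e in kids[[as.character(node)]]) {
      ord <<- c(ord, e)
      if (em[e, 2] > n0) visit(em[e, 2])
    }
  }
  visit(n0 + 1L)
  tr <- list(edge = em[ord, , drop = FALSE], edge.length = lens[ord],
             tip.label = labels, Nnode = length(internal))
  class(tr) <- "phylo"
  tr
}

#' Patristic (path-length) distances of a tree
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric matrix of leaf-to-leaf path lengths, labels ordered
#'   as `tree$tip.label`.
#' @export
treeDistances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

quoteLabel <- function(x) {
  if (grepl("[\\s()\\[\\]:;,']", x, perl = TRUE))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

#' Write a tree as Newick text
#'
#' Branch lengths are always emitted; labels containing whitespace or
#' Newick metacharacters are single-quoted. The tree is written unrooted
#' (basal polytomy), terminated by `;`.
#'
#' @param tree an `ape::phylo`.
#' @param digits significant digits for branch lengths.
#' @return Newick string.
#' @export
writeNewick <- function(tree, digits = 10L) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(node) {
    ks <- kids[[as.character(node)]]
    if (is.null(ks)) return(quoteLabel(tree$tip.label[node]))
    inner <- vapply(ks, function(e)
      paste0(rec(tree$edge[e, 2]), ":", fmt(tree$edge.length[e])),
      character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  paste0(rec(root), ";")
}

#' Write a labeled distance matrix as TSV
#'
#' @param d distance matrix with labels.
#' @param path output path.
#' @export
writeDistanceMatrix <- function(d, path) {
  utils::write.table(cbind(label = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a labeled distance matrix from TSV (or PHYLIP square format)
#'
#' @param path TSV written by [writeDistanceMatrix()], or a PHYLIP square
#'   matrix (first line = number of taxa).
#' @return distance matrix.
#' @export
readDistanceMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*\\d+\\s*$", first)) {
    tab <- utils::read.table(path, skip = 1L, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  labs <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(m) <- list(labs, labs)
  storage.mode(m) <- "double"
  checkDistanceMatrix(m)
}
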