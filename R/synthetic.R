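# residue frequencies used by the generators: uniform over the 20
# standard residues keeps the fixtures neutral with respect to the
# scoring matrix
sampleResidues <- function(n) paste(sample(AA_ALPHABET_STRICT, n,
                                           replace = TRUE), collapse = "")

#' Recipe for a synthetic copepod-luciferase-like family
#'
#' Defines the architecture the generator emulates: a secretion peptide,
#' a flexible N-terminal region homologous to the catalytic domain but
#' with an optional planted vacancy (deleted block), and two tandem
#' copies of the catalytic domain, the second carrying per-residue
#' substitutions at `domain_mut_rate`. Defaults follow the scale of real
#' copepod luciferases (about 200 mature residues with ~90-residue
#' domains).
#'
#' @param seed integer RNG seed; the recipe is a pure function of its
#'   fields, seed included.
#' @param sp_len secretion-peptide length in residues.
#' @param domain_len catalytic-domain length in residues.
#' @param domain_mut_rate substitution probability per residue between
#'   the two domain copies (0-0.5).
#' @param vacancy `c(anchor, length)`: a block of `length` residues is
#'   deleted from the N-region immediately after position `anchor`, or
#'   `NULL` for no vacancy.
#' @param n_mut_rate substitution rate between the domain and the
#'   N-region before the deletion (the N-region is domain-homologous).
#' @param domain_seq optional explicit domain sequence overriding the
#'   random draw (e.g. to plant specific donor residues).
#' @return a `family_recipe` list.
#' @export
familyRecipe <- function(seed = 1L, sp_len = 17L, domain_len = 90L,
                         domain_mut_rate = 0, vacancy = c(50L, 21L),
                         n_mut_rate = 0.3, domain_seq = NULL) {
  stopifnot(sp_len >= 0L, domain_len > 0L,
            domain_mut_rate >= 0, domain_mut_rate <= 0.5,
            n_mut_rate >= 0, n_mut_rate <= 0.5)
  if (!is.null(vacancy)) {
    stopifnot(length(vacancy) == 2L, vacancy[1] >= 1L, vacancy[2] >= 1L,
              vacancy[1] + vacancy[2] <= domain_len)
  }
  if (!is.null(domain_seq)) {
    domain_seq <- toupper(domain_seq)
    stopifnot(nchar(domain_seq) == domain_len)
  }
  structure(list(seed = as.integer(seed), sp_len = as.integer(sp_len),
                 domain_len = as.integer(domain_len),
                 domain_mut_rate = domain_mut_rate, vacancy = vacancy,
                 n_mut_rate = n_mut_rate, domain_seq = domain_seq),
            class = "family_recipe")
}

mutateSeq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit))
    chars[i] <- sample(setdiff(AA_ALPHABET_STRICT, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate a synthetic luciferase-family record
#'
#' Deterministic for a fixed recipe (seed included): the record is
#' `SP || N-region || domain1 || domain2` with SP/N_REGION/DOMAIN1/
#' DOMAIN2 annotations attached. The N-region is a (mutated) copy of the
#' domain with the planted vacancy removed, so the self-alignment
#' pipeline can recover the deleted block as a vacancy donor.
#'
#' @param recipe a recipe from [familyRecipe()].
#' @param id record id.
#' @return an annotated [SeqRecord-class]; the deleted block (if any) is
#'   attached as attribute `"planted_block"`.
#' @export
generateSyntheticFamily <- function(recipe, id = "synluc") {
  stopifnot(inherits(recipe, "family_recipe"))
  withr_seed <- recipe$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  sp <- if (recipe$sp_len > 0L) sampleResidues(recipe$sp_len) else ""
  domain <- if (is.null(recipe$domain_seq)) {
    sampleResidues(recipe$domain_len)
  } else recipe$domain_seq
  nreg <- mutateSeq(domain, recipe$n_mut_rate)
  planted <- NULL
  if (!is.null(recipe$vacancy)) {
    a <- recipe$vacancy[1]; len <- recipe$vacancy[2]
    # the recoverable truth is the domain residues spanning the vacancy:
    # those are what the donor rows expose and what a compensation block
    # would restore (the deleted N-copy residues carry the N divergence)
    planted <- substr(domain, a + 1L, a + len)
    nreg <- paste0(substr(nreg, 1L, a),
                   substr(nreg, a + len + 1L, nchar(nreg)))
  }
  domain2 <- mutateSeq(domain, recipe$domain_mut_rate)
  seqs <- c(sp, nreg, domain, domain2)
  ends <- cumsum(nchar(seqs))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  labels <- c("SP", "N_REGION", "DOMAIN1", "DOMAIN2")
  keep <- nchar(seqs) > 0L
  ann <- data.frame(label = labels[keep], start = starts[keep],
                    end = ends[keep])
  rec <- SeqRecord(id, paste(seqs, collapse = ""), annotations = ann)
  attr(rec, "planted_block") <- planted
  restoreSeedState(old)
  rec
}

#' Recipe for a synthetic emission spectrum
#'
#' @param seed integer RNG seed.
#' @param peaks data.frame (or matrix) with columns `center`, `sigma`,
#'   `amplitude`: Gaussian components in nm / nm / arbitrary units.
#' @param grid `c(start, stop, step)` wavelength grid in nm.
#' @param noise_sd relative (multiplicative) noise s.d.; 0 for none.
#' @return a `spectrum_recipe` list.
#' @export
spectrumRecipe <- function(seed = 1L,
                           peaks = data.frame(center = 497, sigma = 35,
                                              amplitude = 1),
                           grid = c(400, 750, 1), noise_sd = 0) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "sigma", "amplitude") %in% names(peaks)),
            all(peaks$sigma > 0), grid[3] > 0, grid[1] < grid[2],
            all(peaks$center >= grid[1] & peaks$center <= grid[2]),
            noise_sd >= 0)
  structure(list(seed = as.integer(seed), peaks = peaks, grid = grid,
                 noise_sd = noise_sd), class = "spectrum_recipe")
}

#' Generate a synthetic emission spectrum
#'
#' Sum of Gaussian components on the wavelength grid, optionally with
#' multiplicative noise `1 + N(0, noise_sd)` (clamped at zero).
#' Deterministic per recipe seed.
#'
#' @param recipe a recipe from [spectrumRecipe()].
#' @param label spectrum label.
#' @return an [EmissionSpectrum-class].
#' @export
generateSyntheticSpectrum <- function(recipe, label = "synthetic") {
  stopifnot(inherits(recipe, "spectrum_recipe"))
  old <- .Random.seed_exists()
  set.seed(recipe$seed)
  w <- seq(recipe$grid[1], recipe$grid[2], by = recipe$grid[3])
  y <- rep(0, length(w))
  for (i in seq_len(nrow(recipe$peaks)))
    y <- y + recipe$peaks$amplitude[i] *
      exp(-(w - recipe$peaks$center[i])^2 /
            (2 * recipe$peaks$sigma[i]^2))
  if (recipe$noise_sd > 0)
    y <- pmax(y * (1 + stats::rnorm(length(y), 0, recipe$noise_sd)), 0)
  restoreSeedState(old)
  EmissionSpectrum(w, y, label)
}

# save/restore the global RNG state so generators are pure functions of
# their recipe and do not disturb the caller's RNG stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restoreSeedState <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
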