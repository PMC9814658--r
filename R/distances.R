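# Pairwise difference machinery shared by the diversity statistics,
# AMOVA and the permutation test.  Missing data are handled by pairwise
# deletion: each pair is compared over the sites where both sequences
# carry an unambiguous base, and counts are rescaled to per-site or
# per-locus as needed.

# Core pair statistics.  Returns ndiff (raw differing-site counts over
# comparable sites) and ncomp (number of comparable sites) as N x N
# symmetric matrices with zero/irrelevant diagonals.
#
# Only sites with >= 2 distinct non-missing states can contribute
# differences, so the expensive crossproducts run on that (small) subset;
# comparable-site counts only require the pattern of missingness.
pair_stats <- function(aln, int_mat = NULL) {
  im <- if (is.null(int_mat)) encode_states(aln) else int_mat
  N <- nrow(im)
  L <- ncol(im)
  isna <- is.na(im)
  miss <- rowSums(isna)
  nac <- which(colSums(isna) > 0L)
  if (length(nac)) {
    overlap <- tcrossprod(isna[, nac, drop = FALSE] * 1)
  } else {
    overlap <- matrix(0, N, N)
  }
  ncomp <- L - outer(miss, miss, `+`) + overlap

  vs <- variable_sites(im)
  if (length(vs)) {
    v <- im[, vs, drop = FALSE]
    vok <- !is.na(v)
    comp_v <- tcrossprod(vok * 1)
    match_v <- matrix(0, N, N)
    for (s in 1:4) match_v <- match_v + tcrossprod((v == s & vok) * 1)
    ndiff <- comp_v - match_v
  } else {
    ndiff <- matrix(0, N, N)
  }
  diag(ndiff) <- 0
  dimnames(ndiff) <- dimnames(ncomp) <- list(rownames(im), rownames(im))
  list(ndiff = ndiff, ncomp = ncomp)
}

#' Pairwise nucleotide differences
#'
#' Per-locus pairwise distance matrix: for each pair, the number of
#' differing sites over comparable (both non-missing) sites, rescaled to
#' the full alignment length (`diff / comparable * L`).  Pairs with no
#' comparable site are returned as `NA` and downstream consumers exclude
#' them with a warning.
#'
#' @param aln a [hap_alignment()].
#' @return N x N symmetric numeric matrix with zero diagonal.
#' @export
pairwise_differences <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (aln$N < 2) stop("need at least 2 sequences")
  ps <- pair_stats(aln)
  d <- ps$ndiff / ps$ncomp * aln$L
  d[ps$ncomp == 0] <- NA_real_
  diag(d) <- 0
  if (anyNA(d))
    warning("some sequence pairs share no comparable site; entries set NA")
  d
}

# per-site difference fraction matrix (NA where no comparable site)
pair_fraction <- function(aln, int_mat = NULL) {
  ps <- pair_stats(aln, int_mat)
  f <- ps$ndiff / ps$ncomp
  f[ps$ncomp == 0] <- NA_real_
  diag(f) <- 0
  f
}

upper_mean <- function(m) {
  v <- m[upper.tri(m)]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}
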