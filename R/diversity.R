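# Per-group diversity panel: polymorphic/missing site counts, nucleotide
# diversity, haplotype diversity, Watterson's theta, Tajima's D (with a
# beta-approximation significance flag), net divergence between groups,
# and rarefaction curves.
#
# Conventions (matching the scales population mitogenome studies report):
#   * pi is per site; Watterson's theta is per locus.
#   * Missing data: pairwise deletion; per-pair difference counts are
#     divided by the pair's comparable sites, and multiplied by L where a
#     per-locus quantity is needed.

#' Polymorphic and missing site counts
#'
#' A site is polymorphic when at least two distinct non-missing states
#' occur there; `Nm` counts sites with at least one missing state.
#'
#' @param aln a [hap_alignment()] with `N >= 2`.
#' @return list with integer components `Np` and `Nm`.
#' @export
site_summaries <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (aln$N < 2) stop("need at least 2 sequences")
  im <- encode_states(aln)
  list(Np = length(variable_sites(im)),
       Nm = sum(colSums(is.na(im)) > 0L))
}

#' Nucleotide diversity (pi)
#'
#' Mean over all unordered sequence pairs of the per-site difference
#' fraction (differences at pairwise-complete sites divided by the number
#' of such sites).  Pairs sharing no comparable site are excluded from
#' the mean.
#'
#' @param aln a [hap_alignment()] with `N >= 2`.
#' @return pi per site, or `NA` (with a warning) if no pair is comparable.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (aln$N < 2) stop("need at least 2 sequences")
  f <- pair_fraction(aln)
  pi <- upper_mean(f)
  if (is.na(pi)) warning("all sequence pairs incomparable; pi undefined")
  pi
}

#' Haplotype diversity (h)
#'
#' `h = N/(N-1) * (1 - sum p_i^2)` over haplotype frequencies, the
#' small-sample-corrected probability that two random sequences carry
#' different haplotypes.
#'
#' @param ht a `hap_table` from [collapse_haplotypes()].
#' @return h in `[0, 1]`.
#' @export
haplotype_diversity <- function(ht) {
  stopifnot(inherits(ht, "hap_table"))
  n <- ht$N
  if (n < 2) stop("need at least 2 samples")
  p <- ht$counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Watterson's theta (per locus)
#'
#' `theta_W = Np / a1(n)` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param Np number of polymorphic sites.
#' @param n sample size (`>= 2`).
#' @return theta per locus.
#' @export
watterson_theta <- function(Np, n) {
  if (n < 2) stop("need at least 2 samples")
  Np / sum(1 / seq_len(n - 1))
}

# Tajima (1989) normalising constants as functions of sample size
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# D from precomputed per-locus mean pairwise differences, S and n;
# p-value from the beta approximation of the null density
tajima_d_from_summaries <- function(kbar, S, n) {
  if (S == 0) return(list(D = NA_real_, p = NA_real_))
  cst <- tajima_constants(n)
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (!is.finite(v) || v <= 0) return(list(D = NA_real_, p = NA_real_))
  D <- (kbar - S / cst$a1) / sqrt(v)
  Dmin <- (2 / n - 1 / cst$a1) / sqrt(cst$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / cst$a1) / sqrt(cst$e2)
  tmp1 <- 1 + Dmin * Dmax
  tmp2 <- Dmax - Dmin
  a <- -tmp1 * Dmax / tmp2
  b <- tmp1 * Dmin / tmp2
  pv <- stats::pbeta((D - Dmin) / tmp2, b, a)
  list(D = D, p = 2 * min(pv, 1 - pv))
}

#' Tajima's D
#'
#' Normalized difference between the mean-pairwise-difference and
#' segregating-sites estimators of the population mutation rate.  Mean
#' pairwise differences use pairwise deletion rescaled to the full locus
#' length.  Significance (two-sided) uses the beta-distribution
#' approximation of the null.
#'
#' @param aln a [hap_alignment()] with `N >= 2` (>= 4 recommended).
#' @return list with `D` and `p` (both `NA` when the alignment is
#'   monomorphic).
#' @export
tajimas_d <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (aln$N < 2) stop("need at least 2 sequences")
  im <- encode_states(aln)
  S <- length(variable_sites(im))
  kbar <- upper_mean(pair_fraction(aln, im)) * aln$L
  tajima_d_from_summaries(kbar, S, aln$N)
}

#' Net divergence between two groups (D_A)
#'
#' `D_A = d_XY - (d_X + d_Y)/2` per site, where `d_XY` is the mean
#' between-group pairwise difference fraction and `d_X`, `d_Y` are the
#' within-group nucleotide diversities.  Under clean isolation this
#' estimates `2 * mu * T` for split time `T`.
#'
#' @param x,y [hap_alignment()] objects with equal `L`.
#' @return D_A per site.
#' @export
net_divergence <- function(x, y) {
  stopifnot(inherits(x, "hap_alignment"), inherits(y, "hap_alignment"))
  if (x$L != y$L) stop("alignments must have equal length")
  pooled <- hap_alignment(rbind(x$states, y$states),
                          c(paste0("x_", x$ids), paste0("y_", y$ids)))
  f <- pair_fraction(pooled)
  ix <- seq_len(x$N)
  iy <- x$N + seq_len(y$N)
  d_xy <- mean(f[ix, iy, drop = FALSE], na.rm = TRUE)
  within_pi <- function(idx, label) {
    if (length(idx) < 2) {
      warning("group ", label, " has a single sequence; within-group pi = 0")
      return(0)
    }
    upper_mean(f[idx, idx, drop = FALSE])
  }
  d_xy - (within_pi(ix, "X") + within_pi(iy, "Y")) / 2
}

#' Haplotype rarefaction curve
#'
#' Expected number of distinct haplotypes in random subsamples (without
#' replacement) of each size `m`.  Implemented by drawing `reps` random
#' orderings of the samples and counting first occurrences cumulatively,
#' so one pass yields every `m` at once.
#'
#' @param ht a `hap_table` from [collapse_haplotypes()].
#' @param reps number of resampling replicates (default 1000).
#' @param seed integer seed (required; results are deterministic given it).
#' @param m_values subsample sizes to report (default `1:N`).
#' @return data frame with columns `m`, `mean`, `lo`, `hi` (2.5/97.5
#'   percentiles across replicates).
#' @export
rarefaction <- function(ht, reps = 1000, seed, m_values = NULL) {
  stopifnot(inherits(ht, "hap_table"), reps >= 1)
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  N <- ht$N
  if (is.null(m_values)) m_values <- seq_len(N)
  stopifnot(all(m_values >= 1), all(m_values <= N))
  labels <- ht$assignment
  acc <- matrix(0L, reps, length(m_values))
  for (r in seq_len(reps)) {
    perm <- labels[sample.int(N)]
    newhap <- !duplicated(perm)
    acc[r, ] <- cumsum(newhap)[m_values]
  }
  data.frame(m = m_values,
             mean = colMeans(acc),
             lo = apply(acc, 2L, stats::quantile, 0.025),
             hi = apply(acc, 2L, stats::quantile, 0.975),
             row.names = NULL)
}

# one DiversityStats row; expects >= 2 samples
diversity_row <- function(aln) {
  im <- encode_states(aln)
  S <- length(variable_sites(im))
  Nm <- sum(colSums(is.na(im)) > 0L)
  ht <- collapse_haplotypes(aln)
  f <- pair_fraction(aln, im)
  pi <- upper_mean(f)
  kbar <- pi * aln$L
  td <- tajima_d_from_summaries(kbar, S, aln$N)
  data.frame(N = aln$N, Np = S, Nh = ht$Nh, Nm = Nm,
             pi = pi,
             h = haplotype_diversity(ht),
             theta_w = watterson_theta(S, aln$N),
             tajima_d = td$D,
             tajima_p = td$p,
             tajima_sig = !is.na(td$p) && td$p < 0.05)
}

empty_diversity_row <- function(n) {
  data.frame(N = n, Np = NA_integer_, Nh = NA_integer_, Nm = NA_integer_,
             pi = NA_real_, h = NA_real_, theta_w = NA_real_,
             tajima_d = NA_real_, tajima_p = NA_real_, tajima_sig = NA)
}

subset_alignment <- function(aln, idx) {
  out <- hap_alignment(aln$states[idx, , drop = FALSE], aln$ids[idx])
  if (!is.null(aln$meta)) {
    out$meta <- aln$meta[idx, , drop = FALSE]
    rownames(out$meta) <- NULL
  }
  out
}

#' Diversity statistics by group
#'
#' One diversity panel row per group label, plus (when era metadata is
#' attached) rows for the modern and ancient strata and a `total` row.
#' Groups with fewer than two members yield a row of `NA` statistics with
#' a warning.
#'
#' @param aln a [hap_alignment()].
#' @param grouping named character vector or factor mapping each sample
#'   id to a group label; defaults to the metadata `location` column.
#' @return data frame with one row per group (columns `group`, `N`, `Np`,
#'   `Nh`, `Nm`, `pi`, `h`, `theta_w`, `tajima_d`, `tajima_p`,
#'   `tajima_sig`).
#' @export
stats_by_group <- function(aln, grouping = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(grouping)) {
    if (is.null(aln$meta)) stop("no grouping given and no metadata attached")
    grouping <- stats::setNames(aln$meta$location, aln$ids)
  }
  grouping <- grouping[aln$ids]
  if (anyNA(grouping)) stop("every sample must be labeled")
  blocks <- c(split(seq_len(aln$N), as.character(grouping)))
  if (!is.null(aln$meta)) {
    blocks <- c(blocks,
                list(modern = which(aln$meta$era == "modern"),
                     ancient = which(aln$meta$era == "ancient")))
  }
  blocks <- c(blocks, list(total = seq_len(aln$N)))
  blocks <- blocks[lengths(blocks) > 0L]
  rows <- lapply(names(blocks), function(g) {
    idx <- blocks[[g]]
    row <- if (length(idx) < 2) {
      warning("group '", g, "' has fewer than 2 samples; statistics NA")
      empty_diversity_row(length(idx))
    } else {
      diversity_row(subset_alignment(aln, idx))
    }
    cbind(group = g, row)
  })
  do.call(rbind, rows)
}
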