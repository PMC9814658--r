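# Permutation test for diversity change between sample groups, Fisher's
# exact test on 2 x k contingency tables, and the bootstrap-subsampled
# Fisher test for temporal change in clade frequencies.

#' Permutation test for a difference in nucleotide diversity
#'
#' Observed statistic: `|pi_A - pi_B|`.  The null distribution is built
#' by re-partitioning the pooled samples at random into groups of the
#' original sizes `n_perm` times.  The p-value uses the add-one
#' correction `(1 + exceedances) / (1 + n_perm)` and so is never zero.
#'
#' @param aln a [hap_alignment()].
#' @param group_a,group_b disjoint character vectors of sample ids, each
#'   of size >= 2.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (required).
#' @return list of class `perm_test_result`: `observed`, `pi_a`, `pi_b`,
#'   `n_perm`, `n_exceed`, `p`, `seed`.
#' @export
diversity_permutation_test <- function(aln, group_a, group_b,
                                       n_perm = 10000, seed) {
  stopifnot(inherits(aln, "hap_alignment"), n_perm >= 1)
  if (missing(seed)) stop("`seed` is required")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need at least 2 samples")
  ia <- match(group_a, aln$ids)
  ib <- match(group_b, aln$ids)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in group")

  # canonical pooled order (sorted) and canonical resampled-group size
  # (the smaller group), so the null stream -- and hence p -- is
  # invariant to swapping the group labels
  pool <- sort(c(ia, ib))
  f <- pair_fraction(subset_alignment(aln, pool))
  n <- length(pool)
  na_mask <- is.na(f)
  V <- 1 - diag(n)
  V[na_mask] <- 0
  M <- f
  M[na_mask] <- 0
  diag(M) <- 0

  pi_of <- function(z) {
    den <- as.vector(crossprod(z, V %*% z))
    if (den == 0) return(NA_real_)
    as.vector(crossprod(z, M %*% z)) / den
  }
  zA <- as.numeric(pool %in% ia)
  pi_a <- pi_of(zA)
  pi_b <- pi_of(1 - zA)
  obs <- abs(pi_a - pi_b)

  k <- min(length(ia), length(ib))
  set.seed(seed)
  block <- 500L
  exceed <- 0L
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    ZA <- matrix(0, n, nb)
    for (j in seq_len(nb)) ZA[sample.int(n, k), j] <- 1
    ZB <- 1 - ZA
    qa <- colSums(ZA * (M %*% ZA)) / colSums(ZA * (V %*% ZA))
    qb <- colSums(ZB * (M %*% ZB)) / colSums(ZB * (V %*% ZB))
    exceed <- exceed + sum(abs(qa - qb) >= obs - 1e-12, na.rm = TRUE)
    done <- done + nb
  }
  structure(list(observed = obs, pi_a = pi_a, pi_b = pi_b,
                 n_perm = as.integer(n_perm), n_exceed = as.integer(exceed),
                 p = (1 + exceed) / (1 + n_perm), seed = seed),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: |pi_A - pi_B| = %.6g (pi_A = %.6g, pi_B = %.6g)\n",
    x$observed, x$pi_a, x$pi_b))
  cat(sprintf("p = %.4g (%d permutations, %d exceedances)\n",
              x$p, x$n_perm, x$n_exceed))
  invisible(x)
}

# log point probability of a 2 x k table under fixed margins
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

#' Fisher's exact test for a 2 x k table
#'
#' Two-sided p-value: the total probability, under fixed margins, of
#' tables whose point probability does not exceed that of the observed
#' table.  For `k = 2` the hypergeometric distribution is enumerated
#' exactly; for `k > 2` the same criterion is estimated by Monte Carlo
#' sampling of tables with fixed margins (multivariate hypergeometric,
#' via [stats::r2dtable()]).
#'
#' @param tab 2 x k matrix of nonnegative integer counts; both row sums
#'   must be positive.  All-zero columns are dropped with a warning.
#' @param mc_draws Monte Carlo sample size for `k > 2` (default 1e5).
#' @param seed integer seed, required for `k > 2`.
#' @return list: `p`, `method` ("exact" or "monte-carlo"), `table`.
#' @export
fisher_exact <- function(tab, mc_draws = 1e5, seed = NULL) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) stop("table must have 2 rows")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0)) stop("both row sums must be positive")
  zero_col <- colSums(tab) == 0
  if (any(zero_col)) {
    warning("dropping ", sum(zero_col), " all-zero column(s)")
    tab <- tab[, !zero_col, drop = FALSE]
  }
  k <- ncol(tab)
  if (k < 2)
    return(list(p = 1, method = "degenerate", table = tab))

  if (k == 2) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    x <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(x, r1, r2, c1)
    p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    return(list(p = min(p, 1), method = "exact", table = tab))
  }

  if (is.null(seed)) stop("`seed` is required for Monte Carlo (k > 2)")
  set.seed(seed)
  lp_obs <- log_table_prob(tab)
  sims <- stats::r2dtable(mc_draws, rowSums(tab), colSums(tab))
  lp <- vapply(sims, log_table_prob, numeric(1))
  p <- (1 + sum(lp <= lp_obs + 1e-9)) / (1 + mc_draws)
  list(p = p, method = "monte-carlo", table = tab)
}

#' Bootstrap-subsampled Fisher test for temporal clade-frequency change
#'
#' The modern samples are repeatedly subsampled without replacement down
#' to the number of ancient samples; each bootstrap replicate forms a
#' 2 x k era-by-clade contingency table and computes a Fisher exact
#' p-value.  The full p-value distribution is returned together with its
#' mean and a 2.5-97.5 percentile interval (the aggregation is a
#' documented choice; inspect `$p_values` for alternatives).
#'
#' @param clades named character vector mapping sample id to clade label.
#' @param era named character vector mapping sample id to `"modern"` or
#'   `"ancient"`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed (required).
#' @param mc_draws Monte Carlo draws per Fisher test when k > 2.
#' @return list of class `clade_test_result`: `observed` (full 2 x k
#'   table), `p_values`, `p_mean`, `p_ci`, `subsample_size`, `n_boot`,
#'   `seed`.
#' @export
clade_abundance_test <- function(clades, era, n_boot = 1000, seed,
                                 mc_draws = 1e5) {
  if (missing(seed)) stop("`seed` is required")
  ids <- names(clades)
  if (is.null(ids) || is.null(names(era))) stop("named vectors required")
  era <- era[ids]
  if (anyNA(era)) stop("era missing for some samples")
  anc <- ids[era == "ancient"]
  mod <- ids[era == "modern"]
  n_anc <- length(anc)
  if (n_anc < 1) stop("need at least 1 ancient sample")
  if (length(mod) < n_anc)
    stop("need at least as many modern as ancient samples")

  lev <- sort(unique(clades))
  count_tab <- function(mod_ids) {
    rbind(ancient = table(factor(clades[anc], levels = lev)),
          modern = table(factor(clades[mod_ids], levels = lev)))
  }
  observed <- count_tab(mod)

  set.seed(seed)
  pvals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sub <- mod[sample.int(length(mod), n_anc)]
    tab <- count_tab(sub)
    fisher_seed <- sample.int(.Machine$integer.max, 1)
    pvals[b] <- suppressWarnings(
      fisher_exact(tab, mc_draws = mc_draws, seed = fisher_seed)$p)
  }
  structure(list(observed = observed,
                 p_values = pvals,
                 p_mean = mean(pvals),
                 p_ci = stats::quantile(pvals, c(0.025, 0.975)),
                 subsample_size = n_anc,
                 n_boot = as.integer(n_boot),
                 seed = seed),
            class = "clade_test_result")
}

#' @export
print.clade_test_result <- function(x, ...) {
  cat(sprintf(
    "Clade abundance test: %d bootstraps of %d modern samples\n",
    x$n_boot, x$subsample_size))
  print(x$observed)
  cat(sprintf("mean p = %.4g (95%% interval %.4g - %.4g)\n",
              x$p_mean, x$p_ci[1], x$p_ci[2]))
  invisible(x)
}
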