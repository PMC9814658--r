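# Hierarchical analysis of molecular variance (Excoffier-style) on a
# pairwise nucleotide-difference matrix, with permutation p-values.
#
# The difference-count matrix is used directly as the squared-distance
# matrix: for haplotype data the count of differing sites is a squared
# Euclidean distance in per-site state-indicator space (up to a constant
# factor that cancels from every Phi-statistic).

# block sums B[p,q] = sum of d2 over pairs (i in p, j in q), via rowsum
block_sums <- function(d2, pop) {
  pop <- factor(pop)
  rowsum(t(rowsum(d2, pop, reorder = TRUE)), pop, reorder = TRUE)
}

# one-level decomposition (populations only)
amova_ss_1 <- function(d2, pop) {
  pop <- factor(pop)
  N <- nrow(d2)
  n_p <- as.vector(table(pop))
  P <- nlevels(pop)
  B <- block_sums(d2, pop)
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- sum(diag(B) / (2 * n_p))
  ss_ap <- ss_total - ss_wp
  df_ap <- P - 1
  df_wp <- N - P
  sigma_w <- if (df_wp > 0) ss_wp / df_wp else NA_real_
  n0 <- (N - sum(n_p^2) / N) / df_ap
  sigma_a <- (ss_ap / df_ap - sigma_w) / n0
  tot <- sigma_a + sigma_w
  phi_st <- if (!is.na(tot) && tot > 0) sigma_a / tot else NA_real_
  list(ss = c(among_populations = ss_ap, within_populations = ss_wp,
              total = ss_total),
       df = c(among_populations = df_ap, within_populations = df_wp,
              total = N - 1),
       sigma2 = c(among_populations = sigma_a, within_populations = sigma_w),
       phi = c(phi_st = phi_st))
}

# two-level decomposition (groups / populations / individuals)
amova_ss_2 <- function(d2, pop, grp_of_pop) {
  pop <- factor(pop)
  N <- nrow(d2)
  P <- nlevels(pop)
  n_p <- as.vector(table(pop))
  grp <- factor(grp_of_pop[levels(pop)])
  G <- nlevels(grp)
  n_g <- as.vector(rowsum(n_p, grp))       # samples per group

  B <- block_sums(d2, pop)
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- sum(diag(B) / (2 * n_p))
  Bg <- rowsum(t(rowsum(B, grp)), grp)     # G x G group block sums
  S_g <- diag(as.matrix(Bg))
  ss_wg <- sum(S_g / (2 * n_g))            # within groups (pops + indiv)
  ss_ag <- ss_total - ss_wg
  ss_ap <- ss_wg - ss_wp

  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P

  sumn2_in_g <- as.vector(rowsum(n_p^2, grp))
  n1 <- (N - sum(sumn2_in_g / n_g)) / df_ap
  n2 <- (sum(sumn2_in_g / n_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag

  sigma_c <- if (df_wp > 0) ss_wp / df_wp else NA_real_
  sigma_b <- (ss_ap / df_ap - sigma_c) / n1
  sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  phi <- c(
    phi_ct = if (!is.na(tot) && tot > 0) sigma_a / tot else NA_real_,
    phi_sc = if (!is.na(sigma_b + sigma_c) && (sigma_b + sigma_c) > 0)
               sigma_b / (sigma_b + sigma_c) else NA_real_,
    phi_st = if (!is.na(tot) && tot > 0)
               (sigma_a + sigma_b) / tot else NA_real_)
  list(ss = c(among_groups = ss_ag, among_populations = ss_ap,
              within_populations = ss_wp, total = ss_total),
       df = c(among_groups = df_ag, among_populations = df_ap,
              within_populations = df_wp, total = N - 1),
       sigma2 = c(among_groups = sigma_a, among_populations = sigma_b,
                  within_populations = sigma_c),
       phi = phi)
}

perm_p <- function(obs, null) {
  if (is.na(obs)) return(NA_real_)
  null <- null[!is.na(null)]
  (1 + sum(null >= obs - 1e-12)) / (1 + length(null))
}

#' Hierarchical AMOVA with permutation p-values
#'
#' Partitions the squared pairwise distances into among-group,
#' among-population-within-group and within-population components and
#' reports the corresponding Phi-statistics.  With no `groups` argument
#' (or a single group) a one-level AMOVA (populations / individuals) is
#' performed.  Null distributions: individuals are permuted among all
#' populations for `phi_st`, individuals among populations within their
#' group for `phi_sc`, and whole populations among groups for `phi_ct`.
#' P-values use the add-one correction, so `p > 0` always.
#'
#' @param d N x N pairwise difference matrix (see
#'   [pairwise_differences()]); row names must be sample ids when
#'   `populations` is a named vector.
#' @param populations factor/character of population labels, either
#'   aligned with the rows of `d` or named by sample id.
#' @param groups optional named vector mapping population label to group
#'   label (the higher hierarchy level).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (required when `n_perm > 0`).
#' @return An object of class `amova_result`: `ss`, `df`, `sigma2`,
#'   `phi`, `p` (per Phi-statistic), `n_perm`.
#' @export
amova <- function(d, populations, groups = NULL, n_perm = 1000, seed = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  N <- nrow(d)
  if (!is.null(names(populations)) && !is.null(rownames(d)))
    populations <- populations[rownames(d)]
  if (length(populations) != N) stop("one population label per sample needed")
  pop <- factor(as.character(populations))
  if (anyNA(pop)) stop("population label missing for some samples")
  d2 <- d
  if (anyNA(d2)) {
    warning("NA distances imputed with the mean over comparable pairs")
    d2[is.na(d2)] <- mean(d2, na.rm = TRUE)
  }

  if (nlevels(pop) < 2) {
    warning("all samples in one population; among-population level collapsed")
    return(structure(list(
      ss = c(within_populations = sum(d2) / (2 * N), total = sum(d2) / (2 * N)),
      df = c(within_populations = N - 1, total = N - 1),
      sigma2 = c(within_populations = sum(d2) / (2 * N) / (N - 1)),
      phi = c(phi_st = NA_real_), p = c(phi_st = NA_real_),
      n_perm = 0L), class = "amova_result"))
  }

  two_level <- FALSE
  if (!is.null(groups)) {
    g <- groups[levels(pop)]
    if (anyNA(g)) stop("group label missing for some populations")
    if (length(unique(g)) >= 2) two_level <- TRUE
    else warning("single group; among-group level collapsed")
  }

  if (two_level) {
    obs <- amova_ss_2(d2, pop, groups)
  } else {
    obs <- amova_ss_1(d2, pop)
  }

  p <- rep(NA_real_, length(obs$phi))
  names(p) <- names(obs$phi)
  if (n_perm >= 1) {
    if (is.null(seed)) stop("`seed` is required when n_perm > 0")
    set.seed(seed)
    null_st <- matrix(NA_real_, n_perm, length(obs$phi))
    colnames(null_st) <- names(obs$phi)
    grp_of_pop <- if (two_level) groups[levels(pop)] else NULL
    for (b in seq_len(n_perm)) {
      pop_perm <- pop[sample.int(N)]      # individuals among all populations
      if (two_level) {
        dec <- amova_ss_2(d2, pop_perm, groups)
        null_st[b, "phi_st"] <- dec$phi["phi_st"]
        # individuals among populations within their group
        idx <- seq_len(N)
        grp_of_ind <- grp_of_pop[as.character(pop)]
        for (gg in unique(grp_of_ind)) {
          w <- which(grp_of_ind == gg)
          idx[w] <- w[sample.int(length(w))]
        }
        dec_sc <- amova_ss_2(d2, pop[idx], groups)
        null_st[b, "phi_sc"] <- dec_sc$phi["phi_sc"]
        # whole populations among groups
        gperm <- stats::setNames(sample(unname(grp_of_pop)), names(grp_of_pop))
        dec_ct <- amova_ss_2(d2, pop, gperm)
        null_st[b, "phi_ct"] <- dec_ct$phi["phi_ct"]
      } else {
        null_st[b, "phi_st"] <- amova_ss_1(d2, pop_perm)$phi["phi_st"]
      }
    }
    for (nm in names(obs$phi)) p[nm] <- perm_p(obs$phi[nm], null_st[, nm])
  }

  structure(c(obs, list(p = p, n_perm = as.integer(n_perm))),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(df = x$df[names(x$ss)], SS = x$ss)
  print(tab)
  cat("\nVariance components:\n")
  print(x$sigma2)
  cat("\nPhi statistics (", x$n_perm, " permutations):\n", sep = "")
  print(rbind(phi = x$phi, p = x$p[names(x$phi)]))
  invisible(x)
}
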