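# Fixture builders and independent brute-force oracles used across the
# suite.  Oracles are deliberately naive (explicit loops, exhaustive
# enumeration) and share no code with the package internals they check.

aln_from_strings <- function(seqs, ids = NULL, meta = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  states <- do.call(rbind, strsplit(toupper(seqs), ""))
  hap_alignment(states, ids, meta = meta)
}

random_alignment <- function(n, L, miss_prob = 0, n_states = 4) {
  bases <- c("A", "C", "G", "T")[seq_len(n_states)]
  m <- matrix(sample(bases, n * L, replace = TRUE), n, L)
  if (miss_prob > 0) {
    miss <- matrix(runif(n * L) < miss_prob, n, L)
    m[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
  }
  hap_alignment(m, paste0("s", seq_len(n)))
}

# naive per-pair loop: per-site difference fraction and per-locus counts
brute_pair_stats <- function(aln) {
  ch <- aln$states
  n <- nrow(ch)
  is_base <- function(x) x %in% c("A", "C", "G", "T")
  frac <- matrix(NA_real_, n, n)
  locus <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { frac[i, j] <- 0; locus[i, j] <- 0; next }
    ok <- is_base(ch[i, ]) & is_base(ch[j, ])
    if (!any(ok)) next
    nd <- sum(ch[i, ok] != ch[j, ok])
    frac[i, j] <- nd / sum(ok)
    locus[i, j] <- nd / sum(ok) * ncol(ch)
  }
  list(frac = frac, locus = locus)
}

brute_pi <- function(aln) {
  f <- brute_pair_stats(aln)$frac
  v <- f[upper.tri(f)]
  mean(v[!is.na(v)])
}

# exhaustive minimum-change score: per site, minimise over all state
# assignments to internal nodes (and over allowed states of missing tips)
brute_fitch_score <- function(tree, profiles) {
  tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nn <- ntip + tree$Nnode
  prof <- profiles[tree$tip.label, , drop = FALSE]
  total <- 0L
  for (s in seq_len(ncol(prof))) {
    allowed <- lapply(seq_len(nn), function(v) {
      if (v > ntip) return(1:4)
      b <- match(prof[v, s], c("A", "C", "G", "T"))
      if (is.na(b)) 1:4 else b
    })
    grid <- expand.grid(allowed)
    changes <- rep(0L, nrow(grid))
    for (e in seq_len(nrow(edge)))
      changes <- changes + (grid[[edge[e, 1]]] != grid[[edge[e, 2]]])
    total <- total + min(changes)
  }
  total
}

# all 2 x 2 tables with the margins of `tab`; two-sided exact p
brute_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  p_obs <- prob(tab[1, 1])
  sum(vapply(xs, function(x) {
    p <- prob(x)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# explicit sums-of-squares AMOVA decomposition (one level), straight
# from the definitional formulas with scalar loops
brute_amova_1 <- function(d2, pop) {
  pop <- as.character(pop)
  N <- nrow(d2)
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  ss_w <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  n_p <- as.vector(table(pop))
  P <- length(n_p)
  ms_a <- (ss_tot - ss_w) / (P - 1)
  ms_w <- ss_w / (N - P)
  n0 <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ms_a - ms_w) / n0
  list(ss_among = ss_tot - ss_w, ss_within = ss_w,
       sigma_a = sigma_a, sigma_w = ms_w,
       phi_st = sigma_a / (sigma_a + ms_w))
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
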