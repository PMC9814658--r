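# Serial-sampling coalescent simulator.  Generative model: two
# mitochondrial clades that diverged `split_time_years` ago and are
# panmictic (admixed) today; within each clade a haploid coalescent with
# present female effective size proportional to the clade's present-day
# mixture share, exponential growth starting `growth_onset_years` ago
# (constant pre-expansion size further back); tips enter at their
# sampling ages (0 for modern, the site age for ancient samples).
# Mutations are sprinkled as a Poisson process along branches with two
# Jukes-Cantor finite-sites rates: a fast control region and a slower
# rate for the remainder of the molecule.

#' Simulation configuration
#'
#' Defaults emulate the temporal snapper sampling design: 350 modern
#' samples across 10 locations plus 26 ancient samples aged 200-750
#' years; alignment of 16,724 sites whose final ~6% is the fast-evolving
#' control region (5.0e-8 substitutions/site/year, versus 3.28e-9 for
#' the rest); two clades split 650,000 years ago, equally mixed today;
#' exponential expansion beginning 8,000 years ago with a hundred-fold
#' size increase.  The present-day female effective size (4e6 per the
#' two clades combined) is a calibration choice documented in the
#' package vignette; it reproduces nucleotide diversity near 0.005.
#'
#' @param n_modern,n_ancient sample counts per era.
#' @param ancient_ages ages (years) of the ancient samples; `NULL` draws
#'   them uniformly in `[200, 750]` at simulation time.
#' @param L alignment length (sites).
#' @param cr_interval integer vector `c(first, last)` (1-based, inclusive)
#'   delimiting the control region; `NULL` uses the final 6% of sites.
#' @param mu_body,mu_cr substitution rates (per site per year).
#' @param N0_f present-day female effective population size (both clades
#'   combined; each clade gets its mixture share).
#' @param growth_rate exponential growth rate per year (0 = constant
#'   size).  The default corresponds to a 100-fold increase since
#'   `growth_onset_years`.
#' @param growth_onset_years time (years ago) expansion began; earlier
#'   than this the size is constant at the pre-expansion value.
#' @param split_time_years clade divergence time (years ago); `NA` or
#'   `clade_mix` of 0/1 gives a single clade.
#' @param clade_mix present-day proportion of clade I.
#' @param generation_time_years scaling of coalescent time units.
#' @param n_locations number of modern sampling locations.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_modern = 350, n_ancient = 26,
                       ancient_ages = NULL,
                       L = 16724, cr_interval = NULL,
                       mu_body = 3.28e-9, mu_cr = 5.0e-8,
                       N0_f = 4e6,
                       growth_rate = log(100) / 8000,
                       growth_onset_years = 8000,
                       split_time_years = 650000,
                       clade_mix = 0.5,
                       generation_time_years = 1,
                       n_locations = 10) {
  if (is.null(cr_interval)) {
    cr_len <- max(1L, round(0.06 * L))
    cr_interval <- c(L - cr_len + 1L, L)
  }
  cfg <- list(n_modern = as.integer(n_modern),
              n_ancient = as.integer(n_ancient),
              ancient_ages = ancient_ages,
              L = as.integer(L),
              cr_interval = as.integer(cr_interval),
              mu_body = mu_body, mu_cr = mu_cr,
              N0_f = N0_f,
              growth_rate = growth_rate,
              growth_onset_years = growth_onset_years,
              split_time_years = split_time_years,
              clade_mix = clade_mix,
              generation_time_years = generation_time_years,
              n_locations = as.integer(n_locations))
  with(cfg, {
    stopifnot(n_modern >= 0, n_ancient >= 0, n_modern + n_ancient >= 2,
              L >= 1, mu_body >= 0, mu_cr >= 0, N0_f > 0,
              growth_rate >= 0, growth_onset_years >= 0,
              clade_mix >= 0, clade_mix <= 1,
              generation_time_years > 0, n_locations >= 1,
              cr_interval[1] >= 1, cr_interval[2] <= L,
              cr_interval[1] <= cr_interval[2])
    if (!is.null(ancient_ages))
      stopifnot(length(ancient_ages) == n_ancient, all(ancient_ages >= 0))
  })
  structure(cfg, class = "sim_config")
}

cr_length <- function(cfg) cfg$cr_interval[2] - cfg$cr_interval[1] + 1L

# total locus mutation rate per year
mu_locus <- function(cfg) {
  lcr <- cr_length(cfg)
  cfg$mu_body * (cfg$L - lcr) + cfg$mu_cr * lcr
}

single_clade <- function(cfg) {
  cfg$clade_mix %in% c(0, 1) || is.na(cfg$split_time_years)
}

# Solve for the next coalescence time for k lineages at time t (years
# ago), given the clade's present size N0c.  Haploid maternal scaling:
# each pair coalesces at rate 1/(N(t) * generation_time) per year, so
# E[T2] = N0 * gen for constant size and theta = 2 * N0 * gen * mu.
# Exponential growth phase for t < onset, constant pre-expansion size
# beyond; the cumulative hazard is analytic in both phases.
draw_coal_time <- function(t, k, N0c, g, onset, gen) {
  C <- k * (k - 1) / (2 * gen)
  E <- stats::rexp(1)
  if (g > 0 && t < onset) {
    lambda_to_onset <- C * (exp(g * onset) - exp(g * t)) / (g * N0c)
    if (E <= lambda_to_onset)
      return(log(exp(g * t) + E * g * N0c / C) / g)
    E <- E - lambda_to_onset
    t <- onset
  }
  n_now <- if (g > 0) N0c * exp(-g * min(t, onset)) else N0c
  t + E * n_now / C
}

# serial coalescent for one clade; returns parent/child records
# (columns: child id, parent id) and node ages, or NULL when the clade
# MRCA exceeds `max_depth` (rejection)
coalesce_clade <- function(tip_ids, tip_ages, N0c, g, onset, gen,
                           max_depth, next_node) {
  ord <- order(tip_ages)
  pending <- tip_ids[ord]
  pending_ages <- tip_ages[ord]
  active <- integer(0)
  ages <- stats::setNames(tip_ages, tip_ids)
  parent <- integer(0)
  child <- integer(0)
  t <- pending_ages[1]

  repeat {
    if (length(active) + length(pending) <= 1L) break
    t_next_tip <- if (length(pending)) pending_ages[1] else Inf
    if (length(active) < 2L) {
      # nothing can coalesce; fast-forward to the next tip entry
      t <- t_next_tip
    } else {
      tc <- draw_coal_time(t, length(active), N0c, g, onset, gen)
      if (tc < t_next_tip) {
        if (tc > max_depth) return(NULL)        # rejection: too deep
        pick <- sample.int(length(active), 2L)
        a <- active[pick]
        node <- next_node
        next_node <- next_node + 1L
        ages[as.character(node)] <- tc
        parent <- c(parent, node, node)
        child <- c(child, a)
        active <- c(active[-pick], node)
        t <- tc
        next
      }
      t <- t_next_tip
    }
    enter <- pending_ages <= t + 1e-9
    active <- c(active, pending[enter])
    pending <- pending[!enter]
    pending_ages <- pending_ages[!enter]
  }
  list(parent = parent, child = child, ages = ages,
       root = if (length(active)) active else pending,
       next_node = next_node)
}

#' Simulate a serial-sampling genealogy
#'
#' Backwards-in-time coalescent with heterochronous tips under the
#' configured demography.  The two clade ancestral lineages merge at
#' exactly `split_time_years`; a within-clade genealogy deeper than the
#' split is resampled (rejection; count reported).
#'
#' @param cfg a [sim_config()].
#' @param tip_ages numeric vector of tip sampling ages (years).
#' @param tip_clades integer vector (1 or 2) assigning tips to clades.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream (used internally by [simulate_dataset()]).
#' @return list: `tree` (an [ape::phylo] with `tip.label` `t1..tn` and
#'   branch lengths in years), `node_ages` (named by phylo node number),
#'   `n_rejections`.
#' @export
simulate_genealogy <- function(cfg, tip_ages, tip_clades = NULL,
                               seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tip_ages)
  stopifnot(n >= 2)
  if (is.null(tip_clades)) tip_clades <- rep(1L, n)
  stopifnot(length(tip_clades) == n, all(tip_clades %in% c(1L, 2L)))
  g <- cfg$growth_rate
  onset <- cfg$growth_onset_years
  gen <- cfg$generation_time_years
  split <- cfg$split_time_years
  two <- length(unique(tip_clades)) == 2L
  if (two && (is.na(split) || is.null(split)))
    stop("two clades sampled but no split_time_years configured")

  n_rej <- 0L
  repeat {
    next_node <- n + 1L
    parent <- integer(0); child <- integer(0)
    ages <- stats::setNames(tip_ages, seq_len(n))
    roots <- integer(0)
    ok <- TRUE
    for (cl in sort(unique(tip_clades))) {
      idx <- which(tip_clades == cl)
      share <- if (!two) 1 else if (cl == 1L) cfg$clade_mix else 1 - cfg$clade_mix
      N0c <- cfg$N0_f * share
      max_depth <- if (two) split else Inf
      if (length(idx) == 1L) {
        roots <- c(roots, idx)
        next
      }
      res <- coalesce_clade(idx, tip_ages[idx], N0c, g, onset, gen,
                            max_depth, next_node)
      if (is.null(res)) { ok <- FALSE; break }
      parent <- c(parent, res$parent)
      child <- c(child, res$child)
      ages[names(res$ages)] <- res$ages
      roots <- c(roots, res$root)
      next_node <- res$next_node
    }
    if (ok) break
    n_rej <- n_rej + 1L
    if (n_rej > 10000L) stop("rejection rate too high; check split time")
  }

  if (length(roots) == 2L) {
    node <- next_node
    ages[as.character(node)] <- split
    parent <- c(parent, node, node)
    child <- c(child, roots)
    root_id <- node
  } else root_id <- roots

  # renumber: tips 1..n keep ids; internals sorted by decreasing age so
  # the root becomes n+1 (ape convention)
  internal <- sort(unique(parent))
  ord <- internal[order(-ages[as.character(internal)])]
  newid <- stats::setNames(seq_along(ord) + n, ord)
  remap <- function(x) ifelse(x > n, newid[as.character(x)], x)
  edge <- cbind(remap(parent), remap(child))
  storage.mode(edge) <- "integer"
  node_ages <- c(ages[as.character(seq_len(n))],
                 stats::setNames(ages[as.character(ord)], seq_along(ord) + n))
  edge_len <- node_ages[as.character(edge[, 1])] -
    node_ages[as.character(edge[, 2])]
  tree <- structure(list(edge = edge,
                         edge.length = unname(edge_len),
                         tip.label = paste0("t", seq_len(n)),
                         Nnode = length(ord)),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree, node_ages = node_ages, n_rejections = n_rej)
}

#' Sprinkle mutations along a time-scaled tree
#'
#' Poisson number of mutations per branch (rate = branch duration in
#' years times the summed per-partition locus rates); each mutation
#' picks a partition with probability proportional to its total rate, a
#' site uniformly within the partition, and a Jukes-Cantor state change
#' (any of the three other bases, uniformly).  Finite sites: repeat hits
#' are allowed.  The root sequence is uniform random.
#'
#' @param tree [ape::phylo] with branch lengths in years.
#' @param cfg a [sim_config()] (supplies `L`, the control-region
#'   interval and the two rates).
#' @param seed optional integer seed (`NULL` continues the RNG stream).
#' @param tip_ids optional sample ids for the alignment rows (defaults
#'   to the tree tip labels).
#' @return a [hap_alignment()] of the tip sequences.
#' @export
sprinkle_mutations <- function(tree, cfg, seed = NULL, tip_ids = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$L
  lcr <- cr_length(cfg)
  cr_sites <- cfg$cr_interval[1]:cfg$cr_interval[2]
  body_sites <- setdiff(seq_len(L), cr_sites)
  nbody <- length(body_sites)
  rate_cr <- cfg$mu_cr * lcr
  rate_body <- cfg$mu_body * nbody
  rate_tot <- rate_cr + rate_body

  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  edge <- tree$edge
  elen <- tree$edge.length
  ntip <- length(tree$tip.label)
  nnode_all <- ntip + tree$Nnode

  root_seq <- sample.int(4L, L, replace = TRUE)
  # per node: named integer vector of sites whose state differs from the
  # root sequence (repeat hits overwrite, so finite-sites by construction)
  maps <- vector("list", nnode_all)
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  maps[[root]] <- stats::setNames(integer(0), character(0))

  for (i in seq_len(nrow(edge))) {
    m <- maps[[edge[i, 1]]]
    nm <- stats::rpois(1L, elen[i] * rate_tot)
    if (nm > 0L) {
      in_cr <- stats::runif(nm) < rate_cr / rate_tot
      sites <- integer(nm)
      if (any(in_cr))
        sites[in_cr] <- cr_sites[sample.int(lcr, sum(in_cr), replace = TRUE)]
      if (any(!in_cr))
        sites[!in_cr] <- body_sites[sample.int(nbody, sum(!in_cr),
                                               replace = TRUE)]
      for (s in sites) {
        key <- as.character(s)
        cur <- m[key]
        if (is.na(cur)) cur <- root_seq[s]
        m[key] <- (1:4)[-cur][sample.int(3L, 1L)]
      }
    }
    maps[[edge[i, 2]]] <- m
  }

  states <- matrix(BASES[root_seq], ntip, L, byrow = TRUE)
  for (t in seq_len(ntip)) {
    m <- maps[[t]]
    if (length(m)) states[t, as.integer(names(m))] <- BASES[m]
  }
  ids <- if (is.null(tip_ids)) tree$tip.label else tip_ids
  hap_alignment(states, ids)
}

#' Simulate a complete temporal dataset
#'
#' Draws the sampling design (eras, ages, locations, true clade labels),
#' simulates the serial-coalescent genealogy and the mutation process,
#' and returns alignment, metadata and ground truth together.  All
#' randomness flows from `seed`, so reruns are bit-reproducible.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (required).
#' @return list of class `sim_dataset`: `alignment` (a
#'   [hap_alignment()] with metadata attached), `metadata`, `truth`
#'   (data frame `sample_id`, `clade`, `age_years`), `tree`,
#'   `node_ages`, `n_rejections`, `config`.
#' @export
simulate_dataset <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  n <- cfg$n_modern + cfg$n_ancient
  ids <- c(sprintf("M%03d", seq_len(cfg$n_modern)),
           sprintf("A%03d", seq_len(cfg$n_ancient)))
  era <- rep(c("modern", "ancient"), c(cfg$n_modern, cfg$n_ancient))
  ages <- numeric(n)
  if (cfg$n_ancient > 0) {
    anc_ages <- if (is.null(cfg$ancient_ages))
      round(stats::runif(cfg$n_ancient, 200, 750)) else cfg$ancient_ages
    ages[era == "ancient"] <- anc_ages
  }
  locations <- paste0("L", sprintf("%02d", seq_len(cfg$n_locations)))
  loc <- sample(locations, n, replace = TRUE)
  clade <- if (single_clade(cfg)) rep(1L, n) else
    ifelse(stats::runif(n) < cfg$clade_mix, 1L, 2L)
  # guard against an empty clade in tiny designs
  if (!single_clade(cfg) && length(unique(clade)) == 1L)
    clade[1] <- 3L - clade[1]

  sim <- simulate_genealogy(cfg, tip_ages = ages, tip_clades = clade)
  aln <- sprinkle_mutations(sim$tree, cfg, tip_ids = ids)
  meta <- data.frame(sample_id = ids, location = loc, era = era,
                     age_years = ages, stringsAsFactors = FALSE)
  aln <- attach_metadata(aln, meta)
  truth <- data.frame(sample_id = ids,
                      clade = paste0("clade_", clade),
                      age_years = ages, stringsAsFactors = FALSE)
  structure(list(alignment = aln, metadata = meta, truth = truth,
                 tree = sim$tree, node_ages = sim$node_ages,
                 n_rejections = sim$n_rejections, config = cfg,
                 seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d modern + %d ancient samples, L = %d (seed %d)\n",
              x$config$n_modern, x$config$n_ancient, x$config$L, x$seed))
  invisible(x)
}

#' Analytic expectations for constant-size, single-clade configurations
#'
#' Under the haploid (maternal) coalescent with constant female size,
#' `theta = 2 * N0_f * generation_time * locus_rate`; the expected
#' number of segregating sites for `n` contemporaneous samples is
#' `theta * a1(n)` and expected per-site nucleotide diversity is
#' `theta / L`.  Used to validate the simulator.
#'
#' @param cfg a [sim_config()] with `growth_rate = 0` and a single clade.
#' @param n sample size the expectation refers to (default
#'   `n_modern + n_ancient`).
#' @return list: `theta` (per locus), `E_S`, `E_pi_site`.
#' @export
expected_summaries <- function(cfg, n = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$growth_rate > 0 || !single_clade(cfg))
    stop("analytic expectations require a constant-size single-clade config")
  if (is.null(n)) n <- cfg$n_modern + cfg$n_ancient
  theta <- 2 * cfg$N0_f * cfg$generation_time_years * mu_locus(cfg)
  list(theta = theta,
       E_S = theta * sum(1 / seq_len(n - 1)),
       E_pi_site = theta / cfg$L)
}
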