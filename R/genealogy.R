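# Haplotype genealogy via Fitch parsimony.  Given a tree over haplotype
# representatives and their sequences, ancestral states are reconstructed
# by the two-pass Fitch algorithm; zero-change edges are contracted so
# that internal nodes reconstructed identical to a sampled haplotype
# merge with it, and edges carrying m > 1 changes are expanded through
# m - 1 unsampled intermediate nodes, so every edge of the final graph
# represents exactly one nucleotide change.

BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
LOWBIT_BASE <- integer(15)   # lowest set bit -> base index 1..4
for (.b in 15:1) for (.s in 4:1)
  if (bitwAnd(.b, BITS[.s]) > 0L) LOWBIT_BASE[.b] <- .s
rm(.b, .s)

#' Neighbor-joining tree from a distance matrix
#'
#' Fallback tree builder (via [ape::nj()]) for when no externally
#' estimated tree is supplied.
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @return An unrooted [ape::phylo] tree; for fewer than 3 taxa a trivial
#'   star tree is returned with a warning.
#' @export
build_nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (anyNA(d)) {
    warning("NA distances imputed with the mean over comparable pairs")
    d[is.na(d)] <- mean(d, na.rm = TRUE)
  }
  if (nrow(d) < 3) {
    warning("fewer than 3 taxa; returning trivial tree")
    lab <- rownames(d)
    return(ape::read.tree(text = paste0("(", paste(lab, collapse = ","), ");")))
  }
  ape::nj(stats::as.dist(d))
}

# state sets as bitmasks; missing/ambiguous -> full set {A,C,G,T}
profile_bits <- function(profile_chr) {
  b <- BITS[profile_chr]
  b[is.na(b)] <- 15L
  dim(b) <- dim(profile_chr)
  rownames(b) <- rownames(profile_chr)
  b
}

#' Fitch parsimony reconstruction
#'
#' Two-pass Fitch algorithm on a (rooted, binary) tree: the bottom-up
#' pass forms each node's state set as the intersection of its
#' children's sets when nonempty, else their union with one change
#' counted; the top-down pass resolves every node to a single state (the
#' parent's state when it is in the node's set, else the
#' lexicographically smallest member).  Polytomies are resolved to an
#' arbitrary binary form first; unrooted trees are rooted internally
#' (the parsimony score is invariant to both).  Missing tip states
#' contribute the full state set.
#'
#' @param tree [ape::phylo] whose tip labels match `rownames(profiles)`.
#' @param profiles character matrix of tip sequences (rows = tips).
#' @return list: `score` (parsimony score), `resolved` (node x site
#'   matrix of base indices 1-4, tips first in tree order), `tree` (the
#'   binary rooted tree actually used).
#' @export
fitch_reconstruct <- function(tree, profiles) {
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(tree$tip.label, rownames(profiles))
  if (length(missing_tips))
    stop("no sequence for tip(s): ", paste(missing_tips, collapse = ", "))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- ncol(profiles)
  sets <- matrix(0L, ntip + nnode, L)
  sets[seq_len(ntip), ] <- profile_bits(profiles)[tree$tip.label, , drop = FALSE]

  edge <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(edge[, 2L], edge[, 1L])
  # unique parents in postorder edge order = valid bottom-up node order
  changes <- 0L
  for (par in unique(edge[, 1L])) {
    cs <- kids[[as.character(par)]]
    stopifnot(length(cs) == 2L)
    c1 <- sets[cs[1L], ]
    c2 <- sets[cs[2L], ]
    inter <- bitwAnd(c1, c2)
    empty <- inter == 0L
    if (any(empty)) {
      inter[empty] <- bitwOr(c1, c2)[empty]
      changes <- changes + sum(empty)
    }
    sets[par, ] <- inter
  }

  resolved <- matrix(0L, ntip + nnode, L)
  root <- ntip + 1L
  resolved[root, ] <- LOWBIT_BASE[sets[root, ]]
  pre <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1L]; child <- pre[i, 2L]
    pstate_bit <- BITS[resolved[par, ]]
    keep <- bitwAnd(sets[child, ], pstate_bit) > 0L
    res <- integer(L)
    res[keep] <- resolved[par, keep]
    res[!keep] <- LOWBIT_BASE[sets[child, !keep]]
    resolved[child, ] <- res
  }
  list(score = changes, resolved = resolved, tree = tree)
}

#' Build a haplotype genealogy graph
#'
#' Collapses the alignment into haplotypes, reconstructs ancestral
#' sequences on the tree by Fitch parsimony, merges internal nodes whose
#' reconstruction equals a sampled haplotype, and expands multi-change
#' edges through unsampled intermediate nodes so that each edge is one
#' nucleotide change.  Node annotations carry haplotype multiplicity and
#' era/location composition for downstream summaries.
#'
#' @param tree [ape::phylo] over haplotype representatives or over all
#'   samples (auto-collapsed: extra tips of a haplotype are dropped).
#' @param aln a [hap_alignment()].
#' @return object of class `genealogy`: `graph` (igraph), `score`
#'   (parsimony score, equal to the edge count), `ht` (the `hap_table`),
#'   `tree_source` (label describing the tree used).
#' @export
build_haplotype_genealogy <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "hap_alignment"))
  ht <- collapse_haplotypes(aln)
  hap_names <- paste0("H", seq_len(ht$Nh))
  reps <- vapply(ht$members, `[`, character(1), 1L)   # representative id

  if (all(tree$tip.label %in% reps)) {
    tip_map <- stats::setNames(hap_names[match(tree$tip.label, reps)],
                               tree$tip.label)
  } else if (all(tree$tip.label %in% aln$ids)) {
    hap_of_tip <- ht$assignment[match(tree$tip.label, aln$ids)]
    keep_first <- !duplicated(hap_of_tip)
    if (sum(keep_first) < ht$Nh)
      stop("tree does not cover all haplotypes")
    if (any(!keep_first))
      tree <- ape::drop.tip(tree, tree$tip.label[!keep_first])
    hap_of_tip <- ht$assignment[match(tree$tip.label, aln$ids)]
    tip_map <- stats::setNames(hap_names[hap_of_tip], tree$tip.label)
  } else {
    stop("tree tips match neither haplotype representatives nor sample ids")
  }
  profiles <- ht$profile
  rownames(profiles) <- hap_names
  tree$tip.label <- unname(tip_map[tree$tip.label])

  if (ht$Nh == 1L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, 1, name = "H1", type = "haplotype")
    g <- annotate_genealogy(g, ht, hap_names, aln)
    return(structure(list(graph = g, score = 0L, ht = ht,
                          tree_source = "input"), class = "genealogy"))
  }
  if (ht$Nh == 2L) {
    # degenerate: two haplotypes on a path; no reconstruction needed
    fit <- list(score = sum(profiles[1, ] != profiles[2, ] &
                              profiles[1, ] %in% BASES &
                              profiles[2, ] %in% BASES),
                resolved = NULL)
    g <- path_graph_two(profiles, hap_names)
    g <- annotate_genealogy(g, ht, hap_names, aln)
    return(structure(list(graph = g, score = fit$score, ht = ht,
                          tree_source = "input"), class = "genealogy"))
  }

  fit <- fitch_reconstruct(tree, profiles)
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  nnode_all <- ntip + tree$Nnode
  res <- fit$resolved

  # contract zero-change edges (union-find; tips win as representatives)
  parent_uf <- seq_len(nnode_all)
  find <- function(x) { while (parent_uf[x] != x) x <- parent_uf[x]; x }
  edge <- tree$edge
  echg <- integer(nrow(edge))
  for (i in seq_len(nrow(edge)))
    echg[i] <- sum(res[edge[i, 1L], ] != res[edge[i, 2L], ])
  for (i in which(echg == 0L)) {
    a <- find(edge[i, 1L]); b <- find(edge[i, 2L])
    if (a != b) {
      # keep the tip (haplotype) as the representative if present
      if (b <= ntip) { tmp <- a; a <- b; b <- tmp }
      parent_uf[b] <- a
    }
  }
  comp <- vapply(seq_len(nnode_all), find, integer(1))

  node_name <- character(nnode_all)
  node_name[seq_len(ntip)] <- tree$tip.label
  inf_counter <- 0L
  for (v in unique(comp)) {
    if (v > ntip) {
      inf_counter <- inf_counter + 1L
      node_name[v] <- paste0("anc", inf_counter)
    }
  }

  verts <- unique(comp)
  vnames <- node_name[verts]
  vtype <- ifelse(verts <= ntip, "haplotype", "inferred")
  edges_from <- character(0); edges_to <- character(0)
  e_site <- integer(0); e_from <- character(0); e_to <- character(0)
  extra_names <- character(0)
  int_counter <- 0L
  for (i in which(echg > 0L)) {
    a <- comp[edge[i, 1L]]; b <- comp[edge[i, 2L]]
    sa <- res[a, ]; sb <- res[b, ]
    diff_sites <- which(sa != sb)
    m <- length(diff_sites)
    path_nodes <- node_name[a]
    if (m > 1L) {
      new_int <- paste0("i", int_counter + seq_len(m - 1L))
      int_counter <- int_counter + m - 1L
      extra_names <- c(extra_names, new_int)
      path_nodes <- c(path_nodes, new_int)
    }
    path_nodes <- c(path_nodes, node_name[b])
    for (s in seq_len(m)) {
      edges_from <- c(edges_from, path_nodes[s])
      edges_to <- c(edges_to, path_nodes[s + 1L])
      e_site <- c(e_site, diff_sites[s])
      e_from <- c(e_from, BASES[sa[diff_sites[s]]])
      e_to <- c(e_to, BASES[sb[diff_sites[s]]])
    }
  }

  all_names <- c(vnames, extra_names)
  all_types <- c(vtype, rep("intermediate", length(extra_names)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_from, to = edges_to,
               site = e_site, from_state = e_from, to_state = e_to,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_names, type = all_types,
                          stringsAsFactors = FALSE))
  g <- annotate_genealogy(g, ht, hap_names, aln)
  structure(list(graph = g, score = fit$score, ht = ht,
                 tree_source = "input"),
            class = "genealogy")
}

# two haplotypes joined by a path of single-change edges
path_graph_two <- function(profiles, hap_names) {
  p1 <- profiles[1, ]; p2 <- profiles[2, ]
  comparable <- p1 %in% BASES & p2 %in% BASES
  diff_sites <- which(comparable & p1 != p2)
  m <- length(diff_sites)
  if (m == 0L) stop("distinct haplotypes with no resolvable difference")
  nodes <- c(hap_names[1],
             if (m > 1) paste0("i", seq_len(m - 1L)),
             hap_names[2])
  igraph::graph_from_data_frame(
    data.frame(from = nodes[-length(nodes)], to = nodes[-1],
               site = diff_sites,
               from_state = p1[diff_sites], to_state = p2[diff_sites],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = nodes,
      type = c("haplotype", rep("intermediate", max(0L, m - 1L)),
               "haplotype"),
      stringsAsFactors = FALSE))
}

annotate_genealogy <- function(g, ht, hap_names, aln) {
  vn <- igraph::V(g)$name
  mult <- integer(length(vn)); mult[] <- 0L
  samples <- character(length(vn)); samples[] <- ""
  n_modern <- integer(length(vn)); n_ancient <- integer(length(vn))
  locs <- character(length(vn)); locs[] <- ""
  for (k in seq_along(hap_names)) {
    i <- match(hap_names[k], vn)
    if (is.na(i)) next
    ids <- ht$members[[k]]
    mult[i] <- length(ids)
    samples[i] <- paste(ids, collapse = ",")
    if (!is.null(aln$meta)) {
      mm <- aln$meta[match(ids, aln$meta$sample_id), , drop = FALSE]
      n_modern[i] <- sum(mm$era == "modern")
      n_ancient[i] <- sum(mm$era == "ancient")
      lt <- table(mm$location)
      locs[i] <- paste(sprintf("%s:%d", names(lt), lt), collapse = ",")
    }
  }
  g <- igraph::set_vertex_attr(g, "multiplicity", value = mult)
  g <- igraph::set_vertex_attr(g, "samples", value = samples)
  g <- igraph::set_vertex_attr(g, "n_modern", value = n_modern)
  g <- igraph::set_vertex_attr(g, "n_ancient", value = n_ancient)
  g <- igraph::set_vertex_attr(g, "locations", value = locs)
  g
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf(
    "<genealogy> %d haplotype nodes, %d total nodes, %d edges (parsimony score %d)\n",
    sum(igraph::V(x$graph)$type == "haplotype"),
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$score))
  invisible(x)
}

#' Assign samples to clades by cutting long mutational paths
#'
#' Every maximal path of unsampled degree-2 nodes carrying at least
#' `min_cut_changes` nucleotide changes is removed from the genealogy;
#' the remaining connected components define the clades, and samples
#' inherit the clade of their haplotype.  `min_cut_changes = "auto"`
#' uses the longest such path in the graph, so a single dominant deep
#' split yields exactly two clades.
#'
#' @param gen a `genealogy` from [build_haplotype_genealogy()].
#' @param min_cut_changes positive integer threshold, or `"auto"`.
#' @return list of class `clade_assignment`: `clades` (named vector
#'   sample id -> clade label, labels ordered by decreasing clade size),
#'   `haplotype_clades`, `threshold`, `n_clades`.
#' @export
assign_clades <- function(gen, min_cut_changes = "auto") {
  stopifnot(inherits(gen, "genealogy"))
  g <- gen$graph
  vn <- igraph::V(g)$name
  vtype <- igraph::V(g)$type
  deg <- igraph::degree(g)
  interior <- vtype != "haplotype" & deg == 2

  # maximal chains: connected components of the interior-node subgraph
  chains <- list()
  if (any(interior)) {
    sub <- igraph::induced_subgraph(g, which(interior))
    cc <- igraph::components(sub)
    for (ci in seq_len(cc$no)) {
      mem <- igraph::V(sub)$name[cc$membership == ci]
      chains[[length(chains) + 1L]] <-
        list(interior = mem, len = length(mem) + 1L)
    }
  }
  # direct edges between non-interior nodes are chains of length 1
  el <- igraph::as_edgelist(g)
  direct <- !(el[, 1] %in% vn[interior]) & !(el[, 2] %in% vn[interior])
  chain_lens <- c(vapply(chains, `[[`, integer(1), "len"),
                  rep(1L, sum(direct)))

  if (identical(min_cut_changes, "auto")) {
    if (!length(chain_lens)) {
      threshold <- 1L
    } else threshold <- max(chain_lens)
  } else {
    threshold <- as.integer(min_cut_changes)
    stopifnot(threshold >= 1)
  }

  gcut <- g
  drop_v <- character(0)
  for (ch in chains) if (ch$len >= threshold)
    drop_v <- c(drop_v, ch$interior)
  drop_e <- if (threshold <= 1L) which(direct) else integer(0)
  if (length(drop_e)) gcut <- igraph::delete_edges(gcut, drop_e)
  if (length(drop_v)) gcut <- igraph::delete_vertices(gcut, drop_v)

  if (length(chain_lens) && max(chain_lens) < threshold)
    message("no path reaches the cut threshold; single clade returned")

  cc <- igraph::components(gcut)
  memb <- stats::setNames(cc$membership, igraph::V(gcut)$name)
  hap_v <- vn[vtype == "haplotype"]
  hap_comp <- memb[hap_v]

  # clade labels ordered by decreasing number of samples
  mult <- stats::setNames(igraph::V(g)$multiplicity, vn)[hap_v]
  sizes <- rowsum(as.numeric(mult), hap_comp)
  ord <- order(-sizes[, 1])
  relabel <- stats::setNames(paste0("clade_", seq_along(ord)),
                             rownames(sizes)[ord])
  hap_clade <- relabel[as.character(hap_comp)]
  names(hap_clade) <- hap_v

  samples <- stats::setNames(igraph::V(g)$samples, vn)[hap_v]
  sample_clade <- character(0)
  for (hv in hap_v) {
    ids <- strsplit(samples[hv], ",", fixed = TRUE)[[1]]
    sample_clade[ids] <- hap_clade[hv]
  }
  structure(list(clades = sample_clade,
                 haplotype_clades = hap_clade,
                 threshold = threshold,
                 n_clades = length(unique(hap_clade))),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("<clade_assignment> %d clades (cut threshold %d changes)\n",
              x$n_clades, x$threshold))
  print(table(x$clades))
  invisible(x)
}

#' Export a genealogy graph
#'
#' Writes the genealogy as GraphML (primary) and optionally DOT, with
#' node attributes `type`, `multiplicity`, `n_modern`, `n_ancient`,
#' `locations`.
#'
#' @param gen a `genealogy`.
#' @param graphml_path output GraphML path (or `NULL` to skip).
#' @param dot_path output DOT path (or `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_genealogy <- function(gen, graphml_path = NULL, dot_path = NULL) {
  stopifnot(inherits(gen, "genealogy"))
  if (!is.null(graphml_path))
    igraph::write_graph(gen$graph, graphml_path, format = "graphml")
  if (!is.null(dot_path))
    igraph::write_graph(gen$graph, dot_path, format = "dot")
  invisible(c(graphml_path, dot_path))
}
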