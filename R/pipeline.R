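# End-to-end orchestration: input (real files or simulation) -> haplotype
# collapse -> diversity panel -> distances -> tree/genealogy/clades ->
# structure tests -> report bundle on disk.
#
# Reproducibility: one global seed; each stochastic stage derives its own
# seed as a deterministic hash of (global seed, stage name), so streams
# never overlap and toggling one stage cannot shift another's results.

#' Derive a per-stage seed from the global seed
#'
#' Deterministic fold of the stage name into the global seed, modulo
#' 2^31 - 1 (a distinct stream per stage without shared state).
#'
#' @param global_seed integer.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- as.double(global_seed %% 2147483647)
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Pipeline configuration
#'
#' Exactly one of `alignment_path` (optionally with `metadata_path`) or
#' `sim` must be
#' given.  Analysis toggles default to on; procedural constants default
#' to 10,000 permutations for the diversity permutation test, 1,000 for
#' the AMOVA and 1,000 bootstrap replicates for the clade-frequency test.
#'
#' @param alignment_path,metadata_path,tree_path input file paths
#'   (FASTA, TSV, newick).  `tree_path` is optional: without it a
#'   neighbor-joining tree is built from the pairwise differences and
#'   labeled as such in the manifest.
#' @param sim a [sim_config()] to simulate the input instead.
#' @param run_stats,run_amova,run_permtest,run_cladetest,run_genealogy,run_rarefaction
#'   stage toggles.
#' @param n_perm,n_amova_perm,n_boot,rarefaction_reps replicate counts.
#' @param min_cut_changes clade cut threshold (integer or `"auto"`).
#' @param amova_groups optional named vector mapping population
#'   (location) to a higher-level group for the hierarchical AMOVA.
#' @param seed global integer seed (required).
#' @param out_dir output directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment_path = NULL, metadata_path = NULL,
                            tree_path = NULL, sim = NULL,
                            run_stats = TRUE, run_amova = TRUE,
                            run_permtest = TRUE, run_cladetest = TRUE,
                            run_genealogy = TRUE, run_rarefaction = TRUE,
                            n_perm = 10000, n_amova_perm = 1000,
                            n_boot = 1000, rarefaction_reps = 1000,
                            min_cut_changes = "auto",
                            amova_groups = NULL,
                            seed, out_dir) {
  if (missing(seed)) stop("`seed` is required")
  if (missing(out_dir)) stop("`out_dir` is required")
  has_files <- !is.null(alignment_path)
  has_sim <- !is.null(sim)
  if (has_files == has_sim)
    stop("exactly one of `alignment_path` or `sim` must be given")
  if (has_sim) stopifnot(inherits(sim, "sim_config"))
  stopifnot(n_perm >= 1, n_amova_perm >= 1, n_boot >= 1,
            rarefaction_reps >= 1)
  structure(list(alignment_path = alignment_path,
                 metadata_path = metadata_path,
                 tree_path = tree_path, sim = sim,
                 run_stats = run_stats, run_amova = run_amova,
                 run_permtest = run_permtest,
                 run_cladetest = run_cladetest,
                 run_genealogy = run_genealogy,
                 run_rarefaction = run_rarefaction,
                 n_perm = n_perm, n_amova_perm = n_amova_perm,
                 n_boot = n_boot, rarefaction_reps = rarefaction_reps,
                 min_cut_changes = min_cut_changes,
                 amova_groups = amova_groups,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full analysis pipeline
#'
#' Stages execute in dependency order (io, haplotypes, stats, distances,
#' tree, genealogy, clades, structure tests, rarefaction, report).
#' Failures in optional analysis stages are caught and logged into the
#' manifest; input stages abort.  Given the same configuration and seed
#' the bundle on disk is byte-identical across reruns.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list of class `report_bundle` with the in-memory
#'   results and the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  files <- character(0)
  errors <- list()
  res <- list()
  stage <- function(name, enabled, fn) {
    if (!enabled) return(invisible(NULL))
    r <- tryCatch(fn(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(r)) res[[name]] <<- r
    invisible(r)
  }

  # --- io (mandatory) ---
  if (!is.null(cfg$sim)) {
    ds <- simulate_dataset(cfg$sim, seed = derive_seed(cfg$seed, "simulate"))
    aln <- ds$alignment
    write_alignment(aln, out("alignment.fasta"))
    write_tsv(ds$metadata, out("metadata.tsv"))
    write_tsv(ds$truth, out("truth.tsv"))
    files <- c(files, "alignment.fasta", "metadata.tsv", "truth.tsv")
    res$dataset <- ds
    tree <- NULL
  } else {
    aln <- read_alignment(cfg$alignment_path)
    if (!is.null(cfg$metadata_path))
      aln <- attach_metadata(aln, read_metadata(cfg$metadata_path))
    tree <- if (!is.null(cfg$tree_path)) read_tree(cfg$tree_path) else NULL
  }
  res$alignment <- aln

  ht <- collapse_haplotypes(aln)
  res$haplotypes <- ht

  stage("stats", cfg$run_stats, function() {
    tab <- table1_stats(aln)
    write_tsv(tab, out("stats.tsv"))
    render_table1(tab, out("table1.tsv"))
    files <<- c(files, "stats.tsv", "table1.tsv")
    tab
  })

  d <- pairwise_differences(aln)

  tree_source <- "input"
  if (is.null(tree)) {
    tree <- build_nj_tree(d)
    tree_source <- "neighbor-joining fallback"
  }

  stage("genealogy", cfg$run_genealogy, function() {
    gen <- build_haplotype_genealogy(tree, aln)
    gen$tree_source <- tree_source
    write_genealogy(gen, out("genealogy.graphml"), out("genealogy.dot"))
    cl <- assign_clades(gen, cfg$min_cut_changes)
    write_tsv(data.frame(sample_id = names(cl$clades),
                         clade = unname(cl$clades)),
              out("clades.tsv"))
    files <<- c(files, "genealogy.graphml", "genealogy.dot", "clades.tsv")
    list(genealogy = gen, clades = cl)
  })

  stage("amova", cfg$run_amova, function() {
    if (is.null(aln$meta)) stop("AMOVA needs metadata (locations)")
    pops <- stats::setNames(aln$meta$location, aln$ids)
    am <- amova(d, pops, groups = cfg$amova_groups,
                n_perm = cfg$n_amova_perm,
                seed = derive_seed(cfg$seed, "amova"))
    write_json_report(unclass(am), out("amova.json"))
    files <<- c(files, "amova.json")
    am
  })

  stage("permtest", cfg$run_permtest, function() {
    if (is.null(aln$meta)) stop("permutation test needs metadata (era)")
    a_ids <- aln$ids[aln$meta$era == "modern"]
    b_ids <- aln$ids[aln$meta$era == "ancient"]
    if (length(a_ids) < 2 || length(b_ids) < 2)
      stop("need >= 2 modern and >= 2 ancient samples")
    pt <- diversity_permutation_test(aln, a_ids, b_ids,
                                     n_perm = cfg$n_perm,
                                     seed = derive_seed(cfg$seed, "permtest"))
    write_json_report(unclass(pt), out("permtest.json"))
    files <<- c(files, "permtest.json")
    pt
  })

  stage("cladetest", cfg$run_cladetest, function() {
    if (is.null(res$genealogy)) stop("clade test needs the genealogy stage")
    if (is.null(aln$meta)) stop("clade test needs metadata (era)")
    clades <- res$genealogy$clades$clades
    era <- stats::setNames(aln$meta$era, aln$ids)
    ct <- clade_abundance_test(clades, era, n_boot = cfg$n_boot,
                               seed = derive_seed(cfg$seed, "cladetest"))
    ct_out <- unclass(ct)
    ct_out$observed <- as.data.frame.matrix(ct$observed)
    write_json_report(ct_out, out("cladetest.json"))
    files <<- c(files, "cladetest.json")
    ct
  })

  stage("rarefaction", cfg$run_rarefaction, function() {
    rc <- rarefaction(ht, reps = cfg$rarefaction_reps,
                      seed = derive_seed(cfg$seed, "rarefaction"))
    write_tsv(rc, out("rarefaction.tsv"))
    files <<- c(files, "rarefaction.tsv")
    rc
  })

  manifest <- list(
    package = "mitotempo",
    version = as.character(utils::packageVersion("mitotempo")),
    seed = cfg$seed,
    stage_seeds = lapply(stats::setNames(nm = c("simulate", "amova",
                                                "permtest", "cladetest",
                                                "rarefaction")),
                         function(s) derive_seed(cfg$seed, s)),
    tree_source = tree_source,
    config = config_echo(cfg),
    failed_stages = errors,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, files))), files)))
  write_json_report(manifest, out("manifest.json"))

  invisible(structure(c(res, list(manifest = manifest,
                                  out_dir = cfg$out_dir,
                                  files = c(files, "manifest.json"))),
                      class = "report_bundle"))
}

config_echo <- function(cfg) {
  e <- unclass(cfg)
  e$out_dir <- NULL            # location-independent: reruns elsewhere
  if (!is.null(e$sim)) e$sim <- unclass(e$sim)  # must stay byte-identical
  e[!vapply(e, is.null, logical(1))]
}

# per-location x era diversity rows feeding render_table1
table1_stats <- function(aln) {
  if (is.null(aln$meta)) stop("metadata required for the stats table")
  rows <- list()
  add <- function(group, stratum, idx) {
    row <- if (length(idx) < 2) {
      warning("group '", group, "' (", stratum,
              ") has fewer than 2 samples; statistics NA")
      empty_diversity_row(length(idx))
    } else diversity_row(subset_alignment(aln, idx))
    rows[[length(rows) + 1L]] <<- cbind(group = group, stratum = stratum, row)
  }
  for (loc in sort(unique(aln$meta$location))) {
    im <- which(aln$meta$location == loc & aln$meta$era == "modern")
    ia <- which(aln$meta$location == loc & aln$meta$era == "ancient")
    if (length(im)) add(loc, "modern", im)
    if (length(ia)) add(loc, "ancient", ia)
  }
  add("Modern", "modern", which(aln$meta$era == "modern"))
  if (any(aln$meta$era == "ancient"))
    add("Ancient", "ancient", which(aln$meta$era == "ancient"))
  add("total", "all", seq_len(aln$N))
  do.call(rbind, rows)
}

#' Render the per-population statistics table
#'
#' Formats the diversity panel in the conventional layout for temporal
#' studies: one row per sampling location (modern samples) with the
#' ancient stratum, when present, as a parenthesised sub-row, followed
#' by Modern / Ancient / total rows.  Tajima's D values significant at
#' p < 0.05 are starred.
#'
#' @param tab output of the internal per-location/era panel (a data
#'   frame with `group`, `stratum` and the diversity columns), as
#'   produced inside [run_pipeline()].
#' @param path output TSV path.
#' @return the formatted data frame, invisibly.
#' @export
render_table1 <- function(tab, path = NULL) {
  fmt <- function(x, digits) ifelse(is.na(x), "-",
                                    formatC(x, digits = digits,
                                            format = "fg", flag = "#"))
  star <- ifelse(!is.na(tab$tajima_sig) & tab$tajima_sig, "*", "")
  disp <- data.frame(
    group = tab$group,
    N = as.character(tab$N),
    Np = as.character(tab$Np),
    Nh = as.character(tab$Nh),
    Nm = as.character(tab$Nm),
    pi = fmt(tab$pi, 2),
    h = fmt(tab$h, 3),
    theta_w = fmt(tab$theta_w, 4),
    tajima_d = paste0(fmt(tab$tajima_d, 4), star),
    stringsAsFactors = FALSE)
  anc <- tab$stratum == "ancient" & !(tab$group %in% c("Ancient"))
  brack <- function(v) paste0("(", v, ")")
  disp[anc, -1] <- lapply(disp[anc, -1], brack)
  disp$group[anc] <- ""
  if (!is.null(path)) write_tsv(disp, path)
  invisible(disp)
}
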