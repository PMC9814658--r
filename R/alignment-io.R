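# Alignment container, FASTA/TSV/newick I/O, haplotype collapsing.
#
# Internal representation: a character matrix of uppercase single-letter
# states (rows = samples, columns = sites).  Everything outside {A,C,G,T}
# -- N, the gap "-", and IUPAC ambiguity codes -- is treated as missing
# for all computations, but the original letter is preserved for
# round-trip output.

MISSING_OK <- c("N", "-", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
BASES <- c("A", "C", "G", "T")

#' Construct a haplotype alignment
#'
#' Bundles an equal-length set of mitogenome sequences with optional
#' per-sample metadata. Most users will call [read_alignment()] instead;
#' this constructor is exported for programmatic use (e.g. the simulator).
#'
#' @param states character matrix (samples x sites) of single uppercase
#'   letters from `A,C,G,T`, `N`, `-`, or IUPAC ambiguity codes.
#' @param ids character vector of unique sample identifiers, one per row.
#' @param meta optional data frame of sample metadata (see
#'   [read_metadata()]); joined by `sample_id`.
#' @return An object of class `hap_alignment` with elements `states`,
#'   `ids`, `meta`, `N` (samples) and `L` (sites).
#' @export
hap_alignment <- function(states, ids, meta = NULL) {
  if (!is.matrix(states) || !is.character(states))
    stop("`states` must be a character matrix")
  if (length(ids) != nrow(states))
    stop("`ids` must have one entry per sequence")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  if (any(!nzchar(ids)))
    stop("empty sample id")
  bad <- setdiff(unique(as.vector(states)), c(BASES, MISSING_OK))
  if (length(bad))
    stop("states outside the DNA alphabet: ", paste(bad, collapse = ", "))
  rownames(states) <- ids
  obj <- structure(
    list(states = states, ids = ids, meta = NULL,
         N = nrow(states), L = ncol(states)),
    class = "hap_alignment")
  if (!is.null(meta)) obj <- attach_metadata(obj, meta)
  obj
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d sequences x %d sites", x$N, x$L))
  if (!is.null(x$meta)) {
    tab <- table(x$meta$era)
    cat(sprintf("; eras: %s",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Read a multi-FASTA alignment
#'
#' Sequences are uppercased and validated: all records must have the same
#' length, ids (the first whitespace-delimited token of each header) must
#' be unique, and characters must be DNA bases, `N`, `-`, or IUPAC
#' ambiguity codes.
#'
#' @param path path to a FASTA file with at least two records.
#' @return A [hap_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA: ",
                                           conditionMessage(e)))
  if (length(dss) < 2)
    stop("alignment must contain at least 2 records (found ",
         length(dss), ")")
  w <- Biostrings::width(dss)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(w)), collapse = ", "))
  ids <- vapply(strsplit(names(dss), "\\s+"), `[`, character(1), 1L)
  m <- toupper(as.matrix(dss))
  hap_alignment(m, ids)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_alignment()]: ids, record order and (uppercased)
#' states round-trip exactly.
#'
#' @param aln a [hap_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  seqs <- apply(aln$states, 1L, paste0, collapse = "")
  dss <- Biostrings::BStringSet(seqs)
  names(dss) <- aln$ids
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a tab-separated file with header columns `sample_id`,
#' `location`, `era` and `age_years`.  `era` must be `modern` or
#' `ancient`; modern samples must have `age_years == 0`.
#'
#' @param path path to a TSV file.
#' @return A data frame with the four validated columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("sample_id", "location", "era", "age_years")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$location <- as.character(df$location)
  df$era <- as.character(df$era)
  bad_era <- setdiff(unique(df$era), c("modern", "ancient"))
  if (length(bad_era))
    stop("unknown era value(s): ", paste(bad_era, collapse = ", "),
         " (must be 'modern' or 'ancient')")
  df$age_years <- suppressWarnings(as.numeric(df$age_years))
  if (anyNA(df$age_years) || any(df$age_years < 0))
    stop("age_years must be nonnegative numbers")
  if (any(df$era == "modern" & df$age_years != 0))
    stop("modern samples must have age_years = 0")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  df
}

#' Join metadata onto an alignment
#'
#' @param aln a [hap_alignment()].
#' @param meta a metadata data frame as returned by [read_metadata()].
#' @return The alignment with `$meta` set (rows reordered to match the
#'   alignment).
#' @export
attach_metadata <- function(aln, meta) {
  stopifnot(inherits(aln, "hap_alignment"))
  meta <- validate_metadata(meta)
  idx <- match(aln$ids, meta$sample_id)
  if (anyNA(idx))
    stop("metadata missing for sample(s): ",
         paste(utils::head(aln$ids[is.na(idx)], 5), collapse = ", "))
  aln$meta <- meta[idx, , drop = FALSE]
  rownames(aln$meta) <- NULL
  aln
}

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] with validation; polytomies are
#' preserved.
#'
#' @param path path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: no tree in file")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree")
  tr
}

# integer encoding: A=1 C=2 G=3 T=4, everything else NA
encode_states <- function(aln) {
  m <- match(aln$states, BASES)
  dim(m) <- dim(aln$states)
  rownames(m) <- aln$ids
  m
}

# columns with >= 2 distinct non-missing states (conflicts and pairwise
# differences can only arise here)
variable_sites <- function(int_mat) {
  seen <- matrix(FALSE, 4L, ncol(int_mat))
  for (s in 1:4) seen[s, ] <- colSums(int_mat == s, na.rm = TRUE) > 0L
  which(colSums(seen) >= 2L)
}

#' Collapse an alignment into haplotypes
#'
#' Two sequences share a haplotype when they have no conflicting states
#' at any site where both are non-missing (missing = `N`, `-`, or any
#' ambiguity code).  Because this compatibility relation is intransitive
#' in the presence of missing data, assignment is greedy in input order:
#' each sequence joins the first existing haplotype whose merged profile
#' it is compatible with, otherwise it founds a new haplotype; sites the
#' profile lacks are then filled in from the new member.  With no missing
#' data this reduces to exact sequence identity.
#'
#' @param aln a [hap_alignment()].
#' @return An object of class `hap_table`: `profile` (Nh x L character
#'   matrix of merged representative states, `N` where unresolved),
#'   `members` (list of sample-id vectors), `counts`, `assignment`
#'   (per-sample haplotype index, in alignment order) and `Nh`.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (aln$N < 1) stop("empty alignment")
  im <- encode_states(aln)
  vs <- variable_sites(im)
  v <- im[, vs, drop = FALSE]                  # N x nv
  nv <- length(vs)

  assignment <- integer(aln$N)
  profiles <- matrix(NA_integer_, nrow = 0L, ncol = nv)
  for (i in seq_len(aln$N)) {
    x <- v[i, ]
    hit <- 0L
    if (nrow(profiles) > 0L) {
      if (nv == 0L) {
        hit <- 1L
      } else {
        conflict <- rowSums(sweep(profiles, 2L, x, `!=`) &
                            !is.na(profiles) &
                            rep(!is.na(x), each = nrow(profiles))) > 0L
        ok <- which(!conflict)
        if (length(ok)) hit <- ok[1L]
      }
    }
    if (hit == 0L) {
      profiles <- rbind(profiles, x)
      assignment[i] <- nrow(profiles)
    } else {
      fill <- is.na(profiles[hit, ]) & !is.na(x)
      if (any(fill)) profiles[hit, fill] <- x[fill]
      assignment[i] <- hit
    }
  }

  Nh <- nrow(profiles)
  # full-length representative: site consensus for invariant sites,
  # merged profile at variable sites, "N" where nothing observed
  full <- matrix(NA_integer_, Nh, aln$L)
  if (aln$L > 0) {
    cons <- rep(NA_integer_, aln$L)
    for (s in 1:4) {
      has <- colSums(im == s, na.rm = TRUE) > 0L
      cons[is.na(cons) & has] <- s
    }
    full[] <- rep(cons, each = Nh)
    if (nv) full[, vs] <- profiles
  }
  prof_chr <- matrix("N", Nh, aln$L)
  prof_chr[!is.na(full)] <- BASES[full[!is.na(full)]]

  members <- split(aln$ids, assignment)
  members <- members[order(as.integer(names(members)))]
  names(members) <- NULL
  structure(
    list(profile = prof_chr,
         members = members,
         counts = as.integer(lengths(members)),
         assignment = assignment,
         Nh = Nh,
         N = aln$N,
         L = aln$L),
    class = "hap_table")
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf("<hap_table> %d haplotypes from %d samples (%d sites)\n",
              x$Nh, x$N, x$L))
  invisible(x)
}
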