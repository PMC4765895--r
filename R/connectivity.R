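#' Construct a set of drug-induced gene rank profiles
#'
#' A rank profile is one drug-treatment instance: a permutation of the
#' gene universe where rank 1 is the gene most up-regulated by the drug
#' and rank `n` the most down-regulated.  (Use [invert_rank_profiles()]
#' for data recorded with the opposite orientation.)
#'
#' @param rank Integer matrix, genes in rows and instances in columns;
#'   every column must be a permutation of `1..nrow(rank)`.
#' @param meta Data frame with columns `instance_id`, `drug_id`,
#'   `cell_line`, one row per column of `rank`, in the same order.
#' @return An object of class `"rank_profiles"`.
#' @export
rank_profiles <- function(rank, meta) {
  if (!is.matrix(rank) || is.null(rownames(rank)))
    stop("'rank' must be a matrix with gene row names", call. = FALSE)
  req <- c("instance_id", "drug_id", "cell_line")
  if (!is.data.frame(meta) || !all(req %in% names(meta)))
    stop("'meta' must contain columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(meta) != ncol(rank))
    stop("meta rows (", nrow(meta), ") != rank columns (", ncol(rank), ")",
         call. = FALSE)
  n <- nrow(rank)
  expected <- n * (n + 1) / 2
  bad <- which(colSums(rank) != expected |
                 apply(rank, 2L, anyDuplicated) > 0L)
  if (length(bad))
    stop("column(s) not a permutation of 1..n: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  colnames(rank) <- meta$instance_id
  structure(list(rank = rank, meta = meta[, req, drop = FALSE]),
            class = "rank_profiles")
}

#' @export
print.rank_profiles <- function(x, ...) {
  cat(sprintf("<rank_profiles> %d genes x %d instances (%d drugs, %d cell lines)\n",
              nrow(x$rank), ncol(x$rank),
              length(unique(x$meta$drug_id)),
              length(unique(x$meta$cell_line))))
  invisible(x)
}

#' Flip the orientation of rank profiles
#'
#' Maps every rank `r` to `n + 1 - r`, converting profiles where rank 1
#' means most down-regulated into this package's convention (rank 1 =
#' most up-regulated), or vice versa.
#'
#' @param profiles A [rank_profiles()] object.
#' @return A `rank_profiles` object with inverted ranks.
#' @export
invert_rank_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "rank_profiles"))
  profiles$rank <- nrow(profiles$rank) + 1L - profiles$rank
  profiles
}

#' Read rank profiles from TSV files
#'
#' @param rank_path Rank matrix TSV: gene ids in the first column, one
#'   integer column per instance, instance ids in the header.
#' @param meta_path Instance metadata TSV with header
#'   `instance_id`, `drug_id`, `cell_line`.
#' @return A [rank_profiles()] object.
#' @export
read_rank_profiles <- function(rank_path, meta_path) {
  tab <- read.delim(rank_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  rank <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(rank) <- as.character(tab[[1L]])
  storage.mode(rank) <- "integer"
  meta <- read.delim(meta_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  meta <- meta[match(colnames(rank), meta$instance_id), , drop = FALSE]
  if (anyNA(meta$instance_id))
    stop("instance(s) in rank matrix missing from metadata", call. = FALSE)
  rank_profiles(rank, meta)
}

#' Signed Kolmogorov-Smirnov enrichment statistic
#'
#' Measures whether a gene set sits toward the top or the bottom of a
#' ranked list.  For the sorted positions `V(1) < ... < V(t)` of the set
#' in a list of `n` genes, let
#' `a = max_j ( j/t - V(j)/n )` and `b = max_j ( V(j)/n - (j-1)/t )`;
#' the statistic is `a` if `a > b`, else `-b`.  Positive values mean the
#' set is concentrated toward rank 1 (the drug-up-regulated end).
#'
#' @param positions Integer vector of the set's positions (ranks) in the
#'   list; need not be sorted but must be distinct and within `1..n`.
#' @param n Total number of genes in the ranked list.
#' @return A value in `[-1, 1]`.
#' @export
ks_statistic <- function(positions, n) {
  .assert_count(n, "n")
  if (length(positions) == 0L)
    stop("'positions' must be non-empty", call. = FALSE)
  if (any(positions < 1L | positions > n) ||
      anyDuplicated(positions) > 0L)
    stop("'positions' must be distinct integers in 1..n", call. = FALSE)
  .ks_sorted(sort(positions), length(positions), n)
}

# core KS computation on already-sorted positions; no validation
.ks_sorted <- function(v, t, n) {
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Connectivity score of a disease signature against one rank profile
#'
#' Scores the up- and down-regulated disease gene sets separately with
#' [ks_statistic()] and combines them: `score = ks_up - ks_down` when the
#' two statistics have opposite signs (or either is zero), and 0 when
#' they share a sign.  A negative score is the reversal pattern — disease
#' up-genes at the drug-down end of the list and disease down-genes at
#' the drug-up end — which is the therapeutic direction of interest.
#'
#' @param up,down Character vectors of disease up- and down-regulated
#'   gene ids; non-empty, disjoint.
#' @param profile Named integer vector mapping gene id to rank (one
#'   column of a [rank_profiles()] matrix, e.g.
#'   `setNames(p$rank[, 1], rownames(p$rank))`).
#' @param on_missing What to do with signature genes absent from the
#'   profile's universe: `"drop"` them with a warning (default; platform
#'   differences are expected) or `"error"`.
#' @return List with `ks_up`, `ks_down`, `score`.
#' @export
connectivity_score <- function(up, down, profile,
                               on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  if (length(up) == 0L || length(down) == 0L)
    stop("'up' and 'down' must be non-empty", call. = FALSE)
  if (length(intersect(up, down)))
    stop("'up' and 'down' must be disjoint", call. = FALSE)
  universe <- names(profile)
  if (is.null(universe))
    stop("'profile' must be a named rank vector", call. = FALSE)
  absent <- setdiff(c(up, down), universe)
  if (length(absent)) {
    if (on_missing == "error")
      stop("signature gene(s) absent from profile: ",
           paste(head(absent, 5L), collapse = ", "), call. = FALSE)
    warning(length(absent), " signature gene(s) absent from profile; dropped",
            call. = FALSE)
    up <- setdiff(up, absent)
    down <- setdiff(down, absent)
    if (length(up) == 0L || length(down) == 0L)
      stop("signature empty after dropping missing genes", call. = FALSE)
  }
  n <- length(profile)
  ks_up <- ks_statistic(unname(profile[up]), n)
  ks_down <- ks_statistic(unname(profile[down]), n)
  list(ks_up = ks_up, ks_down = ks_down,
       score = .combine_ks(ks_up, ks_down))
}

.combine_ks <- function(ks_up, ks_down) {
  if (ks_up * ks_down > 0) 0 else ks_up - ks_down
}

# Null connectivity scores for signature sizes (t_up, t_down) in a
# universe of n genes.  The positions of a uniformly random gene set are
# a uniformly random subset of 1..n in *any* fixed permutation, so the
# null distribution depends only on (t_up, t_down, n) and one sample can
# be shared across all instances of a screen.
.null_scores <- function(t_up, t_down, n, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(n, t_up + t_down)
    ks_u <- .ks_sorted(sort(pos[seq_len(t_up)]), t_up, n)
    ks_d <- .ks_sorted(sort(pos[t_up + seq_len(t_down)]), t_down, n)
    .combine_ks(ks_u, ks_d)
  }, numeric(1L))
}

#' Permutation p-value for negative connectivity
#'
#' One-sided empirical p-value for the reversal direction: random
#' disjoint gene sets of the same sizes as the signature are drawn
#' without replacement from the profile's universe, their connectivity
#' scores form the null, and
#' `p = (1 + #[null score <= observed]) / (1 + n_perm)`.  The `+1`
#' correction keeps p strictly positive.
#'
#' @inheritParams connectivity_score
#' @param n_perm Number of permutations; default 1000.  Values below 100
#'   trigger a warning.
#' @param seed Integer seed for the permutation draw.
#' @return p-value in `(0, 1]`.
#' @export
connectivity_pvalue <- function(up, down, profile, n_perm = 1000,
                                seed = 1L,
                                on_missing = c("drop", "error")) {
  .assert_scalar_number(n_perm, "n_perm")
  if (n_perm <= 0) stop("'n_perm' must be positive", call. = FALSE)
  if (n_perm < 100) warning("'n_perm' < 100: p-value will be coarse",
                            call. = FALSE)
  obs <- connectivity_score(up, down, profile, on_missing = on_missing)
  n <- length(profile)
  t_up <- length(intersect(up, names(profile)))
  t_down <- length(intersect(down, names(profile)))
  set.seed(seed)
  null <- .null_scores(t_up, t_down, n, n_perm)
  (1 + sum(null <= obs$score)) / (1 + n_perm)
}

#' Screen all drug instances against a disease signature
#'
#' Computes the signed KS connectivity score and a permutation p-value
#' for every instance, applies Benjamini-Hochberg adjustment across the
#' whole screen, and flags significant negative (signature-reversing)
#' instances.  One shared permutation null is used for all instances:
#' under the null a gene set's positions are uniform in any permutation,
#' so the null law depends only on the signature sizes and the universe
#' size.  Sharing the sample also makes p monotone in the score.
#'
#' @param signature A [differential_expression()] result, or any list
#'   with character elements `up` and `down`.
#' @param profiles A [rank_profiles()] object.
#' @param fdr_threshold Adjusted-p threshold for the significance flag;
#'   default 0.1.
#' @param n_perm Permutations for the null; default 1000.
#' @param seed Integer seed.
#' @param on_missing Passed to [connectivity_score()] semantics: drop
#'   signature genes absent from the profile universe (warning) or error.
#' @return Data frame of class `"connectivity_result"` with columns
#'   `instance_id`, `drug_id`, `cell_line`, `ks_up`, `ks_down`, `score`,
#'   `p`, `fdr`, `significant_negative`.
#' @export
screen_instances <- function(signature, profiles, fdr_threshold = 0.1,
                             n_perm = 1000, seed = 1L,
                             on_missing = c("drop", "error")) {
  stopifnot(inherits(profiles, "rank_profiles"))
  on_missing <- match.arg(on_missing)
  .assert_fraction(fdr_threshold, "fdr_threshold", open_left = TRUE)
  if (ncol(profiles$rank) < 1L)
    stop("need at least one profile", call. = FALSE)
  up <- signature$up
  down <- signature$down
  if (length(up) == 0L || length(down) == 0L)
    stop("signature has an empty up or down set", call. = FALSE)
  universe <- rownames(profiles$rank)
  absent <- setdiff(c(up, down), universe)
  if (length(absent)) {
    if (on_missing == "error")
      stop("signature gene(s) absent from profiles: ",
           paste(head(absent, 5L), collapse = ", "), call. = FALSE)
    warning(length(absent),
            " signature gene(s) absent from profiles; dropped",
            call. = FALSE)
    up <- setdiff(up, absent)
    down <- setdiff(down, absent)
  }
  if (length(up) == 0L || length(down) == 0L)
    stop("signature empty after dropping missing genes", call. = FALSE)

  n <- nrow(profiles$rank)
  t_up <- length(up); t_down <- length(down)
  # observed statistics, vectorized over instances
  pos_up <- apply(profiles$rank[up, , drop = FALSE], 2L, sort)
  pos_down <- apply(profiles$rank[down, , drop = FALSE], 2L, sort)
  pos_up <- matrix(pos_up, nrow = t_up)
  pos_down <- matrix(pos_down, nrow = t_down)
  ks_up <- apply(pos_up, 2L, .ks_sorted, t = t_up, n = n)
  ks_down <- apply(pos_down, 2L, .ks_sorted, t = t_down, n = n)
  score <- ifelse(ks_up * ks_down > 0, 0, ks_up - ks_down)

  set.seed(seed)
  null <- .null_scores(t_up, t_down, n, n_perm)
  p <- (1 + vapply(score, function(s) sum(null <= s), numeric(1L))) /
    (1 + n_perm)
  fdr <- bh_fdr(p)

  res <- data.frame(profiles$meta,
                    ks_up = ks_up, ks_down = ks_down, score = score,
                    p = p, fdr = fdr,
                    significant_negative = fdr < fdr_threshold & score < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("connectivity_result", "data.frame")
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}
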