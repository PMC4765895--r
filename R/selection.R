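#' Construct a drug annotation table
#'
#' Per drug: its protein target genes and the compound ids it maps to
#' (DrugBank-style annotations).
#'
#' @param drugs Data frame with columns `drug_id`, `targets`,
#'   `compounds`; the last two are `;`-separated id lists (empty string
#'   for none).
#' @return Object of class `"drug_annotations"`: list with the raw
#'   table and per-drug `target_sets` / `compound_sets`.
#' @export
drug_annotations <- function(drugs) {
  req <- c("drug_id", "targets", "compounds")
  if (!is.data.frame(drugs) || !all(req %in% names(drugs)))
    stop("'drugs' must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(drugs$drug_id))
    stop("duplicated drug id(s)", call. = FALSE)
  split_ids <- function(x) {
    out <- strsplit(as.character(x), ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  structure(
    list(table = drugs[, req, drop = FALSE],
         target_sets = setNames(split_ids(drugs$targets), drugs$drug_id),
         compound_sets = setNames(split_ids(drugs$compounds),
                                  drugs$drug_id)),
    class = "drug_annotations")
}

#' Read a drug annotation TSV
#'
#' @param path TSV with header `drug_id`, `targets`, `compounds`
#'   (`;`-joined id lists).
#' @return A [drug_annotations()] object.
#' @export
read_drug_annotations <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  tab$targets[is.na(tab$targets)] <- ""
  tab$compounds[is.na(tab$compounds)] <- ""
  drug_annotations(tab)
}

#' Potentially useful drugs within one dataset's connectivity screen
#'
#' A drug qualifies when *strictly more than half* of its cell-line
#' instances are flagged as significantly negatively correlated with the
#' disease signature.  Drugs with zero instances are excluded with a
#' warning.
#'
#' @param results A [screen_instances()] result (or any data frame with
#'   `drug_id` and `significant_negative`).
#' @return Character vector of drug ids.
#' @export
puds_per_dataset <- function(results) {
  if (!all(c("drug_id", "significant_negative") %in% names(results)))
    stop("'results' must have columns drug_id, significant_negative",
         call. = FALSE)
  drugs <- unique(results$drug_id)
  n_inst <- table(factor(results$drug_id, levels = drugs))
  if (any(n_inst == 0L)) {
    warning("drug(s) with zero instances excluded", call. = FALSE)
    drugs <- drugs[n_inst[drugs] > 0L]
  }
  n_sig <- tapply(results$significant_negative,
                  factor(results$drug_id, levels = drugs), sum)
  sort(drugs[n_sig / as.integer(n_inst[drugs]) > 0.5])
}

#' Combine per-dataset PUD sets across datasets
#'
#' Drugs significant in at least `min_datasets` of the per-dataset sets.
#'
#' @param per_dataset_sets List of character vectors of drug ids.
#' @param min_datasets Minimum number of datasets; default 2.
#' @return Character vector of drug ids.
#' @export
puds_overall <- function(per_dataset_sets, min_datasets = 2L) {
  if (length(per_dataset_sets) == 0L)
    stop("need at least one per-dataset set", call. = FALSE)
  .assert_count(min_datasets, "min_datasets")
  if (min_datasets > length(per_dataset_sets))
    stop("'min_datasets' exceeds the number of datasets", call. = FALSE)
  counts <- table(unlist(lapply(per_dataset_sets, unique)))
  sort(names(counts)[counts >= min_datasets])
}

#' Randomization test for cross-dataset drug overlap
#'
#' Are the per-dataset significant-drug sets more concordant than chance?
#' In each of `n_rand` replicates the same number of drugs is drawn
#' uniformly without replacement from the screened universe for every
#' dataset, and the number of drugs hit in at least two and in all
#' datasets is recorded.  Empirical p-values use the `+1` correction so
#' they are never zero.
#'
#' @param per_dataset_sets List of character vectors (each a subset of
#'   `universe`).
#' @param universe Character vector of all screened drug ids.
#' @param n_rand Number of randomizations; default 1000.
#' @param seed Integer seed.
#' @return List with `observed_at_least_2`, `observed_all`,
#'   `p_at_least_2`, `p_all`, `n_rand`.
#' @export
overlap_randomization <- function(per_dataset_sets, universe,
                                  n_rand = 1000, seed = 1L) {
  sizes <- lengths(per_dataset_sets)
  if (any(sizes > length(universe)))
    stop("a per-dataset set is larger than the universe", call. = FALSE)
  if (!all(unlist(per_dataset_sets) %in% universe))
    stop("per-dataset sets must be subsets of the universe", call. = FALSE)
  .assert_count(n_rand, "n_rand")
  k <- length(per_dataset_sets)
  obs <- table(factor(unlist(lapply(per_dataset_sets, unique))))
  obs2 <- sum(obs >= 2L)
  obs_all <- sum(obs == k)
  set.seed(seed)
  nu <- length(universe)
  null <- vapply(seq_len(n_rand), function(i) {
    hits <- integer(nu)
    for (s in sizes) {
      idx <- sample.int(nu, s)
      hits[idx] <- hits[idx] + 1L
    }
    c(sum(hits >= 2L), sum(hits == k))
  }, integer(2L))
  list(observed_at_least_2 = obs2, observed_all = obs_all,
       p_at_least_2 = (1 + sum(null[1L, ] >= obs2)) / (1 + n_rand),
       p_all = (1 + sum(null[2L, ] >= obs_all)) / (1 + n_rand),
       n_rand = n_rand)
}

#' Intersect per-dataset key-enzyme predictions
#'
#' Key enzymes predicted in *all* datasets.
#'
#' @param key_sets List of character vectors of gene ids.
#' @return Character vector (the intersection).
#' @export
kpc_intersection <- function(key_sets) {
  if (length(key_sets) == 0L)
    stop("need at least one key-enzyme set", call. = FALSE)
  sort(Reduce(intersect, key_sets))
}

#' Select candidate drugs from PUDs using key enzymes
#'
#' A potentially useful drug (PUD) becomes a candidate when
#' 1. one of its annotated targets is a key enzyme
#'    (rationale `"target_of_kpc"`), or
#' 2. one of its compounds is a substrate or product of a reaction
#'    catalyzed by a key enzyme
#'    (rationale `"substrate_or_product_of_kpc"`).
#'
#' The two categories are exclusive; a drug satisfying both is reported
#' under the target route.  PUDs missing from the annotation table are
#' excluded with a warning.
#'
#' @param puds Character vector of PUD drug ids.
#' @param kpc Character vector of key enzyme gene ids.
#' @param drugs A [drug_annotations()] object.
#' @param model A [metabolic_model()].
#' @return Data frame of class `"candidate_drugs"` with columns
#'   `drug_id`, `rationale`, `relevant_enzymes`, `relevant_compounds`
#'   (the latter two `;`-joined; compounds empty for the target route).
#' @export
select_candidates <- function(puds, kpc, drugs, model) {
  stopifnot(inherits(drugs, "drug_annotations"),
            inherits(model, "metabolic_model"))
  puds <- sort(unique(puds))
  absent <- setdiff(puds, drugs$table$drug_id)
  if (length(absent)) {
    warning(length(absent), " PUD(s) absent from annotation table; excluded",
            call. = FALSE)
    puds <- setdiff(puds, absent)
  }
  # compound -> key enzymes whose reactions involve it
  kpc_rx <- model$reactions$enzyme_gene %in% kpc
  cmp2enz <- list()
  if (any(kpc_rx)) {
    enz <- model$reactions$enzyme_gene[kpc_rx]
    cmps <- mapply(c, model$substrate_sets[kpc_rx],
                   model$product_sets[kpc_rx], SIMPLIFY = FALSE)
    cmp2enz <- lapply(split(rep(enz, lengths(cmps)), unlist(cmps)),
                      unique)
  }
  rows <- lapply(puds, function(d) {
    tgt_hit <- intersect(drugs$target_sets[[d]], kpc)
    if (length(tgt_hit))
      return(data.frame(drug_id = d, rationale = "target_of_kpc",
                        relevant_enzymes = paste(sort(tgt_hit),
                                                 collapse = ";"),
                        relevant_compounds = "",
                        stringsAsFactors = FALSE))
    cmp_hit <- intersect(drugs$compound_sets[[d]], names(cmp2enz))
    if (length(cmp_hit)) {
      enzymes <- sort(unique(unlist(cmp2enz[cmp_hit])))
      return(data.frame(drug_id = d,
                        rationale = "substrate_or_product_of_kpc",
                        relevant_enzymes = paste(enzymes, collapse = ";"),
                        relevant_compounds = paste(sort(cmp_hit),
                                                   collapse = ";"),
                        stringsAsFactors = FALSE))
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(drug_id = character(), rationale = character(),
                      relevant_enzymes = character(),
                      relevant_compounds = character(),
                      stringsAsFactors = FALSE)
  class(out) <- c("candidate_drugs", "data.frame")
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited gene-set format: set name, description, then
#' member genes, one set per line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("malformed GMT line (need name, description, >=1 gene)",
         call. = FALSE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1L), 1L))
}

#' Fisher exact gene-set enrichment
#'
#' For each annotation set, a one-sided Fisher exact test (enrichment
#' direction) on the 2x2 table of query membership vs set membership
#' over the universe, followed by Benjamini-Hochberg adjustment.
#'
#' @param query Character vector of gene ids (non-empty, subset of
#'   `universe`).
#' @param annotation_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); genes outside the universe are ignored.
#' @param universe Character vector of all eligible gene ids.
#' @param fdr_threshold Significance threshold on the adjusted p-value;
#'   default 0.1.
#' @return Data frame with columns `set`, `overlap`, `query_size`,
#'   `set_size`, `universe_size`, `p`, `fdr`, `significant`.
#' @export
fisher_enrichment <- function(query, annotation_sets, universe,
                              fdr_threshold = 0.1) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe", call. = FALSE)
  universe <- unique(universe)
  n_u <- length(universe)
  n_q <- length(query)
  res <- lapply(names(annotation_sets), function(nm) {
    set <- intersect(annotation_sets[[nm]], universe)
    k <- length(intersect(query, set))
    tab <- matrix(c(k, length(set) - k,
                    n_q - k, n_u - length(set) - n_q + k), nrow = 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, overlap = k, query_size = n_q,
               set_size = length(set), universe_size = n_u, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p), , drop = FALSE]
}
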