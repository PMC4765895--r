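#' Construct a metabolic model from a reaction table
#'
#' A reaction is an enzymatic transformation: one catalyzing enzyme-coding
#' gene, at least one substrate compound and at least one product
#' compound.  Two enzyme-coding genes are *linked* when a product of a
#' reaction catalyzed by one is a substrate of a reaction catalyzed by
#' the other; the links form the metabolic enzyme network used by
#' [importance_scores()].
#'
#' @param reactions Data frame with columns `reaction_id`, `enzyme_gene`,
#'   `substrates`, `products`; the compound columns are `;`-separated
#'   compound ids.
#' @param currency_compounds Character vector of compound ids ignored
#'   when deriving links (e.g. ATP, H2O — ubiquitous carriers that would
#'   connect everything).  Empty by default.
#' @return An object of class `"metabolic_model"`: list with `reactions`
#'   and `enzyme_links` (two-column data frame of unordered gene pairs).
#' @export
metabolic_model <- function(reactions, currency_compounds = character()) {
  req <- c("reaction_id", "enzyme_gene", "substrates", "products")
  if (!is.data.frame(reactions) || !all(req %in% names(reactions)))
    stop("'reactions' must contain columns ",
         paste(req, collapse = ", "), call. = FALSE)
  subs <- strsplit(as.character(reactions$substrates), ";", fixed = TRUE)
  prods <- strsplit(as.character(reactions$products), ";", fixed = TRUE)
  if (any(lengths(subs) == 0L) || any(lengths(prods) == 0L))
    stop("every reaction needs at least one substrate and one product",
         call. = FALSE)
  structure(
    list(reactions = reactions[, req, drop = FALSE],
         substrate_sets = subs, product_sets = prods,
         currency_compounds = currency_compounds,
         enzyme_links = build_enzyme_links(reactions, currency_compounds)),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions, %d enzyme genes, %d enzyme links\n",
              nrow(x$reactions), length(unique(x$reactions$enzyme_gene)),
              nrow(x$enzyme_links)))
  invisible(x)
}

#' Read a reaction table TSV into a metabolic model
#'
#' @param path TSV with header `reaction_id`, `enzyme_gene`,
#'   `substrates`, `products` (compounds `;`-joined).
#' @inheritParams metabolic_model
#' @return A [metabolic_model()].
#' @export
read_reaction_table <- function(path, currency_compounds = character()) {
  metabolic_model(read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE),
                  currency_compounds = currency_compounds)
}

#' Derive enzyme-enzyme links from reactions
#'
#' Link `(E1, E2)` exists iff some compound is a product of a reaction
#' catalyzed by `E1` and a substrate of a reaction catalyzed by `E2` (or
#' vice versa).  Self-links are removed, as are links mediated only by
#' compounds on the currency exclusion list.
#'
#' @inheritParams metabolic_model
#' @return Data frame with columns `enzyme1`, `enzyme2`
#'   (`enzyme1 < enzyme2`), one row per unordered pair.
#' @export
build_enzyme_links <- function(reactions, currency_compounds = character()) {
  subs <- strsplit(as.character(reactions$substrates), ";", fixed = TRUE)
  prods <- strsplit(as.character(reactions$products), ";", fixed = TRUE)
  enz <- as.character(reactions$enzyme_gene)
  # compound -> enzymes producing / consuming it
  prod_map <- split(rep(enz, lengths(prods)), unlist(prods))
  sub_map <- split(rep(enz, lengths(subs)), unlist(subs))
  compounds <- setdiff(intersect(names(prod_map), names(sub_map)),
                       currency_compounds)
  if (length(compounds) == 0L)
    return(data.frame(enzyme1 = character(), enzyme2 = character(),
                      stringsAsFactors = FALSE))
  pairs <- do.call(rbind, lapply(compounds, function(cmp) {
    expand.grid(enzyme1 = unique(prod_map[[cmp]]),
                enzyme2 = unique(sub_map[[cmp]]),
                stringsAsFactors = FALSE)
  }))
  pairs <- pairs[pairs$enzyme1 != pairs$enzyme2, , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(data.frame(enzyme1 = character(), enzyme2 = character(),
                      stringsAsFactors = FALSE))
  lo <- pmin(pairs$enzyme1, pairs$enzyme2)
  hi <- pmax(pairs$enzyme1, pairs$enzyme2)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(enzyme1 = lo[keep], enzyme2 = hi[keep],
                    stringsAsFactors = FALSE)
  out[order(out$enzyme1, out$enzyme2), , drop = FALSE]
}

#' Build a thresholded gene co-expression network
#'
#' Edge `(g, h)` is present iff the absolute Pearson correlation of the
#' two genes' expression across all samples is at least `min_abs_pcc`.
#' Genes without any qualifying edge are kept as isolated nodes.
#' Constant (zero-variance) genes cannot be correlated and are excluded
#' from edges with a warning.
#'
#' @param ds A normalized [expression_dataset()] (at least 4 samples).
#' @param min_abs_pcc Absolute-correlation threshold; default 0.7.
#' @return Object of class `"coexpression_network"`: list with `nodes`
#'   (all gene ids) and `edges` (data frame `gene1`, `gene2`, `weight`).
#' @export
build_coexpression_network <- function(ds, min_abs_pcc = 0.7) {
  stopifnot(inherits(ds, "expr_dataset"))
  .assert_fraction(min_abs_pcc, "min_abs_pcc", open_left = TRUE)
  if (ncol(ds$values) < 4L)
    stop("need at least 4 samples", call. = FALSE)
  if (anyNA(ds$values))
    stop("missing values present; run normalize_expression() first",
         call. = FALSE)
  vals <- ds$values
  const <- apply(vals, 1L, function(x) var(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant gene(s) excluded from edges",
            call. = FALSE)
  }
  cmat <- suppressWarnings(cor(t(vals[!const, , drop = FALSE])))
  cmat[is.na(cmat)] <- 0
  # tiny tolerance so exactly collinear pairs survive a threshold of 1
  idx <- which(abs(cmat) >= min_abs_pcc - 1e-12 & upper.tri(cmat),
               arr.ind = TRUE)
  genes <- rownames(cmat)
  structure(
    list(nodes = rownames(vals),
         edges = data.frame(gene1 = genes[idx[, 1L]],
                            gene2 = genes[idx[, 2L]],
                            weight = cmat[idx],
                            stringsAsFactors = FALSE),
         min_abs_pcc = min_abs_pcc),
    class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges (|PCC| >= %g)\n",
              length(x$nodes), nrow(x$edges), x$min_abs_pcc))
  invisible(x)
}

#' Partition a co-expression network into modules
#'
#' Greedy agglomerative maximization of Newman-Girvan modularity
#' (fast-greedy community detection) on the thresholded graph.  The
#' algorithm is deterministic; `seed` is accepted for interface
#' uniformity with the other pipeline stages.  Isolated genes become
#' singleton modules.
#'
#' @param net A [build_coexpression_network()] result.
#' @param seed Integer seed (kept for a reproducibility contract shared
#'   by all pipeline stages).
#' @return Object of class `"module_partition"`: list with `assignment`
#'   (named integer vector gene -> module id) and `auc` (named numeric,
#'   filled by [score_modules()]).
#' @export
partition_modules <- function(net, seed = 1L) {
  stopifnot(inherits(net, "coexpression_network"))
  if (length(net$nodes) == 0L) stop("empty network", call. = FALSE)
  set.seed(seed)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene1", "gene2")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  if (igraph::ecount(g) > 0L) {
    comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
    assignment <- igraph::membership(comm)
    assignment <- setNames(as.integer(assignment), names(assignment))
  } else {
    assignment <- setNames(seq_along(net$nodes), net$nodes)
  }
  structure(list(assignment = assignment[net$nodes], auc = NULL),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("<module_partition> %d genes in %d modules (largest %d, %d singletons)\n",
              length(x$assignment), length(sizes), max(sizes),
              sum(sizes == 1L)))
  invisible(x)
}

#' Cancer-specificity AUC of a gene module
#'
#' Each sample is scored by the median expression of the module's genes;
#' the ROC AUC of that score for separating cancer from normal samples is
#' computed by pair counting (ties count one half) and oriented as
#' `max(AUC, 1 - AUC)`, so 0.5 means uninformative and 1 means the
#' module's median expression perfectly separates the classes in either
#' direction.
#'
#' @param module_genes Character vector of gene ids (non-empty; must be
#'   present in the dataset).
#' @param ds An [expression_dataset()] with both classes present.
#' @return AUC in `[0.5, 1]`.
#' @export
module_auc <- function(module_genes, ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  module_genes <- intersect(module_genes, rownames(ds$values))
  if (length(module_genes) == 0L)
    stop("module has no genes in the dataset", call. = FALSE)
  vals <- ds$values[module_genes, , drop = FALSE]
  score <- apply(vals, 2L, median, na.rm = TRUE)
  auc <- .auc_midrank(score[ds$phenotype == "cancer"],
                      score[ds$phenotype == "normal"])
  max(auc, 1 - auc)
}

# Mann-Whitney AUC via midranks: equivalent to pair counting with ties
# contributing 1/2.
.auc_midrank <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Attach per-module cancer-specificity AUCs to a partition
#'
#' @param partition A [partition_modules()] result.
#' @param ds The [expression_dataset()] the network was built from.
#' @return The partition with its `auc` element filled (named by module
#'   id).
#' @export
score_modules <- function(partition, ds) {
  stopifnot(inherits(partition, "module_partition"))
  by_mod <- split(names(partition$assignment), partition$assignment)
  partition$auc <- vapply(by_mod, module_auc, numeric(1L), ds = ds)
  partition
}

#' Importance scores for enzyme-coding genes
#'
#' For every enzyme gene `g` present in the partition: `d_in` counts its
#' metabolic links to enzymes in the same co-expression module, `d_tot`
#' its links to any scored enzyme.  The enrichment of within-module links
#' is the upper tail of the hypergeometric law: drawing `d_tot` partners
#' from the `N` scored enzymes of which `K` lie in `g`'s module, the
#' probability of at least `d_in` co-module partners.  The score is
#' `auc_m(g) * (-log10 p)`, combining the module's cancer specificity
#' with the link enrichment.  Enzyme genes absent from the partition are
#' skipped with a warning.
#'
#' @param partition A [score_modules()]-scored partition.
#' @param model A [metabolic_model()].
#' @return Data frame with columns `gene`, `module`, `auc`, `d_in`,
#'   `d_tot`, `enrichment`, `score`, `is_key` (score strictly above the
#'   median score).
#' @export
importance_scores <- function(partition, model) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(model, "metabolic_model"))
  if (is.null(partition$auc))
    stop("partition has no module AUCs; run score_modules() first",
         call. = FALSE)
  enzymes <- unique(as.character(model$reactions$enzyme_gene))
  absent <- setdiff(enzymes, names(partition$assignment))
  if (length(absent)) {
    warning(length(absent),
            " enzyme gene(s) absent from the partition; skipped",
            call. = FALSE)
    enzymes <- setdiff(enzymes, absent)
  }
  if (length(enzymes) == 0L)
    stop("no enzyme gene present in the partition", call. = FALSE)

  # adjacency restricted to scored enzymes
  links <- model$enzyme_links
  keep <- links$enzyme1 %in% enzymes & links$enzyme2 %in% enzymes
  links <- links[keep, , drop = FALSE]
  partners <- split(c(links$enzyme2, links$enzyme1),
                    c(links$enzyme1, links$enzyme2))

  mod <- partition$assignment[enzymes]
  n_total <- length(enzymes)
  mod_size <- table(factor(mod))

  d_in <- integer(length(enzymes))
  d_tot <- integer(length(enzymes))
  for (i in seq_along(enzymes)) {
    pp <- partners[[enzymes[i]]]
    d_tot[i] <- length(pp)
    d_in[i] <- sum(partition$assignment[pp] == mod[i])
  }
  k_module <- as.integer(mod_size[as.character(mod)])
  tail_p <- phyper(d_in - 1L, k_module, n_total - k_module, d_tot,
                   lower.tail = FALSE)
  enrichment <- ifelse(d_in == 0L, 0, -log10(tail_p))
  score <- partition$auc[as.character(mod)] * enrichment
  res <- data.frame(gene = enzymes, module = as.integer(mod),
                    auc = unname(partition$auc[as.character(mod)]),
                    d_in = d_in, d_tot = d_tot,
                    enrichment = enrichment, score = unname(score),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$is_key <- res$score > median(res$score)
  res
}

#' Key enzyme-coding genes from importance scores
#'
#' Genes whose importance score is strictly greater than the median score
#' over all scored enzyme genes.  With many tied scores (e.g. all equal)
#' the set can be empty.
#'
#' @param scores An [importance_scores()] data frame.
#' @return Character vector of gene ids.
#' @export
key_enzymes <- function(scores) {
  if (nrow(scores) == 0L) stop("no scored genes", call. = FALSE)
  scores$gene[scores$score > median(scores$score)]
}

#' Run the full key-enzyme prediction on one dataset
#'
#' Convenience wrapper: builds the co-expression network, partitions it
#' into modules, scores module cancer specificity, computes enzyme
#' importance scores, and extracts key enzymes.
#'
#' @param ds A normalized [expression_dataset()].
#' @param model A [metabolic_model()].
#' @param min_abs_pcc Co-expression edge threshold; default 0.7.
#' @param seed Integer seed.
#' @return List of class `"met_express"` with `scores`, `key_enzymes`,
#'   `partition`.
#' @export
met_express <- function(ds, model, min_abs_pcc = 0.7, seed = 1L) {
  net <- build_coexpression_network(ds, min_abs_pcc = min_abs_pcc)
  part <- score_modules(partition_modules(net, seed = seed), ds)
  scores <- importance_scores(part, model)
  structure(list(scores = scores, key_enzymes = key_enzymes(scores),
                 partition = part, dataset_id = ds$dataset_id),
            class = "met_express")
}

#' @export
print.met_express <- function(x, ...) {
  cat(sprintf("<met_express '%s'> %d enzyme genes scored, %d key enzymes\n",
              x$dataset_id, nrow(x$scores), length(x$key_enzymes)))
  invisible(x)
}
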