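#' Configuration for the synthetic study generator
#'
#' Defines the conditions of a simulated drug-repositioning study:
#' several case/control expression datasets over a shared gene universe
#' with latent-factor co-expression modules and planted differentially
#' expressed genes; drug-induced gene rank profiles with planted
#' signature-reversing drugs; a metabolic reaction network with planted
#' key enzymes sitting inside cancer-specific modules; and drug
#' annotations with planted candidate drugs.
#'
#' @param n_genes Genes in the shared universe.
#' @param n_normal,n_cancer Samples per class in each dataset.
#' @param n_datasets Number of expression datasets.
#' @param n_modules Number of co-expression modules; the first half
#'   (rounded up) are cancer-specific.
#' @param module_size_range Length-2 integer vector: min and max genes
#'   per module.
#' @param cancer_module_effect Mean shift `delta` of the latent module
#'   factor in cancer samples for cancer-specific modules.
#' @param sigma Standard deviation of the per-gene residual noise
#'   (log2 scale).
#' @param de_fraction Fraction of genes with planted differential
#'   expression (drawn outside the modules; half up, half down).
#' @param de_effect Log2 shift `Delta` applied to planted DE genes in
#'   cancer samples.
#' @param n_drugs Number of drugs in the rank-profile compendium.
#' @param instances_per_drug Cell-line instances per drug.
#' @param n_reversers Number of planted signature-reversing drugs.
#' @param reversal_strength Additive score shift `beta` applied to
#'   signature genes in reverser instances before ranking.
#' @param n_enzymes Enzyme-coding genes in the metabolic model.
#' @param n_reactions Minimum number of reactions (the structured link
#'   construction may require a few more).
#' @param n_planted_key_enzymes Enzymes planted inside cancer-specific
#'   modules with dense within-module metabolic links.
#' @param n_planted_candidates Reverser drugs annotated so that the
#'   selection stage should recover them (half via the target route,
#'   half via the substrate/product route).
#' @param missing_rate Fraction of expression entries set missing
#'   completely at random.
#' @param seed Integer seed; every generator derives its random stream
#'   from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 2000, n_normal = 30, n_cancer = 30,
                              n_datasets = 3, n_modules = 8,
                              module_size_range = c(30, 80),
                              cancer_module_effect = 2, sigma = 0.3,
                              de_fraction = 0.05, de_effect = 3,
                              n_drugs = 200, instances_per_drug = 5,
                              n_reversers = 10, reversal_strength = 2,
                              n_enzymes = 200, n_reactions = 300,
                              n_planted_key_enzymes = 20,
                              n_planted_candidates = 6,
                              missing_rate = 0.01, seed = 1L) {
  cfg <- list(
    n_genes = .assert_count(n_genes, "n_genes"),
    n_normal = .assert_count(n_normal, "n_normal"),
    n_cancer = .assert_count(n_cancer, "n_cancer"),
    n_datasets = .assert_count(n_datasets, "n_datasets"),
    n_modules = .assert_count(n_modules, "n_modules"),
    module_size_range = module_size_range,
    cancer_module_effect = .assert_scalar_number(cancer_module_effect,
                                                 "cancer_module_effect"),
    sigma = .assert_scalar_number(sigma, "sigma"),
    de_fraction = .assert_fraction(de_fraction, "de_fraction",
                                   open_left = TRUE, open_right = TRUE),
    de_effect = .assert_scalar_number(de_effect, "de_effect"),
    n_drugs = .assert_count(n_drugs, "n_drugs"),
    instances_per_drug = .assert_count(instances_per_drug,
                                       "instances_per_drug"),
    n_reversers = .assert_count(n_reversers, "n_reversers", min = 0L),
    reversal_strength = .assert_scalar_number(reversal_strength,
                                              "reversal_strength"),
    n_enzymes = .assert_count(n_enzymes, "n_enzymes"),
    n_reactions = .assert_count(n_reactions, "n_reactions"),
    n_planted_key_enzymes = .assert_count(n_planted_key_enzymes,
                                          "n_planted_key_enzymes"),
    n_planted_candidates = .assert_count(n_planted_candidates,
                                         "n_planted_candidates", min = 0L),
    missing_rate = .assert_fraction(missing_rate, "missing_rate",
                                    open_right = TRUE),
    seed = .assert_count(seed, "seed", min = 0L))
  if (length(module_size_range) != 2L ||
      module_size_range[1L] > module_size_range[2L] ||
      module_size_range[1L] < 2L)
    stop("'module_size_range' must be an increasing pair of counts >= 2",
         call. = FALSE)
  if (cfg$reversal_strength < 0)
    stop("'reversal_strength' must be nonnegative", call. = FALSE)
  if (cfg$n_planted_key_enzymes > cfg$n_enzymes)
    stop("'n_planted_key_enzymes' must not exceed 'n_enzymes'",
         call. = FALSE)
  if (cfg$n_enzymes > cfg$n_genes)
    stop("'n_enzymes' must not exceed 'n_genes'", call. = FALSE)
  if (cfg$n_reversers > cfg$n_drugs)
    stop("'n_reversers' must not exceed 'n_drugs'", call. = FALSE)
  if (cfg$n_planted_candidates > cfg$n_reversers)
    stop("more planted candidates than reverser drugs", call. = FALSE)
  if (cfg$n_modules * module_size_range[2L] > cfg$n_genes)
    stop("module sizes may exceed n_genes: reduce n_modules or module sizes",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d genes, %d datasets (%d+%d), %d drugs x %d instances, %d enzymes, seed %d\n",
    x$n_genes, x$n_datasets, x$n_normal, x$n_cancer, x$n_drugs,
    x$instances_per_drug, x$n_enzymes, x$seed))
  invisible(x)
}

# Shared biology across datasets: gene universe, module layout, baseline
# means, factor loadings and planted DE genes.  Re-derived identically by
# every generator from config$seed.
.shared_structure <- function(config) {
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  sizes <- sample(seq(config$module_size_range[1L],
                      config$module_size_range[2L]),
                  config$n_modules, replace = TRUE)
  if (sum(sizes) > config$n_genes)
    stop("module sizes exceed n_genes", call. = FALSE)
  module_genes <- sample(genes, sum(sizes))
  assignment <- setNames(rep(0L, config$n_genes), genes)
  assignment[module_genes] <- rep(seq_len(config$n_modules), times = sizes)
  cancer_modules <- seq_len(ceiling(config$n_modules / 2))
  baseline <- setNames(rnorm(config$n_genes, mean = 8, sd = 1.5), genes)
  loading <- setNames(runif(config$n_genes, 0.5, 1.5), genes)

  background <- genes[assignment == 0L]
  n_de <- round(config$de_fraction * config$n_genes)
  if (n_de < 2L) n_de <- 2L
  if (n_de > length(background))
    stop("de_fraction too large for the non-module gene pool", call. = FALSE)
  de_genes <- sample(background, n_de)
  half <- floor(n_de / 2)
  list(genes = genes, assignment = assignment,
       cancer_modules = cancer_modules, baseline = baseline,
       loading = loading,
       de_up = sort(de_genes[seq_len(half)]),
       de_down = sort(de_genes[(half + 1L):n_de]))
}

#' Generate synthetic case/control expression datasets
#'
#' Latent-factor model on the log2 scale.  Every gene has a baseline
#' mean `~ Normal(8, 1.5^2)`.  Each module carries one latent factor per
#' sample, `Normal(0, 1)` in normal samples and
#' `Normal(delta, 1)` in cancer samples when the module is
#' cancer-specific; a module gene's expression is
#' `baseline + loading * factor + Normal(0, sigma^2)` with loadings
#' `~ Uniform(0.5, 1.5)`.  Planted DE genes (outside the modules, shared
#' across datasets) are shifted by `+Delta` (up set) or `-Delta` (down
#' set) in cancer samples.  Entries are then set missing completely at
#' random at `missing_rate`.  The gene universe, module layout and
#' planted DE sets are identical across the datasets; factors and noise
#' are independent.  Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `truth` (module assignment, cancer-specific module ids, planted DE
#'   up/down gene sets).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  shared <- .shared_structure(config)
  n_s <- config$n_normal + config$n_cancer
  phen <- rep(c("normal", "cancer"), c(config$n_normal, config$n_cancer))
  is_cancer <- phen == "cancer"
  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    set.seed(config$seed + 1000L + d)
    vals <- matrix(rnorm(config$n_genes * n_s, sd = config$sigma),
                   nrow = config$n_genes,
                   dimnames = list(shared$genes,
                                   sprintf("ds%d_s%03d", d, seq_len(n_s))))
    vals <- vals + shared$baseline
    for (m in seq_len(config$n_modules)) {
      mu <- if (m %in% shared$cancer_modules)
        ifelse(is_cancer, config$cancer_module_effect, 0) else 0
      f <- rnorm(n_s, mean = mu, sd = 1)
      idx <- which(shared$assignment == m)
      vals[idx, ] <- vals[idx, ] +
        outer(shared$loading[idx], f)
    }
    vals[shared$de_up, is_cancer] <-
      vals[shared$de_up, is_cancer] + config$de_effect
    vals[shared$de_down, is_cancer] <-
      vals[shared$de_down, is_cancer] - config$de_effect
    if (config$missing_rate > 0) {
      nas <- which(runif(length(vals)) < config$missing_rate)
      vals[nas] <- NA_real_
    }
    datasets[[d]] <- expression_dataset(
      vals, setNames(phen, colnames(vals)),
      dataset_id = sprintf("synthetic_ds%d", d))
  }
  list(datasets = datasets,
       truth = list(module_assignment = shared$assignment,
                    cancer_modules = shared$cancer_modules,
                    planted_de_up = shared$de_up,
                    planted_de_down = shared$de_down))
}

#' Generate drug-induced gene rank profiles with planted reversers
#'
#' Per instance every gene receives a score `epsilon ~ Normal(0, 1)`;
#' for reverser drugs the score is `-beta * s_g + epsilon` where
#' `s_g = +1` for disease-up genes, `-1` for disease-down genes and 0
#' otherwise — so disease-up genes sink toward the drug-down end of the
#' list and vice versa.  Ranks are assigned by descending score: rank 1
#' is the most drug-up-regulated gene.  Reverser drugs are a random
#' subset of size `n_reversers`.
#'
#' @param config A [simulation_config()].
#' @param signature List with character elements `up` and `down`
#'   (typically the planted DE sets or a fitted
#'   [differential_expression()] signature).
#' @param genes Character vector, the gene universe of the profiles;
#'   defaults to the config's shared universe.
#' @return List with `profiles` (a [rank_profiles()] object) and `truth`
#'   (`planted_reverser_drugs`).
#' @export
generate_rank_profiles <- function(config, signature, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(signature$up) == 0L && length(signature$down) == 0L)
    stop("empty signature", call. = FALSE)
  if (is.null(genes)) genes <- .shared_structure(config)$genes
  if (!all(c(signature$up, signature$down) %in% genes))
    stop("signature gene(s) outside the gene universe", call. = FALSE)
  set.seed(config$seed + 2L)
  n <- length(genes)
  drug_ids <- sprintf("drug%03d", seq_len(config$n_drugs))
  reversers <- sort(sample(drug_ids, config$n_reversers))
  s <- setNames(rep(0, n), genes)
  s[signature$up] <- 1
  s[signature$down] <- -1
  n_inst <- config$n_drugs * config$instances_per_drug
  rank <- matrix(0L, nrow = n, ncol = n_inst,
                 dimnames = list(genes, NULL))
  meta <- data.frame(
    instance_id = sprintf("inst%05d", seq_len(n_inst)),
    drug_id = rep(drug_ids, each = config$instances_per_drug),
    cell_line = rep(sprintf("CL%d", seq_len(config$instances_per_drug)),
                    times = config$n_drugs),
    stringsAsFactors = FALSE)
  for (j in seq_len(n_inst)) {
    score <- rnorm(n)
    if (meta$drug_id[j] %in% reversers)
      score <- score - config$reversal_strength * s
    rank[, j] <- rank(-score, ties.method = "first")
  }
  list(profiles = rank_profiles(rank, meta),
       truth = list(planted_reverser_drugs = reversers))
}

#' Generate a metabolic reaction network with planted key enzymes
#'
#' Enzyme-coding genes are drawn from the expression universe: the
#' planted key enzymes sit inside cancer-specific co-expression modules
#' and receive several product-to-substrate reaction chains to co-module
#' enzymes (high within-module metabolic degree); the remaining enzymes
#' are placed in non-cancer modules or the unstructured background and
#' are chained mostly across modules (within-module degree ~ 0).  Every
#' reaction has one catalyzing enzyme, at least one substrate and at
#' least one product; standalone reactions pad the table up to at least
#' `n_reactions`.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` element of [generate_expression()] (module
#'   assignment and cancer-module ids).
#' @return List with `model` (a [metabolic_model()]) and `truth`
#'   (`planted_key_enzymes`, `enzyme_genes`).
#' @export
generate_metabolic_model <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  assignment <- truth$module_assignment
  cancer_modules <- truth$cancer_modules
  set.seed(config$seed + 3L)
  genes <- names(assignment)
  de_genes <- c(truth$planted_de_up, truth$planted_de_down)

  cancer_genes <- genes[assignment %in% cancer_modules]
  keys <- sort(sample(cancer_genes, config$n_planted_key_enzymes))
  # co-module partner enzymes for the key enzymes
  partners <- character()
  for (m in unique(assignment[keys])) {
    pool <- setdiff(genes[assignment == m], keys)
    partners <- c(partners, sample(pool, min(8L, length(pool))))
  }
  other_pool <- setdiff(genes[!(assignment %in% cancer_modules) &
                                !(genes %in% de_genes)],
                        c(keys, partners))
  n_bg <- config$n_enzymes - length(keys) - length(partners)
  if (n_bg < 0)
    stop("n_enzymes too small for the planted key enzymes and their partners",
         call. = FALSE)
  background <- sample(other_pool, min(n_bg, length(other_pool)))
  enzymes <- c(keys, partners, background)

  cmp_counter <- 0L
  new_cmp <- function(k = 1L) {
    ids <- sprintf("c%05d", cmp_counter + seq_len(k))
    cmp_counter <<- cmp_counter + k
    ids
  }
  rx <- list()
  add_rx <- function(enzyme, substrate, product) {
    rx[[length(rx) + 1L]] <<- data.frame(
      reaction_id = sprintf("rx%05d", length(rx) + 1L),
      enzyme_gene = enzyme, substrates = substrate, products = product,
      stringsAsFactors = FALSE)
  }
  link <- function(e1, e2) {
    # product of e1's reaction is substrate of e2's reaction
    c_shared <- new_cmp()
    ends <- new_cmp(2L)
    add_rx(e1, ends[1L], c_shared)
    add_rx(e2, c_shared, ends[2L])
  }
  # dense within-module chains for the key enzymes
  for (e in keys) {
    m <- assignment[e]
    co <- setdiff(enzymes[assignment[enzymes] == m], e)
    for (p in sample(co, min(6L, length(co)))) link(e, p)
  }
  # background enzymes chain across modules
  for (e in background) {
    pool <- enzymes[assignment[enzymes] != assignment[e] |
                      assignment[enzymes] == 0L]
    pool <- setdiff(pool, c(e, keys))
    if (length(pool)) link(e, sample(pool, 1L))
  }
  # every enzyme catalyzes at least one reaction; pad to n_reactions
  done <- unique(vapply(rx, function(r) r$enzyme_gene, character(1L)))
  for (e in setdiff(enzymes, done)) add_rx(e, new_cmp(), new_cmp())
  while (length(rx) < config$n_reactions) {
    add_rx(sample(background, 1L), new_cmp(), new_cmp())
  }
  model <- metabolic_model(do.call(rbind, rx))
  list(model = model,
       truth = list(planted_key_enzymes = keys,
                    enzyme_genes = sort(enzymes)))
}

#' Generate drug annotations with planted candidate drugs
#'
#' A subset of the reverser drugs is planted as candidates: half receive
#' a planted key enzyme among their targets (`target_of_kpc` route), the
#' other half receive compound ids that are substrates or products of
#' reactions catalyzed by planted key enzymes
#' (`substrate_or_product_of_kpc` route).  All other drugs get background
#' targets (non-enzyme genes) and compound ids outside the metabolic
#' model, so they can never be selected.
#'
#' @param config A [simulation_config()].
#' @param model The [metabolic_model()] from
#'   [generate_metabolic_model()].
#' @param reversers Character vector of planted reverser drug ids.
#' @param key_enzymes Character vector of planted key enzyme gene ids.
#' @return List with `drugs` (a [drug_annotations()] object) and `truth`
#'   (`planted_candidate_drugs` with a `rationale` attribute-like data
#'   frame `candidate_table`).
#' @export
generate_drug_annotations <- function(config, model, reversers,
                                      key_enzymes) {
  stopifnot(inherits(config, "sim_config"),
            inherits(model, "metabolic_model"))
  if (config$n_planted_candidates > length(reversers))
    stop("more planted candidates than reverser drugs", call. = FALSE)
  set.seed(config$seed + 4L)
  drug_ids <- sprintf("drug%03d", seq_len(config$n_drugs))
  enzymes <- unique(model$reactions$enzyme_gene)
  universe <- sprintf("g%04d", seq_len(config$n_genes))
  bg_targets <- setdiff(universe, enzymes)

  # compounds adjacent to each key enzyme's reactions
  key_rx <- model$reactions$enzyme_gene %in% key_enzymes
  key_cmp_by_enz <- split(
    unlist(mapply(c, model$substrate_sets[key_rx],
                  model$product_sets[key_rx], SIMPLIFY = FALSE)),
    rep(model$reactions$enzyme_gene[key_rx],
        lengths(model$substrate_sets[key_rx]) +
          lengths(model$product_sets[key_rx])))

  candidates <- sample(reversers, config$n_planted_candidates)
  n_target_route <- ceiling(config$n_planted_candidates / 2)
  target_route <- candidates[seq_len(n_target_route)]
  compound_route <- setdiff(candidates, target_route)

  targets <- vector("character", config$n_drugs)
  compounds <- vector("character", config$n_drugs)
  names(targets) <- names(compounds) <- drug_ids
  for (d in drug_ids) {
    n_t <- sample(1:3, 1L)
    targets[d] <- paste(sample(bg_targets, n_t), collapse = ";")
    compounds[d] <- paste(sprintf("bgc%04d", sample.int(9999L, 2L)),
                          collapse = ";")
  }
  for (d in target_route) {
    key <- sample(key_enzymes, 1L)
    targets[d] <- paste(c(key, sample(bg_targets, 2L)), collapse = ";")
  }
  for (d in compound_route) {
    keys2 <- sample(key_enzymes, min(2L, length(key_enzymes)))
    cmp <- vapply(keys2, function(k) sample(key_cmp_by_enz[[k]], 1L),
                  character(1L))
    compounds[d] <- paste(unique(cmp), collapse = ";")
  }
  drugs <- drug_annotations(data.frame(
    drug_id = drug_ids, targets = targets[drug_ids],
    compounds = compounds[drug_ids], stringsAsFactors = FALSE))
  candidate_table <- data.frame(
    drug_id = candidates,
    rationale = c(rep("target_of_kpc", length(target_route)),
                  rep("substrate_or_product_of_kpc",
                      length(compound_route))),
    stringsAsFactors = FALSE)
  list(drugs = drugs,
       truth = list(planted_candidate_drugs = sort(candidates),
                    candidate_table =
                      candidate_table[order(candidate_table$drug_id), ,
                                      drop = FALSE]))
}

#' Generate a complete synthetic study
#'
#' Runs all four generators with consistent shared structure and merges
#' the planted ground truth.  The signature handed to the rank-profile
#' generator is the *planted* DE gene set (the disease biology a real
#' signature estimates).
#'
#' @param config A [simulation_config()].
#' @return Object of class `"synthetic_study"`: list with `config`,
#'   `datasets`, `profiles`, `model`, `drugs`, `truth`.
#' @export
simulate_study <- function(config = simulation_config()) {
  expr <- generate_expression(config)
  prof <- generate_rank_profiles(
    config, list(up = expr$truth$planted_de_up,
                 down = expr$truth$planted_de_down))
  met <- generate_metabolic_model(config, expr$truth)
  ann <- generate_drug_annotations(config, met$model,
                                   prof$truth$planted_reverser_drugs,
                                   met$truth$planted_key_enzymes)
  structure(
    list(config = config, datasets = expr$datasets,
         profiles = prof$profiles, model = met$model, drugs = ann$drugs,
         truth = c(expr$truth, prof$truth, met$truth, ann$truth)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  print(x$config)
  cat(sprintf("  planted: %d DE up, %d DE down, %d reversers, %d key enzymes, %d candidates\n",
              length(x$truth$planted_de_up),
              length(x$truth$planted_de_down),
              length(x$truth$planted_reverser_drugs),
              length(x$truth$planted_key_enzymes),
              length(x$truth$planted_candidate_drugs)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the same plain-text formats the readers consume: one expression
#' and phenotype TSV per dataset, the rank matrix and instance metadata,
#' the reaction table, the drug annotation table, and the ground truth
#' as JSON.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in study$datasets) {
    tab <- data.frame(gene = rownames(ds$values), ds$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, file.path(dir, paste0(ds$dataset_id, "_expr.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(names(ds$phenotype),
                           as.character(ds$phenotype)),
                file.path(dir, paste0(ds$dataset_id, "_pheno.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  rk <- data.frame(gene = rownames(study$profiles$rank),
                   study$profiles$rank, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(rk, file.path(dir, "rank_profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$profiles$meta, file.path(dir, "instances.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$model$reactions, file.path(dir, "reactions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$drugs$table, file.path(dir, "drugs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- study$truth
  truth$module_assignment <- as.list(truth$module_assignment)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
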