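#' Run the combined drug-repositioning pipeline
#'
#' End-to-end analysis over several expression datasets and one
#' rank-profile compendium:
#'
#' 1. normalize each dataset and call differential expression;
#' 2. screen every drug instance against each dataset's signature and
#'    collect per-dataset PUD sets (majority of instances significantly
#'    negative), then intersect into overall PUDs (>= `min_datasets`);
#' 3. run key-enzyme prediction ([met_express()]) per dataset and
#'    intersect into the key cancer enzyme set;
#' 4. select candidate drugs whose targets or compounds involve a key
#'    enzyme.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param profiles A [rank_profiles()] object.
#' @param model A [metabolic_model()].
#' @param drugs A [drug_annotations()] object.
#' @param alpha,fc_threshold DE thresholds; defaults 0.01 and 2.
#' @param fdr_threshold Connectivity screen FDR threshold; default 0.1.
#' @param min_datasets Datasets a drug must be significant in; default 2.
#' @param min_abs_pcc Co-expression edge threshold; default 0.7.
#' @param n_perm Permutations for the connectivity null; default 1000.
#' @param seed Integer seed for all randomized stages.
#' @return Object of class `"repositioning_result"` with elements
#'   `signatures`, `screens`, `puds_by_dataset`, `puds`, `key_sets`,
#'   `kpc`, `candidates`.
#' @export
run_pipeline <- function(datasets, profiles, model, drugs,
                         alpha = 0.01, fc_threshold = 2,
                         fdr_threshold = 0.1, min_datasets = 2L,
                         min_abs_pcc = 0.7, n_perm = 1000, seed = 1L) {
  stopifnot(length(datasets) >= 1L)
  normed <- lapply(datasets, normalize_expression)
  signatures <- lapply(normed, differential_expression,
                       alpha = alpha, fc_threshold = fc_threshold)
  screens <- lapply(seq_along(normed), function(i)
    screen_instances(signatures[[i]], profiles,
                     fdr_threshold = fdr_threshold, n_perm = n_perm,
                     seed = seed + i))
  puds_by_dataset <- lapply(screens, puds_per_dataset)
  puds <- puds_overall(puds_by_dataset,
                       min_datasets = min(min_datasets, length(datasets)))
  mex <- lapply(seq_along(normed), function(i)
    met_express(normed[[i]], model, min_abs_pcc = min_abs_pcc,
                seed = seed + i))
  key_sets <- lapply(mex, `[[`, "key_enzymes")
  kpc <- kpc_intersection(key_sets)
  candidates <- select_candidates(puds, kpc, drugs, model)
  structure(
    list(signatures = signatures, screens = screens,
         puds_by_dataset = puds_by_dataset, puds = puds,
         key_sets = key_sets, kpc = kpc, candidates = candidates),
    class = "repositioning_result")
}

#' @export
print.repositioning_result <- function(x, ...) {
  cat("<repositioning_result>\n")
  cat(sprintf("  per-dataset PUDs: %s\n",
              paste(lengths(x$puds_by_dataset), collapse = " / ")))
  cat(sprintf("  overall PUDs: %d\n", length(x$puds)))
  cat(sprintf("  per-dataset key enzymes: %s\n",
              paste(lengths(x$key_sets), collapse = " / ")))
  cat(sprintf("  key cancer enzymes (all datasets): %d\n",
              length(x$kpc)))
  cat(sprintf("  candidate drugs: %d (%d target route, %d compound route)\n",
              nrow(x$candidates),
              sum(x$candidates$rationale == "target_of_kpc"),
              sum(x$candidates$rationale == "substrate_or_product_of_kpc")))
  invisible(x)
}

# sensitivity / precision / recall of a predicted set vs a planted set
.set_metrics <- function(predicted, planted) {
  tp <- length(intersect(predicted, planted))
  c(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
    precision = if (length(predicted)) tp / length(predicted) else NA_real_)
}

#' Run the pipeline on a synthetic study and score recovery
#'
#' Executes [run_pipeline()] on the generated data and compares every
#' stage's output with the planted ground truth.
#'
#' @param study A [simulate_study()] result.
#' @param ... Passed to [run_pipeline()].
#' @param seed Integer seed for the pipeline's randomized stages.
#' @return List with the pipeline `result` and a `metrics` list:
#'   `pud_sensitivity`, `pud_precision`, `key_enzyme_sensitivity` (mean
#'   per-dataset), `kpc_sensitivity`, `candidate_precision`,
#'   `candidate_recall`.
#' @export
evaluate_synthetic <- function(study, seed = study$config$seed, ...) {
  stopifnot(inherits(study, "synthetic_study"))
  res <- run_pipeline(study$datasets, study$profiles, study$model,
                      study$drugs, seed = seed, ...)
  truth <- study$truth
  pud <- .set_metrics(res$puds, truth$planted_reverser_drugs)
  key_sens <- vapply(res$key_sets, function(k)
    .set_metrics(k, truth$planted_key_enzymes)[["sensitivity"]],
    numeric(1L))
  kpc <- .set_metrics(res$kpc, truth$planted_key_enzymes)
  cand <- .set_metrics(res$candidates$drug_id,
                       truth$planted_candidate_drugs)
  list(result = res,
       metrics = list(
         pud_sensitivity = unname(pud[["sensitivity"]]),
         pud_precision = unname(pud[["precision"]]),
         key_enzyme_sensitivity = mean(key_sens),
         kpc_sensitivity = unname(kpc[["sensitivity"]]),
         candidate_precision = unname(cand[["precision"]]),
         candidate_recall = unname(cand[["sensitivity"]])))
}
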