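#' Construct an expression dataset
#'
#' Bundles a gene-by-sample expression matrix with binary phenotype labels
#' (`"normal"` / `"cancer"`).  This is the unit on which differential
#' expression, co-expression networks, and module AUCs are computed.
#'
#' @param values Numeric matrix, genes in rows and samples in columns; row
#'   and column names are the gene and sample identifiers.  Missing
#'   entries are allowed (`NA`).
#' @param phenotype Character or factor vector of labels, one per sample,
#'   each `"normal"` or `"cancer"`.  If named, names must match the sample
#'   ids of `values`.
#' @param dataset_id Identifier for the dataset.
#'
#' @return An object of class `"expr_dataset"`: a list with elements
#'   `dataset_id`, `values`, and `phenotype` (a factor with levels
#'   `normal`, `cancer` aligned with the columns of `values`).
#' @export
expression_dataset <- function(values, phenotype, dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names",
         call. = FALSE)
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(names(phenotype))) {
    missing <- setdiff(colnames(values), names(phenotype))
    if (length(missing))
      stop("sample(s) missing from phenotype: ",
           paste(missing, collapse = ", "), call. = FALSE)
    phenotype <- phenotype[colnames(values)]
  }
  if (length(phenotype) != ncol(values))
    stop("'phenotype' length (", length(phenotype),
         ") does not match the number of samples (", ncol(values), ")",
         call. = FALSE)
  phenotype <- as.character(phenotype)
  bad <- setdiff(unique(phenotype), c("normal", "cancer"))
  if (length(bad))
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  phenotype <- factor(phenotype, levels = c("normal", "cancer"))
  if (any(table(phenotype) == 0L))
    stop("both phenotype classes (normal, cancer) must be non-empty",
         call. = FALSE)
  structure(
    list(dataset_id = dataset_id, values = values,
         phenotype = setNames(phenotype, colnames(values))),
    class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  tab <- table(x$phenotype)
  cat(sprintf("<expr_dataset '%s'> %d genes x %d samples (%d normal, %d cancer)\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              tab[["normal"]], tab[["cancer"]]))
  na <- sum(is.na(x$values))
  if (na > 0)
    cat(sprintf("  %d missing entries (%.2f%%)\n", na,
                100 * na / length(x$values)))
  invisible(x)
}

#' Read an expression matrix and phenotype table from TSV files
#'
#' The expression file has one header row of sample ids and one row per
#' gene (gene id in the first column).  The phenotype file has two
#' columns, `sample_id` and `label`, without a header.
#'
#' @param path Path to the expression TSV.
#' @param phenotype_path Path to the phenotype TSV.
#' @param dataset_id Identifier; defaults to the expression file name.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, phenotype_path,
                            dataset_id = basename(path)) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene row(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values))
    stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(values) <- gene_ids
  ph <- read.delim(phenotype_path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  phenotype <- setNames(as.character(ph[[2L]]), as.character(ph[[1L]]))
  expression_dataset(values, phenotype, dataset_id = dataset_id)
}

#' Normalize an expression dataset
#'
#' Applies a log2 transform when the data look like raw (linear-scale)
#' intensities, removes genes with too many missing values, and imputes
#' the rest:
#'
#' * if the overall median expression (missing entries excluded) exceeds
#'   16, every value `v` is replaced by `log2(v + 1)`;
#' * genes missing in more than `null_fraction_max` of samples are
#'   dropped;
#' * remaining missing entries are imputed with the gene's per-phenotype
#'   class mean.
#'
#' @param ds An [expression_dataset()].
#' @param null_fraction_max Maximum tolerated fraction of missing values
#'   per gene; default 0.2.
#' @return A normalized `expr_dataset` with no missing values.
#' @export
normalize_expression <- function(ds, null_fraction_max = 0.2) {
  stopifnot(inherits(ds, "expr_dataset"))
  .assert_fraction(null_fraction_max, "null_fraction_max", open_right = TRUE)
  values <- ds$values
  med <- median(values, na.rm = TRUE)
  if (is.finite(med) && med > 16) {
    if (any(values < 0, na.rm = TRUE))
      stop("negative expression values: cannot apply log2 transform",
           call. = FALSE)
    values <- log2(values + 1)
  }
  na_frac <- rowMeans(is.na(values))
  values <- values[na_frac <= null_fraction_max, , drop = FALSE]
  if (anyNA(values)) {
    for (cls in levels(ds$phenotype)) {
      idx <- which(ds$phenotype == cls)
      block <- values[, idx, drop = FALSE]
      if (anyNA(block)) {
        cls_mean <- rowMeans(block, na.rm = TRUE)
        nas <- which(is.na(block), arr.ind = TRUE)
        block[nas] <- cls_mean[nas[, 1L]]
        values[, idx] <- block
      }
    }
  }
  expression_dataset(values, ds$phenotype, dataset_id = ds$dataset_id)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values; a thin, validating wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop("'pvalues' must be numeric", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Differential expression with a moderated t-statistic
#'
#' For every gene the log2 fold change is `mean(cancer) - mean(normal)`.
#' Significance uses a two-sample t-statistic with empirical-Bayes
#' variance moderation: each gene's pooled variance is shrunk toward the
#' across-gene mean variance with prior weight `d0` (prior degrees of
#' freedom), and p-values are taken from a t distribution with
#' `d0 + n1 + n2 - 2` degrees of freedom.  With `d0 = 0` this reduces to
#' the ordinary equal-variance two-sample t-test.  P-values are BH
#' adjusted; the signature contains genes with `fdr < alpha` and
#' `|log2FC| > log2(fc_threshold)`, split by sign.
#'
#' @param ds A normalized [expression_dataset()] without missing values.
#' @param alpha FDR threshold for signature membership; default 0.01.
#' @param fc_threshold Fold-change threshold (linear scale); default 2,
#'   i.e. `|log2FC| > 1`.
#' @param d0 Prior degrees of freedom of the variance shrinkage; default 4.
#' @return An object of class `"disease_signature"`: list with character
#'   vectors `up` and `down` and a per-gene `table`
#'   (`gene`, `log2fc`, `t`, `p`, `fdr`).
#' @export
differential_expression <- function(ds, alpha = 0.01, fc_threshold = 2,
                                    d0 = 4) {
  stopifnot(inherits(ds, "expr_dataset"))
  .assert_fraction(alpha, "alpha", open_left = TRUE)
  .assert_scalar_number(fc_threshold, "fc_threshold")
  .assert_scalar_number(d0, "d0")
  if (d0 < 0) stop("'d0' must be nonnegative", call. = FALSE)
  if (anyNA(ds$values))
    stop("missing values present; run normalize_expression() first",
         call. = FALSE)
  idx_n <- which(ds$phenotype == "normal")
  idx_c <- which(ds$phenotype == "cancer")
  n1 <- length(idx_n); n2 <- length(idx_c)
  if (n1 < 2L || n2 < 2L)
    stop("each phenotype class needs at least 2 samples", call. = FALSE)

  xn <- ds$values[, idx_n, drop = FALSE]
  xc <- ds$values[, idx_c, drop = FALSE]
  mn <- rowMeans(xn); mc <- rowMeans(xc)
  log2fc <- mc - mn
  df <- n1 + n2 - 2L
  s2 <- (rowSums((xn - mn)^2) + rowSums((xc - mc)^2)) / df
  s2_0 <- mean(s2)                      # shrinkage target
  s2_tilde <- (d0 * s2_0 + df * s2) / (d0 + df)
  tstat <- log2fc / sqrt(s2_tilde * (1 / n1 + 1 / n2))
  p <- 2 * pt(abs(tstat), df = df + d0, lower.tail = FALSE)
  fdr <- bh_fdr(p)

  pass <- fdr < alpha & abs(log2fc) > log2(fc_threshold)
  genes <- rownames(ds$values)
  structure(
    list(up = genes[pass & log2fc > 0],
         down = genes[pass & log2fc < 0],
         table = data.frame(gene = genes, log2fc = log2fc, t = tstat,
                            p = p, fdr = fdr, row.names = NULL,
                            stringsAsFactors = FALSE),
         alpha = alpha, fc_threshold = fc_threshold, d0 = d0,
         dataset_id = ds$dataset_id),
    class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("<disease_signature '%s'> %d up / %d down of %d genes (fdr < %g, fc > %g)\n",
              x$dataset_id, length(x$up), length(x$down), nrow(x$table),
              x$alpha, x$fc_threshold))
  invisible(x)
}

#' Write a disease signature to TSV
#'
#' One row per gene with `gene`, `log2fc`, `p`, `fdr`, and `direction`
#' (`up`, `down`, or `ns`).
#'
#' @param signature A [differential_expression()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "disease_signature"))
  tab <- signature$table
  tab$direction <- "ns"
  tab$direction[tab$gene %in% signature$up] <- "up"
  tab$direction[tab$gene %in% signature$down] <- "down"
  write.table(tab[, c("gene", "log2fc", "p", "fdr", "direction")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation between two datasets' mean expression profiles
#'
#' Per-gene mean expression over all samples is computed in each dataset,
#' restricted to the common genes, and the Pearson correlation between
#' the two mean vectors is returned.  Used to check that independent
#' datasets are correlated but not redundant.
#'
#' @param ds1,ds2 [expression_dataset()] objects.
#' @return Pearson correlation coefficient.
#' @export
dataset_correlation <- function(ds1, ds2) {
  stopifnot(inherits(ds1, "expr_dataset"), inherits(ds2, "expr_dataset"))
  common <- intersect(rownames(ds1$values), rownames(ds2$values))
  if (length(common) < 3L)
    stop("need at least 3 common genes, got ", length(common),
         call. = FALSE)
  m1 <- rowMeans(ds1$values[common, , drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(ds2$values[common, , drop = FALSE], na.rm = TRUE)
  cor(m1, m2)
}
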