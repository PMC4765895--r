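test_that("read_expression parses a toy TSV and validates its inputs", {
  expr_file <- withr::local_tempfile(fileext = ".tsv")
  pheno_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "gA\t1\t2\t3\t4",
               "gB\t5\t6\t7\t8",
               "gC\t2\t2\t2\t9"), expr_file)
  writeLines(c("s1\tnormal", "s2\tnormal", "s3\tcancer", "s4\tcancer"),
             pheno_file)
  ds <- read_expression(expr_file, pheno_file, dataset_id = "toy")
  expect_s3_class(ds, "expr_dataset")
  expect_equal(dim(ds$values), c(3L, 4L))
  expect_equal(rownames(ds$values), c("gA", "gB", "gC"))
  expect_equal(as.character(ds$phenotype),
               c("normal", "normal", "cancer", "cancer"))

  # sample missing from the phenotype file
  writeLines(c("s1\tnormal", "s2\tnormal", "s3\tcancer"), pheno_file)
  expect_error(read_expression(expr_file, pheno_file), "missing")

  # duplicated gene row is reported by name
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "gA\t1\t2\t3\t4",
               "gA\t5\t6\t7\t8"), expr_file)
  writeLines(c("s1\tnormal", "s2\tnormal", "s3\tcancer", "s4\tcancer"),
             pheno_file)
  expect_error(read_expression(expr_file, pheno_file), "gA")
})

test_that("expression_dataset rejects unknown labels and single-class data", {
  vals <- matrix(1:8, 2, 4,
                 dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(expression_dataset(vals, c("normal", "normal", "tumour",
                                          "cancer")),
               "unknown phenotype")
  expect_error(expression_dataset(vals, rep("cancer", 4)), "non-empty")
  expect_error(expression_dataset(vals, c("normal", "cancer")), "length")
})

test_that("normalize_expression log2-transforms only raw-scale data", {
  vals <- matrix(c(400, 600, 500, 700, 300, 800, 450, 550), 2, 4,
                 dimnames = list(c("a", "b"), paste0("s", 1:4)))
  ds <- expression_dataset(vals, c("normal", "normal", "cancer", "cancer"))
  out <- normalize_expression(ds)
  expect_equal(out$values, log2(vals + 1))

  # already on log scale (median 8): untouched
  ds_log <- expression_dataset(vals / 64, c("normal", "normal",
                                            "cancer", "cancer"))
  expect_equal(normalize_expression(ds_log)$values, vals / 64)

  # negative values are incompatible with the transform
  vals_neg <- vals; vals_neg[1, 1] <- -1
  ds_neg <- expression_dataset(vals_neg, c("normal", "normal",
                                           "cancer", "cancer"))
  expect_error(normalize_expression(ds_neg), "negative")
})

test_that("normalize_expression drops over-missing genes and imputes the rest", {
  set.seed(1)
  vals <- matrix(rnorm(30, 8), 3, 10,
                 dimnames = list(c("keep", "drop", "impute"),
                                 paste0("s", 1:10)))
  vals["drop", 1:3] <- NA      # 30% missing > 20% threshold
  vals["impute", 2] <- NA      # 10% missing: imputed
  ds <- expression_dataset(vals, rep(c("normal", "cancer"), each = 5))
  out <- normalize_expression(ds, null_fraction_max = 0.2)
  expect_equal(rownames(out$values), c("keep", "impute"))
  expect_false(anyNA(out$values))
  # imputed with the gene's per-class (normal) mean
  expect_equal(out$values["impute", "s2"],
               mean(vals["impute", c(1, 3, 4, 5)]))
})

test_that("bh_fdr implements the BH step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p & q <= 1))
    expect_true(all(order(p) == order(p)[order(q[order(p)])] |
                      !is.unsorted(q[order(p)])))  # order-preserving
  }
})

test_that("moderated t with d0 = 0 reduces to the ordinary two-sample t-test", {
  ds <- toy_dataset(n_genes = 30, n_normal = 6, n_cancer = 6, seed = 3)
  sig <- differential_expression(ds, d0 = 0)
  classic <- apply(ds$values, 1L, function(x)
    stats::t.test(x[ds$phenotype == "cancer"],
                  x[ds$phenotype == "normal"],
                  var.equal = TRUE)$p.value)
  expect_equal(sig$table$p, unname(classic), tolerance = 1e-12)
})

test_that("signature membership honors both the fdr and fold-change gates", {
  # 40 null genes plus one strong and one below-threshold shifted gene
  set.seed(8)
  vals <- matrix(rnorm(42 * 20, 8, 0.2), 42, 20,
                 dimnames = list(sprintf("g%02d", 1:42), paste0("s", 1:20)))
  cancer <- 11:20
  vals["g01", cancer] <- vals["g01", cancer] + 3    # clear up gene
  vals["g02", cancer] <- vals["g02", cancer] + 0.7  # significant, small FC
  ds <- expression_dataset(vals, rep(c("normal", "cancer"), each = 10))
  sig <- differential_expression(ds)
  expect_true("g01" %in% sig$up)
  g02 <- sig$table[sig$table$gene == "g02", ]
  expect_lt(g02$fdr, 0.01)            # significant ...
  expect_false("g02" %in% sig$up)     # ... but fails |log2FC| > 1
  expect_length(sig$down, 0)
})

test_that("signature is invariant to row and column permutations", {
  ds <- toy_dataset(n_genes = 40, n_normal = 8, n_cancer = 8, seed = 5,
                    sd = 0.3)
  ds$values["g05", ds$phenotype == "cancer"] <-
    ds$values["g05", ds$phenotype == "cancer"] + 2.5
  set.seed(11)
  perm_g <- sample(nrow(ds$values))
  perm_s <- sample(ncol(ds$values))
  ds2 <- expression_dataset(ds$values[perm_g, perm_s],
                            ds$phenotype[perm_s])
  s1 <- differential_expression(ds)
  s2 <- differential_expression(ds2)
  expect_setequal(s1$up, s2$up)
  expect_setequal(s1$down, s2$down)
  expect_true("g05" %in% s1$up)
})

test_that("differential expression requires two samples per class", {
  vals <- matrix(rnorm(12, 8), 3, 4,
                 dimnames = list(letters[1:3], paste0("s", 1:4)))
  ds <- expression_dataset(vals, c("normal", "cancer", "cancer", "cancer"))
  expect_error(differential_expression(ds), "at least 2 samples")
})

test_that("dataset_correlation is 1 for identical and affine profiles", {
  ds <- toy_dataset(n_genes = 30, seed = 6)
  expect_equal(dataset_correlation(ds, ds), 1)
  ds2 <- ds
  ds2$values <- 2.5 * ds$values + 3
  expect_equal(dataset_correlation(ds, ds2), 1)

  small <- expression_dataset(
    matrix(rnorm(8, 8), 2, 4,
           dimnames = list(c("g01", "g02"), paste0("t", 1:4))),
    rep(c("normal", "cancer"), each = 2))
  expect_error(dataset_correlation(ds, small), "common genes")
})

test_that("independent synthetic datasets sharing planted structure correlate", {
  cfg <- small_config(seed = 5)
  sim <- generate_expression(cfg)
  pcc <- dataset_correlation(sim$datasets[[1]], sim$datasets[[2]])
  # direct formula on common genes
  m1 <- rowMeans(sim$datasets[[1]]$values, na.rm = TRUE)
  m2 <- rowMeans(sim$datasets[[2]]$values, na.rm = TRUE)
  expect_equal(pcc, cor(m1, m2))
  expect_gt(pcc, 0)
})

test_that("moderated-t results are concordant with limma on the same data", {
  skip_if_not_installed("limma")
  ds <- toy_dataset(n_genes = 60, n_normal = 8, n_cancer = 8, seed = 13,
                    sd = 0.5)
  ds$values["g03", ds$phenotype == "cancer"] <-
    ds$values["g03", ds$phenotype == "cancer"] + 2
  sig <- differential_expression(ds)
  design <- stats::model.matrix(~ ds$phenotype)
  fit <- limma::eBayes(limma::lmFit(ds$values, design))
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  # identical effect estimates; strongly concordant evidence ordering
  expect_equal(sig$table$log2fc, unname(tab$logFC), tolerance = 1e-10)
  expect_gt(cor(rank(sig$table$p), rank(tab$P.Value),
                method = "spearman"), 0.95)
  expect_equal(which.min(sig$table$p), which.min(tab$P.Value))
})
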