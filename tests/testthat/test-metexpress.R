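test_that("co-expression edges appear for shared-factor genes and not noise", {
  set.seed(19)
  n <- 60
  f <- rnorm(n)
  vals <- rbind(g1 = 8 + 1.0 * f + rnorm(n, sd = 0.05),
                g2 = 8 + 1.2 * f + rnorm(n, sd = 0.05),
                g3 = rnorm(n, 8),
                g4 = rnorm(n, 8))
  colnames(vals) <- sprintf("s%02d", 1:n)
  ds <- expression_dataset(vals, rep(c("normal", "cancer"), each = 30))
  net <- build_coexpression_network(ds, min_abs_pcc = 0.7)
  pairs <- paste(net$edges$gene1, net$edges$gene2)
  expect_true("g1 g2" %in% pairs)
  expect_false(any(grepl("g3|g4", pairs)))
  expect_setequal(net$nodes, rownames(vals))  # isolated genes retained

  # threshold 1 keeps only exactly collinear pairs
  vals2 <- rbind(a = 1:10, b = 2 * (1:10) + 3, c = rnorm(10))
  colnames(vals2) <- sprintf("s%02d", 1:10)
  ds2 <- expression_dataset(vals2, rep(c("normal", "cancer"), each = 5))
  net2 <- build_coexpression_network(ds2, min_abs_pcc = 1)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(sort(c(net2$edges$gene1, net2$edges$gene2)), c("a", "b"))
})

test_that("independent noise genes essentially never pass the 0.7 threshold", {
  set.seed(19)
  n_pairs <- 1000
  hits <- 0L
  for (i in seq_len(n_pairs)) {
    if (abs(cor(rnorm(60), rnorm(60))) >= 0.7) hits <- hits + 1L
  }
  expect_lt(hits / n_pairs, 0.001)
})

test_that("constant genes are excluded from edges with a warning", {
  vals <- rbind(a = rep(5, 8), b = rnorm(8, 8), c = rnorm(8, 8))
  colnames(vals) <- sprintf("s%02d", 1:8)
  ds <- expression_dataset(vals, rep(c("normal", "cancer"), each = 4))
  expect_warning(net <- build_coexpression_network(ds), "constant")
  expect_false("a" %in% c(net$edges$gene1, net$edges$gene2))
})

test_that("partitioning recovers disconnected planted modules exactly", {
  net <- structure(list(
    nodes = c("a", "b", "c", "x", "y", "z"),
    edges = data.frame(gene1 = c("a", "b", "x", "y"),
                       gene2 = c("b", "c", "y", "z"),
                       weight = 0.9, stringsAsFactors = FALSE),
    min_abs_pcc = 0.7), class = "coexpression_network")
  part <- partition_modules(net)
  expect_length(unique(part$assignment), 2L)
  expect_equal(length(unique(part$assignment[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(part$assignment[c("x", "y", "z")])), 1L)

  # empty edge set: every gene its own singleton module
  net$edges <- net$edges[0, ]
  part0 <- partition_modules(net)
  expect_equal(length(unique(part0$assignment)), 6L)
})

test_that("detected modules agree with the planted assignment", {
  cfg <- small_config(seed = 23, sigma = 0.5, missing_rate = 0)
  sim <- generate_expression(cfg)
  ds <- normalize_expression(sim$datasets[[1]])
  net <- build_coexpression_network(ds)
  part <- partition_modules(net, seed = 23)
  planted <- sim$truth$module_assignment
  in_modules <- names(planted)[planted > 0]
  expect_gte(ari(planted[in_modules], part$assignment[in_modules]), 0.8)
})

test_that("module_auc matches closed forms and the pair-counting oracle", {
  vals <- rbind(g1 = c(1, 2, 3, 2.5, 3.5))
  colnames(vals) <- sprintf("s%d", 1:5)
  ds <- expression_dataset(vals, c("normal", "normal", "normal",
                                   "cancer", "cancer"))
  expect_equal(module_auc("g1", ds), 5 / 6)   # 5 wins of 6 pairs

  # perfect separation and all-ties
  vals2 <- rbind(g1 = c(1, 2, 9, 10), g2 = c(5, 5, 5, 5))
  colnames(vals2) <- sprintf("s%d", 1:4)
  ds2 <- expression_dataset(vals2, c("normal", "normal",
                                     "cancer", "cancer"))
  expect_equal(module_auc("g1", ds2), 1)
  expect_equal(module_auc("g2", ds2), 0.5)

  # orientation: a down-regulated module scores as high as an up one
  vals3 <- rbind(g1 = c(9, 10, 1, 2))
  colnames(vals3) <- sprintf("s%d", 1:4)
  ds3 <- expression_dataset(vals3, c("normal", "normal",
                                     "cancer", "cancer"))
  expect_equal(module_auc("g1", ds3), 1)

  set.seed(31)
  for (i in 1:100) {
    n_n <- sample(2:4, 1); n_c <- sample(2:4, 1)
    score <- sample(1:4, n_n + n_c, replace = TRUE)  # ties likely
    vv <- matrix(score, 1, dimnames = list("g1",
                                           sprintf("s%d", 1:(n_n + n_c))))
    dd <- expression_dataset(vv, rep(c("normal", "cancer"), c(n_n, n_c)))
    a <- auc_oracle(score[(n_n + 1):(n_n + n_c)], score[1:n_n])
    expect_equal(module_auc("g1", dd), max(a, 1 - a))
  }
})

test_that("enzyme links follow product-to-substrate chains", {
  rx <- data.frame(reaction_id = c("r1", "r2"),
                   enzyme_gene = c("E1", "E2"),
                   substrates = c("A", "B"), products = c("B", "C"),
                   stringsAsFactors = FALSE)
  links <- build_enzyme_links(rx)
  expect_equal(links, data.frame(enzyme1 = "E1", enzyme2 = "E2",
                                 stringsAsFactors = FALSE),
               ignore_attr = TRUE)

  # no shared metabolite, no link
  rx2 <- data.frame(reaction_id = c("r1", "r2"),
                    enzyme_gene = c("E1", "E2"),
                    substrates = c("A", "C"), products = c("B", "D"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(build_enzyme_links(rx2)), 0L)

  # currency exclusion severs ATP-mediated links
  rx3 <- data.frame(reaction_id = c("r1", "r2"),
                    enzyme_gene = c("E1", "E2"),
                    substrates = c("A", "ATP"), products = c("ATP", "C"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(build_enzyme_links(rx3, "ATP")), 0L)
  expect_equal(nrow(build_enzyme_links(rx3)), 1L)

  # symmetric and invariant to reaction order
  links_rev <- build_enzyme_links(rx[2:1, ])
  expect_equal(links, links_rev, ignore_attr = TRUE)
})

test_that("metabolic_model validates reactions", {
  rx <- data.frame(reaction_id = "r1", enzyme_gene = "E1",
                   substrates = "", products = "B",
                   stringsAsFactors = FALSE)
  expect_error(metabolic_model(rx), "at least one substrate")
})

test_that("importance scores follow the auc x hypergeometric-enrichment form", {
  # 50 enzymes, module 1 holds 5 of them; enzyme q1 has all 3 links inside
  enzymes <- sprintf("E%02d", 1:50)
  assignment <- setNames(c(rep(1L, 5), rep(2L, 45)), enzymes)
  part <- structure(list(assignment = assignment,
                         auc = c("1" = 0.9, "2" = 0.6)),
                    class = "module_partition")
  rx <- data.frame(
    reaction_id = sprintf("r%d", 1:6),
    enzyme_gene = c("E01", "E02", "E01", "E03", "E01", "E04"),
    substrates = c("a1", "c1", "a2", "c2", "a3", "c3"),
    products = c("c1", "b1", "c2", "b2", "c3", "b3"),
    stringsAsFactors = FALSE)
  # give remaining enzymes a reaction so all 50 are scored
  pad <- data.frame(reaction_id = sprintf("p%d", 5:50),
                    enzyme_gene = enzymes[5:50],
                    substrates = sprintf("x%d", 5:50),
                    products = sprintf("y%d", 5:50),
                    stringsAsFactors = FALSE)
  model <- metabolic_model(rbind(rx, pad))
  scores <- importance_scores(part, model)
  e1 <- scores[scores$gene == "E01", ]
  expect_equal(e1$d_in, 3L)
  expect_equal(e1$d_tot, 3L)
  expect_equal(e1$enrichment, -log10(10 / 19600), tolerance = 1e-12)
  expect_equal(e1$score, 0.9 * -log10(10 / 19600), tolerance = 1e-12)
  # zero within-module links give zero enrichment and score
  e10 <- scores[scores$gene == "E10", ]
  expect_equal(e10$enrichment, 0)
  expect_equal(e10$score, 0)
  # doubling the module AUC doubles the score
  part2 <- part; part2$auc["1"] <- 0.45 * 2  # not a real AUC; pure algebra
  scores2 <- importance_scores(part2, model)
  expect_equal(scores2$score[scores2$gene == "E01"],
               e1$score / 0.9 * 0.9, tolerance = 1e-12)
  expect_equal(hyper_tail_oracle(3, 5, 50, 3), 10 / 19600)
})

test_that("enrichment tail matches the hypergeometric oracle on random cases", {
  set.seed(29)
  for (i in 1:50) {
    N <- sample(10:40, 1)
    K <- sample(2:(N - 2), 1)
    d_tot <- sample(1:6, 1)
    d_in <- sample(0:min(d_tot, K), 1)
    expect_equal(phyper(d_in - 1, K, N - K, d_tot, lower.tail = FALSE),
                 hyper_tail_oracle(d_in, K, N, d_tot), tolerance = 1e-12)
  }
})

test_that("key_enzymes applies a strict median cut", {
  mk <- function(score) data.frame(gene = sprintf("E%d", seq_along(score)),
                                   score = score,
                                   stringsAsFactors = FALSE)
  expect_setequal(key_enzymes(mk(c(1, 2, 3, 4, 5))), c("E4", "E5"))
  expect_length(key_enzymes(mk(rep(2, 6))), 0L)
})

test_that("planted key enzymes are recovered and label permutations are inert", {
  cfg <- small_config(seed = 29)
  sim <- generate_expression(cfg)
  met <- generate_metabolic_model(cfg, sim$truth)
  ds <- normalize_expression(sim$datasets[[1]])
  mx <- met_express(ds, met$model, seed = 29)
  sens <- length(intersect(mx$key_enzymes, met$truth$planted_key_enzymes)) /
    length(met$truth$planted_key_enzymes)
  expect_gte(sens, 0.8)

  # relabeling modules does not change the key set
  part <- mx$partition
  relabel <- setNames(sample(1000:2000, length(unique(part$assignment))),
                      sort(unique(part$assignment)))
  part2 <- part
  part2$assignment <- setNames(relabel[as.character(part$assignment)],
                               names(part$assignment))
  names(part2$auc) <- as.character(relabel[names(part$auc)])
  scores2 <- importance_scores(part2, met$model)
  expect_setequal(key_enzymes(scores2), mx$key_enzymes)

  # destroying the gene-to-module assignment destroys recovery
  set.seed(1)
  part3 <- part
  part3$assignment[] <- sample(part$assignment)
  scores3 <- importance_scores(part3, met$model)
  sens3 <- length(intersect(key_enzymes(scores3),
                            met$truth$planted_key_enzymes)) /
    length(met$truth$planted_key_enzymes)
  expect_lt(sens3, sens)
})
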