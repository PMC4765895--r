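# Independent brute-force oracles used against the package implementations.

# Signed KS statistic by naive loops over the two max-expressions.
ks_oracle <- function(positions, n) {
  v <- sort(positions)
  t <- length(v)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# Benjamini-Hochberg step-up by its definition: q_i = min_{j: p_(j) >= p_(i)}
# min(1, n * p_(j) / j), realized as a backward running minimum.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, n * p[o] / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# ROC AUC by exhaustive pair counting (ties count one half).
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Hypergeometric upper-tail P(X >= k) by direct enumeration.
hyper_tail_oracle <- function(k, set_size, universe, draws) {
  kk <- k:min(draws, set_size)
  sum(choose(set_size, kk) * choose(universe - set_size, draws - kk)) /
    choose(universe, draws)
}

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  tot <- choose(sum(tab), 2)
  expected <- sa * sb / tot
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# Small expression dataset with a prescribed gene/sample layout.
toy_dataset <- function(n_genes = 20, n_normal = 5, n_cancer = 5,
                        seed = 42, sd = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * (n_normal + n_cancer), mean = 8, sd = sd),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d",
                                         seq_len(n_normal + n_cancer))))
  expression_dataset(
    vals, rep(c("normal", "cancer"), c(n_normal, n_cancer)),
    dataset_id = "toy")
}

# Reduced-scale simulation config for fast tests; ... overrides defaults.
small_config <- function(...) {
  args <- list(n_genes = 400, n_normal = 12, n_cancer = 12,
               n_datasets = 2, n_modules = 4,
               module_size_range = c(15, 30), n_drugs = 30,
               instances_per_drug = 3, n_reversers = 4,
               n_enzymes = 50, n_reactions = 80,
               n_planted_key_enzymes = 6, n_planted_candidates = 3,
               missing_rate = 0.01)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
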