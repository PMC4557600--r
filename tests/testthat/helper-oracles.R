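# Independent oracles used across the suite. Each is deliberately written
# from the defining arithmetic, not from the library routine it checks.

# Benjamini-Hochberg step-up by hand: sort descending, p * m / rank,
# cumulative minimum, clip at 1, return in original order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Hypergeometric upper tail by support enumeration of the pmf,
# each term from binomial coefficients.
hyper_oracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), 0))
}

# Two-sided Fisher's exact p for a 2x2 table by exact enumeration over the
# hypergeometric support: sum the probabilities of all tables with the
# observed margins whose probability does not exceed the observed one.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), 0)
  p_obs <- pr[support == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Spearman rho as Pearson on average ranks, written from the sum formulas.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# tiny expression matrix fixture
tiny_matrix <- function(values, ids, samples, kind = "miRNA") {
  m <- matrix(values, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, samples))
  expression_matrix(m, kind)
}

# minimal one-cell-line design: n_bio biological x n_tech technical per arm
tiny_design <- function(n_bio = 3, n_tech = 2, cell_line = "HN1957") {
  default_design <- getFromNamespace("default_design", "miRmRNet")
  cfg <- sim_config(n_mirna = 1, n_mrna = 1, cell_lines = cell_line,
                    n_bio = n_bio, n_tech = n_tech, n_de_mirna = 0,
                    n_de_mrna = 0, n_edges = 0)
  default_design(cfg)
}
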