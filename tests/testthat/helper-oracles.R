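# independent oracles used across the suite; deliberately naive
# implementations that share no code with the package internals

# random genes x samples matrix with unique dimnames
toy_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 6, 2), n_genes, n_samples)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}

# position-by-position running-sum enrichment for ONE sample: walk the
# descending-expression gene list accumulating the weighted in-set CDF minus
# the uniform out-of-set CDF, term by term
ssgsea_oracle_one <- function(x, gene_ids, set, alpha) {
  ord <- order(-x, gene_ids)
  rnk <- rank(x, ties.method = "average")
  inset <- gene_ids[ord] %in% set
  w_sum <- sum(rnk[ord][inset]^alpha)
  n_out <- sum(!inset)
  cum_in <- 0
  cum_out <- 0
  es <- 0
  for (pos in seq_along(ord)) {
    if (inset[pos]) {
      cum_in <- cum_in + rnk[ord][pos]^alpha / w_sum
    } else {
      cum_out <- cum_out + 1 / n_out
    }
    es <- es + (cum_in - cum_out)
  }
  es
}

ssgsea_oracle <- function(expr, set, alpha = 0.25) {
  vapply(seq_len(ncol(expr)), function(j) {
    ssgsea_oracle_one(expr[, j], rownames(expr), set, alpha)
  }, numeric(1))
}

# Monte-Carlo oracle for the rank-aggregation rho: each order-statistic
# tail P(at least k of m uniforms <= r_(k)) is estimated by simulation and
# the minimum over k taken, mirroring the closed form without using it
rra_mc_oracle <- function(r_obs, n_draws = 1e5, seed = 1) {
  m <- length(r_obs)
  r <- sort(r_obs)
  withr::with_seed(seed, {
    U <- matrix(runif(n_draws * m), n_draws, m)
    p_k <- vapply(seq_len(m), function(k) {
      mean(rowSums(U <= r[k]) >= k)
    }, numeric(1))
    k_min <- which.min(p_k)
    list(rho_mc = p_k[k_min],
         se = sqrt(p_k[k_min] * (1 - p_k[k_min]) / n_draws))
  })
}

# Mann-Whitney pairwise concordance count with half credit for ties
auc_pair_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  conc <- 0
  for (a in pos) for (b in neg) {
    conc <- conc + (a > b) + 0.5 * (a == b)
  }
  conc / (length(pos) * length(neg))
}

# small standard split used by model-search tests
split3 <- function() {
  list(training = "cohort01", internal = "cohort02", external = "cohort03")
}
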