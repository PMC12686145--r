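test_that("running-sum scorer matches the position-by-position oracle", {
  for (r in 1:50) {
    n_g <- withr::with_seed(r, sample(5:100, 1))
    n_s <- withr::with_seed(r + 500, sample(1:10, 1))
    expr <- toy_expr(n_g, n_s, seed = r)
    set <- withr::with_seed(r + 1000,
                            sample(rownames(expr), sample(2:min(10, n_g - 1), 1)))
    alpha <- c(0.25, 1)[r %% 2 + 1]
    got <- ssgsea_score(expr, set, alpha = alpha)
    want <- ssgsea_oracle(expr, set, alpha = alpha)
    expect_equal(unname(as.numeric(got)), want, tolerance = 1e-9)
  }
})

test_that("scores are rank-based and order-invariant", {
  expr <- toy_expr(40, 5, seed = 2)
  set <- rownames(expr)[c(3, 9, 22)]
  base <- ssgsea_score(expr, set)

  # strictly increasing transform of one sample leaves its score unchanged
  expr2 <- expr
  expr2[, 2] <- exp(expr2[, 2] / 3) + 5
  expect_equal(ssgsea_score(expr2, set)[[2]], base[[2]])

  # permuting gene rows and sample columns changes nothing (up to names)
  perm <- withr::with_seed(1, expr[sample(nrow(expr)), sample(ncol(expr))])
  got <- ssgsea_score(perm, set)
  expect_equal(as.numeric(got[names(base)]), as.numeric(base))

  # a set occupying the top |S| ranks beats the same set at the bottom
  x <- matrix(seq(10, 1), ncol = 1,
              dimnames = list(paste0("g", 1:10), "s1"))
  top <- ssgsea_score(x, paste0("g", 1:3))
  bottom <- ssgsea_score(x, paste0("g", 8:10))
  expect_gt(top[[1]], bottom[[1]])
})

test_that("scorer errors and normalization behave as documented", {
  expr <- toy_expr(20, 4, seed = 3)
  expect_error(ssgsea_score(expr, c("nope1", "nope2")), "no genes")
  raw <- ssgsea_score(expr, rownames(expr)[1:4])
  norm <- ssgsea_score(expr, rownames(expr)[1:4], normalize = TRUE)
  expect_equal(as.numeric(norm),
               as.numeric(raw) / (max(raw) - min(raw)))
  const <- expr
  const[, 1] <- 1
  expect_warning(ssgsea_score(const, rownames(expr)[1:4]), "constant")
})

test_that("mean module score is location-invariant and centred on nulls", {
  expr <- toy_expr(200, 8, seed = 4)
  set <- rownames(expr)[1:10]
  s <- mean_module_score(expr, set, n_control = 20, seed = 1)

  # adding a constant to every gene of one sample leaves its score unchanged
  shifted <- expr
  shifted[, 3] <- shifted[, 3] + 7
  s2 <- mean_module_score(shifted, set, n_control = 20, seed = 1)
  expect_equal(s2[[3]], s[[3]])

  # planted up-set scores higher in non-responders, matching group means
  sim <- simulate_cohorts(n_cohorts = 1, samples_per_cohort = 80,
                          n_genes = 150, n_up = 15, n_down = 0,
                          effect_size = 1.5, seed = 5)
  co <- sim$cohorts[[1]]
  ms <- mean_module_score(co$expr, sim$truth$up_genes, seed = 2)
  nr <- co$labels == "NR"
  expect_gt(mean(ms[nr]), mean(ms[!nr]))
  direct <- colMeans(co$expr[sim$truth$up_genes, ])
  expect_gt(mean(direct[nr]), mean(direct[!nr]))
})

test_that("signature score is antisymmetric and self-cancelling", {
  expr <- toy_expr(60, 6, seed = 6)
  up <- rownames(expr)[1:6]
  down <- rownames(expr)[11:16]
  for (scorer in c("ssgsea", "module")) {
    args <- if (scorer == "module") list(seed = 3, n_control = 10) else list()
    s <- do.call(caf_sig_score,
                 c(list(expr, list(up = up, down = down), scorer = scorer),
                   args))
    sw <- do.call(caf_sig_score,
                  c(list(expr, list(up = down, down = up), scorer = scorer),
                    args))
    expect_equal(as.numeric(sw), -as.numeric(s))
    self <- do.call(caf_sig_score,
                    c(list(expr, list(up = up, down = up), scorer = scorer,
                           validate = FALSE), args))
    expect_equal(as.numeric(self), rep(0, ncol(expr)))
  }
  expect_error(caf_sig_score(expr, list(up = up, down = up)), "overlap")
})

test_that("planted signature separates responders at effect 1.5", {
  sim <- simulate_cohorts(n_cohorts = 1, samples_per_cohort = 100,
                          n_genes = 200, n_up = 20, n_down = 20,
                          effect_size = 1.5, seed = 8)
  co <- sim$cohorts[[1]]
  sc <- caf_sig_score(co$expr, list(up = sim$truth$up_genes,
                                    down = sim$truth$down_genes))
  expect_gte(roc_auc(sc, co$labels)$auc, 0.85)
})

test_that("signature partition follows group means and recovers truth", {
  expr <- matrix(c(8, 8, 6, 6,   # gene up in NR
                   5, 5, 7, 7,   # gene down in NR
                   4, 4, 4, 4),  # exact tie -> excluded
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("gu", "gd", "gt"), paste0("s", 1:4)))
  labels <- c("NR", "NR", "R", "R")
  part <- partition_signature(expr, labels, c("gu", "gd", "gt"))
  expect_identical(part$up, "gu")
  expect_identical(part$down, "gd")
  expect_identical(part$excluded, "gt")
  expect_warning(partition_signature(expr, labels, c("gu", "missing")),
                 "absent")

  sim <- simulate_cohorts(n_cohorts = 1, samples_per_cohort = 200,
                          n_genes = 100, n_up = 20, n_down = 20,
                          effect_size = 1.5, seed = 10)
  co <- sim$cohorts[[1]]
  part <- partition_signature(co$expr, co$labels,
                              c(sim$truth$up_genes, sim$truth$down_genes))
  correct <- mean(c(sim$truth$up_genes %in% part$up,
                    sim$truth$down_genes %in% part$down))
  expect_gte(correct, 0.95)
})

test_that("QC filter applies the four strict rules and logs each", {
  # boundary survivors: thresholds themselves are not violations
  edge <- data.frame(cell_id = c("b1", "b2"),
                     umi_count = c(40000, 10000),
                     n_genes = c(2000, 500),
                     pct_mito = c(20, 20))
  expect_equal(nrow(qc_filter(edge)$removed), 0)

  over <- data.frame(cell_id = "c", umi_count = 40001, n_genes = 2000,
                     pct_mito = 5)
  res <- qc_filter(over)
  expect_equal(res$removed$cell_id, "c")
  expect_equal(res$log$rules, "umi_high")

  # one violator per rule plus two clean cells -> 2 retained
  toy <- data.frame(
    cell_id = paste0("c", 1:6),
    umi_count = c(50000, 1000, 1000, 1000, 1000, 2000),
    n_genes = c(2000, 400, 6000, 2000, 2000, 3000),
    pct_mito = c(5, 5, 5, 30, 5, 10))
  res <- qc_filter(toy)
  expect_equal(nrow(res$retained), 2)
  expect_setequal(res$retained$cell_id, c("c5", "c6"))
  expect_equal(res$log$rules[res$log$cell_id == "c1"], "umi_high")
  expect_equal(res$log$rules[res$log$cell_id == "c2"], "gene_low")
  expect_equal(res$log$rules[res$log$cell_id == "c3"], "gene_high")
  expect_equal(res$log$rules[res$log$cell_id == "c4"], "mito_high")

  # retained and removed partition the input
  expect_setequal(c(res$retained$cell_id, res$removed$cell_id), toy$cell_id)
  expect_length(intersect(res$retained$cell_id, res$removed$cell_id), 0)

  bad <- toy
  bad$umi_count[1] <- -1
  expect_error(qc_filter(bad), "non-negative")
})
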