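test_that("the default grid enumerates 113 combinations deterministically", {
  reg <- algorithm_registry()
  grid <- build_grid(reg)
  expect_equal(nrow(grid), 113)
  expect_false(anyDuplicated(grid$combo_id) > 0)
  expect_identical(grid, build_grid(reg))

  # 1 x 1 and 2 x 3 product manifests
  m1 <- data.frame(selector = "lasso", classifier = "lda")
  expect_equal(nrow(build_grid(reg, m1)), 1)
  m6 <- expand.grid(selector = c("lasso", "enet"),
                    classifier = c("lda", "nb", "svm"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(build_grid(reg, m6)), 6)

  expect_error(build_grid(reg, data.frame(selector = "magic",
                                          classifier = "lda")),
               "unregistered")
  expect_error(build_grid(reg, "not_a_combo"), "unknown combo")
})

test_that("LOOCV AUC matches an explicit hand-rolled leave-one-out loop", {
  X <- withr::with_seed(1, matrix(rnorm(12 * 4), 12, 4,
                                  dimnames = list(NULL, paste0("g", 1:4))))
  y <- rep(c(0, 1), 6)
  X[y == 1, 1] <- X[y == 1, 1] + 1.5
  fit <- function(X, y) {
    glm.fit(cbind(1, X), y, family = binomial())
  }
  pred <- function(m, X) as.numeric(cbind(1, X) %*% coef(m))
  got <- loocv_auc(X, y, fit, pred)
  # independent loop
  held <- numeric(12)
  for (i in 1:12) {
    m <- glm(y[-i] ~ X[-i, , drop = FALSE], family = binomial())
    b <- coef(m)
    held[i] <- b[1] + sum(b[-1] * X[i, ])
  }
  expect_equal(got, auc_pair_oracle(held, y))

  expect_error(loocv_auc(X[1:5, ], y[1:5], fit, pred), "at least 6")
  expect_error(loocv_auc(X, rep(0, 12), fit, pred), "both classes")
  expect_error(loocv_auc(X, c(1, rep(0, 11)), fit, pred), ">= 2")
})

test_that("LOOCV AUC is near 0.5 when labels are independent of features", {
  aucs <- vapply(1:50, function(r) {
    withr::with_seed(r, {
      X <- matrix(rnorm(60 * 3), 60, 3,
                  dimnames = list(NULL, paste0("g", 1:3)))
      y <- rbinom(60, 1, 0.5)
      if (sum(y) < 2 || sum(1 - y) < 2) y <- rep(c(0, 1), 30)
      loocv_auc(X, y,
                function(X, y) glm.fit(cbind(1, X), y, family = binomial()),
                function(m, X) as.numeric(cbind(1, X) %*% coef(m)))
    })
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("run_combo applies the fewer-than-five-genes omission rule", {
  sim <- simulate_cohorts(n_cohorts = 3, samples_per_cohort = 30,
                          n_genes = 40, n_up = 5, n_down = 5,
                          effect_size = 2, seed = 20)
  reg <- algorithm_registry()
  reg$selectors$tiny4 <- function(X, y, k, seed) colnames(X)[1:4]
  combo <- data.frame(combo_id = "tiny4+lda", selector = "tiny4",
                      classifier = "lda")
  res <- run_combo(combo, sim$cohorts, split3(), registry = reg, seed = 1)
  expect_true(res$omitted)
  expect_match(res$reason, "fewer than 5")
})

test_that("separable training data yields LOOCV AUC 1 for a sparse linear combo", {
  sim <- simulate_cohorts(n_cohorts = 3, samples_per_cohort = 20,
                          n_genes = 40, n_up = 5, n_down = 5,
                          effect_size = 3, seed = 21)
  res <- run_combo(data.frame(combo_id = "embedded+lasso",
                              selector = "embedded", classifier = "lasso"),
                   sim$cohorts, split3(), seed = 2)
  expect_false(res$omitted)
  expect_equal(res$loocv_auc, 1.0)
  # strong planted signal carries to the other cohorts
  expect_gt(res$group_auc[["external"]], 0.9)
})

test_that("permuted labels keep per-cohort AUCs near chance", {
  aucs <- unlist(lapply(1:5, function(r) {
    sim <- simulate_cohorts(n_cohorts = 3, samples_per_cohort = 60,
                            n_genes = 50, n_up = 5, n_down = 5,
                            effect_size = 1.5, seed = 300 + r)
    perm <- withr::with_seed(400 + r, {
      lapply(sim$cohorts, function(co) {
        co$labels <- sample(co$labels)
        co
      })
    })
    res <- run_combo(data.frame(combo_id = "lasso+lda", selector = "lasso",
                                classifier = "lda"),
                     perm, split3(), seed = 500 + r)
    if (res$omitted) NULL else res$cohort_auc
  }))
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})

test_that("leaderboard ranks by mean of group means with parsimony ties", {
  mk <- function(id, tr, int, ext, n) {
    structure(list(combo_id = id, selector = "s", classifier = "c",
                   selected_genes = paste0("g", seq_len(n)),
                   group_auc = c(training = tr, internal = int,
                                 external = ext),
                   mean_auc = mean(c(tr, int, ext)), omitted = FALSE),
              class = "fitted_combo")
  }
  fits <- list(mk("a", 0.9, 0.8, 0.7, 10),
               mk("b", 0.8, 0.8, 0.8, 7),
               mk("c", 0.6, 0.9, 0.9, 7))
  lb <- rank_models(fits)
  expect_equal(lb$mean_auc, rep(0.8, 3))
  # fewest genes first, then combo id
  expect_identical(lb$combo_id, c("b", "c", "a"))

  expect_equal(nrow(rank_models(fits[1])), 1)
  omit <- structure(list(combo_id = "z", selector = "s", classifier = "c",
                         selected_genes = character(0), omitted = TRUE,
                         mean_auc = NA_real_), class = "fitted_combo")
  expect_error(rank_models(list(omit)), "all combinations")
})

test_that("risk scores equal the stored linear combination by hand", {
  sim <- simulate_cohorts(n_cohorts = 3, samples_per_cohort = 30,
                          n_genes = 40, n_up = 6, n_down = 6,
                          effect_size = 2, seed = 22)
  res <- run_combo(data.frame(combo_id = "lasso+stepglm", selector = "lasso",
                              classifier = "stepglm"),
                   sim$cohorts, split3(), seed = 3)
  expect_false(res$omitted)
  expr <- sim$cohorts$cohort03$expr
  got <- risk_score(res, expr)

  b <- res$coefficients
  m <- expr[res$feature_genes, , drop = FALSE]
  m <- (m - rowMeans(m)) / apply(m, 1, sd)
  manual <- b[["(Intercept)"]] +
    as.numeric(t(m[setdiff(names(b), "(Intercept)"), , drop = FALSE]) %*%
                 b[setdiff(names(b), "(Intercept)")])
  expect_equal(unname(as.numeric(got)), manual)

  # strictly monotone transform of scores leaves the AUC unchanged
  y <- sim$cohorts$cohort03$labels
  expect_equal(roc_auc(got, y)$auc, roc_auc(got + got^3, y)$auc)

  # orientation: non-responders score higher at a strong effect
  expect_gt(median(got[y == "NR"]), median(got[y == "R"]))

  expect_error(risk_score(res, expr[setdiff(rownames(expr),
                                            res$selected_genes[1]), ]),
               "lacks model gene")
})

test_that("the ensemble search is deterministic and respects the gene floor", {
  sim <- simulate_cohorts(n_cohorts = 3, samples_per_cohort = 40,
                          n_genes = 60, n_up = 8, n_down = 8,
                          effect_size = 2, seed = 23)
  f1 <- caf_sig(sim$cohorts, split3(), manifest = reduced_manifest("fast8"),
                seed = 5)
  f2 <- caf_sig(sim$cohorts, split3(), manifest = reduced_manifest("fast8"),
                seed = 5)
  expect_identical(f1$leaderboard, f2$leaderboard)
  expect_true(all(f1$leaderboard$n_genes >= 5))
  expect_true(all(f1$leaderboard$mean_auc >= 0 &
                    f1$leaderboard$mean_auc <= 1))
  expect_s3_class(f1, "caf_sig")
  expect_output(print(f1), "best combination")
  # predict() routes through the best combination
  p <- predict(f1, sim$cohorts$cohort02$expr)
  expect_length(p, 40)
  expect_true(all(is.finite(p)))
})

test_that("split validation catches overlap and unknown cohorts", {
  sim <- simulate_cohorts(n_cohorts = 2, samples_per_cohort = 20,
                          n_genes = 30, n_up = 4, n_down = 4, seed = 24)
  expect_error(
    caf_sig(sim$cohorts, list(training = "cohort01", internal = "cohort01",
                              external = "cohort02")),
    "disjoint")
  expect_error(
    caf_sig(sim$cohorts, list(training = "cohort01", internal = "cohort02",
                              external = "cohortXX")),
    "unknown cohort")
})
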