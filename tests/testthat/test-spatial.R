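line_table <- function() {
  data.frame(
    cell_id = c("r1", "t1", "t2", "t3"),
    x = c(0, 1, 2, 3), y = 0,
    cell_type = c("ref", "tgt", "tgt", "tgt"),
    section_id = "s1", group = "R", stringsAsFactors = FALSE)
}

test_that("k-distance matches hand computation and geometric invariances", {
  kd <- k_distance(line_table(), "ref", "tgt", k = 2)
  expect_equal(kd$k_distance, 1.5)  # mean of distances 1 and 2

  # coincident target cells give distance zero
  co <- line_table()
  co$x <- 0
  expect_equal(k_distance(co, "ref", "tgt", k = 3)$k_distance, 0)

  # homogeneity: scaling coordinates by 2 doubles the distance
  sc <- line_table()
  sc$x <- sc$x * 2
  expect_equal(k_distance(sc, "ref", "tgt", k = 2)$k_distance, 3)

  # translation and rotation leave it unchanged
  tr <- line_table()
  tr$x <- tr$x + 10
  tr$y <- tr$y - 4
  expect_equal(k_distance(tr, "ref", "tgt", k = 2)$k_distance, 1.5)
  rot <- line_table()
  rot$y <- rot$x       # rotate the line by 90 degrees
  rot$x <- 0
  expect_equal(k_distance(rot, "ref", "tgt", k = 2)$k_distance, 1.5)

  # fewer than k targets -> missing with a warning
  expect_warning(kd4 <- k_distance(line_table(), "ref", "tgt", k = 4),
                 "fewer than k")
  expect_true(is.na(kd4$k_distance))
})

test_that("same-type queries exclude the reference cell itself", {
  tab <- data.frame(cell_id = c("a", "b", "c"),
                    x = c(0, 1, 2), y = 0, cell_type = "ref",
                    section_id = "s1", group = "R")
  kd <- k_distance(tab, "ref", "ref", k = 1)
  expect_equal(kd$k_distance, c(1, 1, 1))
})

test_that("proximity ranking orders types by median with average-rank ties", {
  kt <- data.frame(
    section_id = "s1", group = "R",
    cell_id = rep(c("r1", "r2"), 3),
    target_type = rep(c("A", "B", "C"), each = 2),
    k_distance = c(0.5, 1.5, 4, 6, 1.5, 2.5), k = 2)
  class(kt) <- c("kdist_table", "data.frame")
  R <- rank_by_proximity(kt)
  expect_equal(R["s1", ], c(A = 1, B = 3, C = 2))

  # tie -> average ranks
  kt$k_distance[5:6] <- c(0.5, 1.5)
  R2 <- rank_by_proximity(kt)
  expect_equal(R2["s1", ], c(A = 1.5, B = 3, C = 1.5))
})

test_that("rank aggregation reproduces closed-form binomial tails", {
  # a type ranked 1st of 10 in all 5 sections: rho = 0.1^5
  R <- matrix(0, 5, 10, dimnames = list(NULL, LETTERS[1:10]))
  for (s in 1:5) R[s, ] <- c(1, 1 + withr::with_seed(s, sample(9)))
  res <- rra_aggregate(R)
  expect_equal(res$rho[res$type == "A"], 1e-5, tolerance = 1e-12)
  expect_equal(res$corrected[res$type == "A"], 10 * 1e-5, tolerance = 1e-12)
  expect_identical(res$type[1], "A")
  expect_equal(res$position, seq_len(10))

  # single section: aggregate ordering equals that section's ordering
  one <- matrix(c(2, 1, 3), 1, dimnames = list(NULL, c("A", "B", "C")))
  expect_identical(rra_aggregate(one)$type, c("B", "A", "C"))

  # invariance to section (row) order
  perm <- R[c(3, 1, 5, 2, 4), ]
  expect_equal(rra_aggregate(perm), res)
})

test_that("rho agrees with a Monte-Carlo order-statistic oracle", {
  for (r in 1:5) {
    m <- withr::with_seed(r, sample(3:8, 1))
    n_types <- withr::with_seed(r + 50, sample(4:8, 1))
    ranks <- t(withr::with_seed(r + 100,
                                replicate(m, sample(n_types))))
    colnames(ranks) <- paste0("t", seq_len(n_types))
    res <- rra_aggregate(ranks)
    j <- withr::with_seed(r + 150, sample(n_types, 1))
    type <- paste0("t", j)
    mc <- rra_mc_oracle(ranks[, type] / n_types, n_draws = 2e4,
                        seed = r + 200)
    expect_lt(abs(res$rho[res$type == type] - mc$rho_mc),
              3 * mc$se + 1e-9)
  }
})

test_that("uniform-permutation null keeps corrected scores honest", {
  hits <- withr::with_seed(77, {
    vapply(1:300, function(r) {
      ranks <- t(replicate(6, sample(6)))
      colnames(ranks) <- paste0("t", 1:6)
      res <- rra_aggregate(ranks)
      sum(res$corrected < 0.05)
    }, numeric(1))
  })
  expect_lte(mean(hits) / 6, 0.05)
})

test_that("group comparison detects a planted proximity contrast", {
  tt <- data.frame(type = c("near_nr", "neutral"),
                   sigma_responder = c(5, 3),
                   sigma_nonresponder = c(1, 3))
  p_hit <- vapply(1:10, function(r) {
    s <- simulate_sections(tt, n_sections_responder = 5,
                           n_sections_nonresponder = 5,
                           cells_per_type = 50, seed = 600 + r)
    kd <- k_distance(s$cells, "iCAF", k = 2)
    cmp <- compare_groups(kd, "near_nr")
    cmp$median_diff < 0 && cmp$p_value < 0.05
  }, logical(1))
  expect_gte(mean(p_hit), 0.9)

  # permuting group labels kills significance most of the time
  s <- simulate_sections(tt, n_sections_responder = 3,
                         n_sections_nonresponder = 3,
                         cells_per_type = 40, seed = 9)
  kd <- k_distance(s$cells, "iCAF", k = 2)
  null_p <- withr::with_seed(10, {
    vapply(1:20, function(i) {
      kd2 <- kd
      secs <- unique(kd2$section_id)
      newg <- setNames(sample(rep(c("R", "NR"), length.out = length(secs))),
                       secs)
      kd2$group <- newg[kd2$section_id]
      compare_groups(kd2, "near_nr")$p_value
    }, numeric(1))
  })
  expect_gte(mean(null_p > 0.05), 0.7)
})

test_that("planted nearest type wins the aggregate ranking", {
  tt <- data.frame(type = c("A", "B", "C"),
                   sigma_responder = c(2, 6, 18),
                   sigma_nonresponder = c(2, 6, 18))
  firsts <- vapply(1:10, function(r) {
    s <- simulate_sections(tt, n_sections_responder = 5,
                           n_sections_nonresponder = 0,
                           cells_per_type = 40, seed = 700 + r)
    kd <- k_distance(s$cells, "iCAF", k = 2)
    rra_aggregate(rank_by_proximity(kd))$type[1] == "A"
  }, logical(1))
  expect_gte(mean(firsts), 0.9)
})

test_that("spatial inputs are validated", {
  tab <- line_table()
  expect_error(k_distance(tab[, -2], "ref", "tgt", 1), "columns")
  tab2 <- tab
  tab2$x[1] <- NA
  expect_error(k_distance(tab2, "ref", "tgt", 1), "finite")
  expect_error(k_distance(tab, "ghost", "tgt", 1), "no 'ghost' cells")
  expect_error(compare_groups(k_distance(tab, "ref", "tgt", 2), "tgt"),
               "both response groups")
})
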