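#' Prepare cohorts for model fitting
#'
#' Restricts all cohorts to their common gene space and applies per-cohort
#' gene-wise standardization (mean 0, SD 1 within each cohort), the
#' package's stand-in for heavier cross-cohort batch correction. Matrices
#' are transposed to samples x genes for the learners.
#'
#' @param cohorts named list; each element a list with \code{expr} (genes x
#'   samples matrix) and \code{labels} (R/NR).
#' @return list with \code{X} (named list of samples x genes matrices),
#'   \code{y} (named list of 0/1 vectors, 1 = non-responder) and
#'   \code{genes} (common gene space).
#' @export
prepare_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) == 0 || is.null(names(cohorts))) {
    stop("`cohorts` must be a non-empty named list", call. = FALSE)
  }
  genes <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$expr)))
  if (length(genes) < 2) {
    stop("cohorts share fewer than 2 genes", call. = FALSE)
  }
  X <- lapply(cohorts, function(co) {
    m <- co$expr[genes, , drop = FALSE]
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1  # constant genes become all-zero rather than NaN
    t((m - mu) / s)
  })
  y <- lapply(cohorts, function(co) response01(co$labels))
  list(X = X, y = y, genes = genes)
}

#' Leave-one-out cross-validated AUC
#'
#' For each sample i the model is fitted on all remaining samples and sample
#' i is scored; the AUC of the n held-out scores against the labels is
#' returned. Only the training side of each fold must contain both classes
#' (the held-out side is a single sample), so each class needs at least two
#' members overall.
#'
#' @param X samples x genes matrix.
#' @param y 0/1 labels (1 = non-responder) or R/NR labels.
#' @param fit function(X, y) returning a model.
#' @param predict_fn function(model, X) returning numeric scores (higher =
#'   non-responder).
#' @return the LOOCV AUC (scalar).
#' @examples
#' X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("g", 1:5)))
#' y <- rep(c(0, 1), 6)
#' f <- function(X, y) glm.fit(cbind(1, X), y, family = binomial())
#' p <- function(m, X) as.numeric(cbind(1, X) %*% coef(m))
#' loocv_auc(X, y, f, p)
#' @export
loocv_auc <- function(X, y, fit, predict_fn) {
  if (!is.numeric(y)) y <- response01(y)
  n <- nrow(X)
  if (n < 6) stop("LOOCV requires at least 6 samples", call. = FALSE)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  if (any(tab < 2)) {
    stop("each class needs >= 2 samples so every fold's training side ",
         "keeps both classes", call. = FALSE)
  }
  s <- vapply(seq_len(n), function(i) {
    m <- fit(X[-i, , drop = FALSE], y[-i])
    as.numeric(predict_fn(m, X[i, , drop = FALSE]))
  }, numeric(1))
  auc_mw(s, y)
}

## Mann-Whitney AUC with half-credit for ties; 1 = non-responder ranked top
auc_mw <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and evaluate one selector x classifier combination
#'
#' Runs the combination's feature selector on the pooled training-group
#' samples, applies the fewer-than-\code{min_genes} omission rule, tunes any
#' classifier hyperparameters by LOOCV on the training pool (chosen to
#' maximize LOOCV AUC), refits on the full training pool, and computes AUC
#' in every cohort. Training-group cohorts are scored with the LOOCV
#' held-out predictions (an honest estimate); internal/external cohorts with
#' the refitted model. For embedded combos the classifier performs its own
#' gene selection and the omission rule applies to the fitted model's genes.
#'
#' @param combo one row of \code{\link{build_grid}} output (or a list with
#'   \code{combo_id}, \code{selector}, \code{classifier}).
#' @param cohorts named list of cohorts (see \code{\link{prepare_cohorts}}).
#' @param split list with character elements \code{training},
#'   \code{internal}, \code{external} naming disjoint cohort sets.
#' @param registry an \code{\link{algorithm_registry}}.
#' @param min_genes omission threshold: models with fewer genes are dropped.
#' @param seed integer seed; stochastic learners are seeded per combo id.
#' @param strict nest feature selection inside every LOOCV fold
#'   (anti-leakage mode; slower, non-default).
#' @return object of class \code{"fitted_combo"}.
#' @export
run_combo <- function(combo, cohorts, split, registry = algorithm_registry(),
                      min_genes = 5, seed = 1, strict = FALSE) {
  prep <- prepare_cohorts(cohorts)
  run_combo_prepped(as.list(combo), prep, check_split(split, names(prep$X)),
                    registry, min_genes, seed, strict)
}

check_split <- function(split, cohort_names) {
  need <- c("training", "internal", "external")
  if (!is.list(split) || !all(need %in% names(split))) {
    stop("`split` needs elements training, internal, external", call. = FALSE)
  }
  all_ids <- unlist(split[need])
  if (anyDuplicated(all_ids)) stop("split groups must be disjoint", call. = FALSE)
  missing <- setdiff(all_ids, cohort_names)
  if (length(missing) > 0) {
    stop("split references unknown cohort(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(lengths(split[need]) == 0)) {
    stop("every split group must be non-empty", call. = FALSE)
  }
  split[need]
}

run_combo_prepped <- function(combo, prep, split, registry, min_genes, seed,
                              strict = FALSE) {
  id <- combo$combo_id
  cls <- registry$classifiers[[combo$classifier]]
  Xtr <- do.call(rbind, prep$X[split$training])
  ytr <- unlist(prep$y[split$training], use.names = FALSE)
  if (length(unique(ytr)) < 2) {
    stop("training group has a single response class", call. = FALSE)
  }
  embedded <- identical(combo$selector, "embedded")

  select_fun <- if (embedded) {
    function(X, y) colnames(X)
  } else {
    sel <- registry$selectors[[combo$selector]]
    function(X, y) sel(X, y, k = registry$top_k,
                       seed = derive_seed(seed, paste0(id, ":sel")))
  }
  selected <- select_fun(Xtr, ytr)

  omit_result <- function(n_found, what) {
    structure(list(
      combo_id = id, selector = combo$selector, classifier = combo$classifier,
      selected_genes = character(0), omitted = TRUE,
      reason = sprintf("%s yielded %d gene(s); fewer than %d model genes",
                       what, n_found, min_genes),
      cohort_auc = NULL, group_auc = NULL, mean_auc = NA_real_
    ), class = "fitted_combo")
  }
  if (!embedded && length(selected) < min_genes) {
    return(omit_result(length(selected), "feature selection"))
  }

  Xs <- Xtr[, selected, drop = FALSE]
  grid <- cls$grid
  if (is.function(grid)) grid <- grid(Xs, ytr)
  # one LOOCV pass scores every candidate parameter set; the set with the
  # best held-out AUC is retained and its held-out scores give the honest
  # training-group AUC. Strict mode reruns selection inside every fold.
  S <- loo_score_matrix(cls, Xs, ytr, grid, seed = derive_seed(seed, id),
                        strict = strict, select_fun = select_fun,
                        Xfull = Xtr)
  tune <- apply(S, 2, auc_mw, y = ytr)
  best_g <- which.max(tune)
  params <- grid[[best_g]]
  loo_scores <- S[, best_g]
  loocv_auc_value <- tune[[best_g]]

  model <- cls$fit(Xs, ytr, params, seed = derive_seed(seed, id))
  if (embedded) {
    selected <- cls$model_genes(model)
    if (length(selected) < min_genes) {
      return(omit_result(length(selected), "embedded model fitting"))
    }
  }

  # per-cohort AUC: training cohorts from LOOCV held-out scores,
  # validation cohorts from the refit model
  offsets <- c(0, cumsum(vapply(prep$X[split$training], nrow, numeric(1))))
  cohort_auc <- setNames(rep(NA_real_, length(prep$X)), names(prep$X))
  for (ci in names(prep$X)) {
    yc <- prep$y[[ci]]
    if (length(unique(yc)) < 2) {
      warning("cohort '", ci, "' has a single class; AUC set to missing")
      next
    }
    if (ci %in% split$training) {
      j <- match(ci, split$training)
      idx <- (offsets[j] + 1):offsets[j + 1]
      cohort_auc[ci] <- auc_mw(loo_scores[idx], ytr[idx])
    } else {
      sc <- cls$predict(model, prep$X[[ci]][, colnames(Xs), drop = FALSE])
      cohort_auc[ci] <- auc_mw(as.numeric(sc), yc)
    }
  }
  group_auc <- vapply(split, function(ids) {
    mean(cohort_auc[ids], na.rm = TRUE)
  }, numeric(1))
  structure(list(
    combo_id = id, selector = combo$selector, classifier = combo$classifier,
    selected_genes = selected, feature_genes = colnames(Xs),
    params = params, model = model,
    classifier_type = cls$type,
    coefficients = extract_coefs(combo$classifier, model, selected),
    loocv_auc = loocv_auc_value,
    cohort_auc = cohort_auc, group_auc = group_auc,
    mean_auc = mean(group_auc, na.rm = TRUE),
    omitted = FALSE, reason = NA_character_, seed = seed
  ), class = "fitted_combo")
}

## leave-one-out held-out score matrix (samples x grid candidates); path
## classifiers (glmnet) serve all candidates from one fit per fold
loo_score_matrix <- function(cls, Xs, y, grid, seed, strict = FALSE,
                             select_fun = NULL, Xfull = NULL) {
  n <- nrow(Xs)
  S <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    Xi_tr <- Xs[-i, , drop = FALSE]
    Xi_te <- Xs[i, , drop = FALSE]
    if (strict) {
      g <- select_fun(Xfull[-i, , drop = FALSE], y[-i])
      if (length(g) == 0) g <- colnames(Xs)
      Xi_tr <- Xfull[-i, g, drop = FALSE]
      Xi_te <- Xfull[i, g, drop = FALSE]
    }
    if (!is.null(cls$fit_multi)) {
      m <- cls$fit_multi(Xi_tr, y[-i], grid, seed = seed)
      S[i, ] <- cls$predict_multi(m, Xi_te, grid)
    } else {
      for (g in seq_along(grid)) {
        m <- cls$fit(Xi_tr, y[-i], grid[[g]], seed = seed)
        S[i, g] <- as.numeric(cls$predict(m, Xi_te))
      }
    }
  }
  S
}

## linear-coefficient extraction where the model admits it (on the
## standardized-gene scale); NULL for non-linear learners
extract_coefs <- function(classifier, model, selected) {
  switch(classifier,
    lasso = , ridge = , enet = {
      b <- as.matrix(coef(model$fit, s = model$lambda))[, 1]
      b[c("(Intercept)", selected)]
    },
    stepglm = {
      b <- model$coef
      b[is.na(b)] <- 0
      b
    },
    glmboost = {
      b <- model$coef
      c("(Intercept)" = model$f0 - sum(b * model$center), b)
    },
    plsglm = {
      bc <- model$coef
      bc[is.na(bc)] <- 0
      bg <- as.numeric(model$pls$R %*% bc[-1])
      names(bg) <- rownames(model$pls$R)
      c("(Intercept)" = bc[[1]] - sum(bg * model$pls$center), bg)
    },
    NULL)
}

#' Rank fitted combinations into a leaderboard
#'
#' Overall mean AUC = mean of the training/internal/external group means;
#' combinations are sorted descending, ties broken by fewer model genes then
#' lexicographic combo id (parsimony first). Omitted combinations are
#' excluded.
#'
#' @param fits list of \code{\link{run_combo}} results.
#' @return data.frame of class \code{"caf_sig_leaderboard"} with columns
#'   \code{combo_id, selector, classifier, n_genes, auc_training,
#'   auc_internal, auc_external, mean_auc}.
#' @export
rank_models <- function(fits) {
  keep <- Filter(function(f) !f$omitted, fits)
  if (length(keep) == 0) stop("all combinations were omitted", call. = FALSE)
  lb <- do.call(rbind, lapply(keep, function(f) {
    data.frame(combo_id = f$combo_id, selector = f$selector,
               classifier = f$classifier,
               n_genes = length(f$selected_genes),
               auc_training = f$group_auc[["training"]],
               auc_internal = f$group_auc[["internal"]],
               auc_external = f$group_auc[["external"]],
               mean_auc = f$mean_auc, stringsAsFactors = FALSE)
  }))
  lb <- lb[order(-lb$mean_auc, lb$n_genes, lb$combo_id), ]
  rownames(lb) <- NULL
  class(lb) <- c("caf_sig_leaderboard", "data.frame")
  lb
}

#' Risk scores from a fitted combination
#'
#' Linear models emit the linear predictor (sum of gene coefficients times
#' expression plus intercept); non-linear models emit the predicted
#' probability of non-response. Either way higher scores mean predicted
#' non-response; any strictly monotone transform leaves the AUC unchanged.
#'
#' @param fitted a \code{\link{run_combo}} result (not omitted).
#' @param expr genes x samples matrix for a new cohort (log2 scale).
#' @param standardize apply the per-cohort gene-wise standardization the
#'   model was trained under (default TRUE).
#' @return named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(fitted, expr, standardize = TRUE) {
  if (!inherits(fitted, "fitted_combo")) {
    stop("`fitted` must be a run_combo() result", call. = FALSE)
  }
  if (fitted$omitted) stop("combination was omitted: ", fitted$reason,
                           call. = FALSE)
  expr <- check_expr(expr)
  # embedded models consume their full training feature space even though
  # only selected_genes carry nonzero weight
  need <- fitted$feature_genes
  missing <- setdiff(need, rownames(expr))
  if (length(missing) > 0) {
    stop("expression matrix lacks model gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- expr[need, , drop = FALSE]
  if (standardize) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    m <- (m - mu) / s
  }
  X <- t(m)
  cls <- make_classifiers()[[fitted$classifier]]
  sc <- as.numeric(cls$predict(fitted$model, X))
  structure(setNames(sc, colnames(expr)),
            orientation = "higher = predicted non-responder",
            type = fitted$classifier_type)
}

#' Fit the Caf.Sig ensemble model search
#'
#' The package's central fitting function. Every combination in the manifest
#' is fitted with \code{\link{run_combo}} on the training cohort group,
#' models with fewer than \code{min_genes} genes are omitted, AUC is
#' computed in every cohort, and combinations are ranked by the mean of the
#' training/internal/external group-mean AUCs. The top combination is
#' retained as the Caf.Sig model; its per-sample predictions are the Caf.Sig
#' risk scores (higher = predicted non-responder).
#'
#' @inheritParams run_combo
#' @param manifest optional manifest subset: a character vector of combo ids
#'   (see \code{\link{reduced_manifest}}) or a data.frame; default is the
#'   registry's full 113-entry manifest.
#' @param keep_fits keep every fitted combination in the returned object
#'   (default keeps only the best; the leaderboard always covers all).
#' @return object of class \code{"caf_sig"} with components
#'   \code{leaderboard}, \code{best} (a \code{fitted_combo}), \code{split},
#'   \code{n_omitted}, \code{seed} and (optionally) \code{fits}.
#' @examples
#' \donttest{
#' sim <- simulate_cohorts(n_cohorts = 3, samples_per_cohort = 40,
#'                         n_genes = 60, n_up = 8, n_down = 8,
#'                         effect_size = 2, seed = 7)
#' fit <- caf_sig(sim$cohorts,
#'                split = list(training = "cohort01", internal = "cohort02",
#'                             external = "cohort03"),
#'                manifest = reduced_manifest("fast8"), seed = 7)
#' print(fit)
#' }
#' @export
caf_sig <- function(cohorts, split, registry = algorithm_registry(),
                    manifest = NULL, min_genes = 5, seed = 1,
                    strict = FALSE, keep_fits = FALSE) {
  grid <- build_grid(registry, manifest)
  prep <- prepare_cohorts(cohorts)
  split <- check_split(split, names(prep$X))
  fits <- vector("list", nrow(grid))
  names(fits) <- grid$combo_id
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- tryCatch(
      run_combo_prepped(as.list(grid[i, ]), prep, split, registry,
                        min_genes, seed, strict),
      error = function(e) {
        structure(list(combo_id = grid$combo_id[i],
                       selector = grid$selector[i],
                       classifier = grid$classifier[i],
                       selected_genes = character(0), omitted = TRUE,
                       reason = paste("fit error:", conditionMessage(e)),
                       mean_auc = NA_real_),
                  class = "fitted_combo")
      })
  }
  lb <- rank_models(fits)
  out <- list(leaderboard = lb, best = fits[[lb$combo_id[1]]],
              split = split, seed = seed, min_genes = min_genes,
              n_omitted = sum(vapply(fits, `[[`, logical(1), "omitted")),
              omitted = lapply(Filter(function(f) f$omitted, fits),
                               function(f) f$reason),
              call = match.call())
  if (keep_fits) out$fits <- fits
  structure(out, class = "caf_sig")
}

#' @export
print.caf_sig <- function(x, ...) {
  cat("Caf.Sig ensemble model search\n")
  cat(sprintf("  combinations evaluated: %d (%d omitted)\n",
              nrow(x$leaderboard) + x$n_omitted, x$n_omitted))
  b <- x$best
  cat(sprintf("  best combination: %s (%d model genes)\n",
              b$combo_id, length(b$selected_genes)))
  cat(sprintf("  group AUC  training %.3f | internal %.3f | external %.3f\n",
              b$group_auc[["training"]], b$group_auc[["internal"]],
              b$group_auc[["external"]]))
  cat(sprintf("  mean AUC: %.3f\n", b$mean_auc))
  invisible(x)
}

#' @export
summary.caf_sig <- function(object, n = 10, ...) {
  cat("Leaderboard (top", min(n, nrow(object$leaderboard)), "of",
      nrow(object$leaderboard), "ranked combinations):\n")
  print(head(as.data.frame(object$leaderboard), n), digits = 3)
  cat("\nModel genes of the best combination:\n")
  cat(" ", paste(object$best$selected_genes, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.caf_sig <- function(object, ...) {
  b <- object$best$coefficients
  if (is.null(b)) {
    message("best combination's classifier (", object$best$classifier,
            ") has no linear coefficient representation")
    return(invisible(NULL))
  }
  b
}

#' Predict Caf.Sig risk scores for new samples
#'
#' @param object a \code{\link{caf_sig}} fit.
#' @param newdata genes x samples expression matrix (log2 scale).
#' @param ... passed to \code{\link{risk_score}}.
#' @return named numeric vector of risk scores (higher = predicted
#'   non-responder).
#' @export
predict.caf_sig <- function(object, newdata, ...) {
  risk_score(object$best, newdata, ...)
}

#' @export
print.fitted_combo <- function(x, ...) {
  if (x$omitted) {
    cat(sprintf("combination %s: omitted (%s)\n", x$combo_id, x$reason))
  } else {
    cat(sprintf("combination %s: %d genes, mean AUC %.3f\n",
                x$combo_id, length(x$selected_genes), x$mean_auc))
  }
  invisible(x)
}
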