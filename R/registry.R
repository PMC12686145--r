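#' Algorithm registry for the ensemble model search
#'
#' Registers the feature-selection methods and classifiers the model search
#' combines, together with the default combination manifest. The default
#' manifest pairs 9 feature-selection-capable methods (lasso, elastic net,
#' ridge coefficient ranking, forward stepwise, componentwise-boosting
#' importance, random-forest importance, gradient-boosted-tree importance,
#' partial-least-squares loadings, recursive feature elimination with a
#' linear margin classifier) with 12 classifiers (random forest, lasso,
#' ridge, elastic net, stepwise GLM, componentwise linear boosting, LDA,
#' PLS-logistic, slow-learning boosted trees, extreme gradient boosting,
#' linear SVM, naive Bayes), giving 108 combinations, plus 5 standalone
#' embedded models whose classifier performs its own gene selection (lasso,
#' ridge, elastic net, boosted linear, stepwise GLM) -- 113 entries in all.
#'
#' @param top_k number of genes rank-only selectors keep (default 20).
#' @return list with elements \code{selectors}, \code{classifiers} and
#'   \code{manifest} (data.frame \code{combo_id, selector, classifier}).
#' @seealso \code{\link{build_grid}}, \code{\link{caf_sig}}
#' @examples
#' reg <- algorithm_registry()
#' nrow(reg$manifest)
#' @export
algorithm_registry <- function(top_k = 20) {
  top_k <- check_count(top_k, "top_k")
  selectors <- make_selectors(top_k)
  classifiers <- make_classifiers()
  emb <- c("lasso", "ridge", "enet", "glmboost", "stepglm")
  manifest <- rbind(
    expand.grid(selector = names(selectors), classifier = names(classifiers),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(selector = "embedded", classifier = emb,
               stringsAsFactors = FALSE)
  )
  manifest <- manifest[order(manifest$selector, manifest$classifier), ]
  manifest <- data.frame(
    combo_id = paste(manifest$selector, manifest$classifier, sep = "+"),
    manifest, stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  list(selectors = selectors, classifiers = classifiers, manifest = manifest,
       top_k = top_k)
}

#' Enumerate the model-search combination grid
#'
#' Returns the registry's manifest in deterministic order after validating
#' that every entry references a registered selector and classifier. The
#' default registry yields exactly 113 combinations.
#'
#' @param registry an \code{\link{algorithm_registry}} result.
#' @param manifest optional replacement manifest (data.frame with columns
#'   \code{selector} and \code{classifier}; \code{combo_id} is derived when
#'   absent).
#' @return data.frame \code{combo_id, selector, classifier}.
#' @examples
#' nrow(build_grid(algorithm_registry()))  # 113
#' @export
build_grid <- function(registry, manifest = NULL) {
  if (is.null(manifest)) manifest <- registry$manifest
  if (is.character(manifest)) {
    keep <- registry$manifest$combo_id %in% manifest
    missing <- setdiff(manifest, registry$manifest$combo_id)
    if (length(missing) > 0) {
      stop("unknown combo id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    manifest <- registry$manifest[keep, ]
  }
  if (!all(c("selector", "classifier") %in% names(manifest))) {
    stop("manifest needs columns `selector` and `classifier`", call. = FALSE)
  }
  if (is.null(manifest$combo_id)) {
    manifest$combo_id <- paste(manifest$selector, manifest$classifier, sep = "+")
  }
  bad_sel <- setdiff(unique(manifest$selector),
                     c(names(registry$selectors), "embedded"))
  bad_cls <- setdiff(unique(manifest$classifier), names(registry$classifiers))
  if (length(bad_sel) > 0 || length(bad_cls) > 0) {
    stop("manifest references unregistered algorithm(s): ",
         paste(c(bad_sel, bad_cls), collapse = ", "), call. = FALSE)
  }
  emb <- manifest$selector == "embedded"
  if (any(emb)) {
    ok <- manifest$classifier[emb] %in% c("lasso", "ridge", "enet",
                                          "glmboost", "stepglm")
    if (!all(ok)) {
      stop("embedded combos require a self-selecting classifier", call. = FALSE)
    }
  }
  manifest <- manifest[order(manifest$selector, manifest$classifier),
                       c("combo_id", "selector", "classifier")]
  rownames(manifest) <- NULL
  manifest
}

#' Reduced combination manifests
#'
#' Convenience subsets of the default manifest for bounded-compute runs:
#' \code{"reduced20"} spans all nine selectors and most classifiers in 20
#' combinations (including lasso feature selection with a random-forest
#' classifier); \code{"fast8"} keeps 8 combinations of inexpensive linear
#' learners, suitable for replicate-heavy null experiments.
#'
#' @param kind \code{"reduced20"} or \code{"fast8"}.
#' @return character vector of combo ids, usable as the \code{manifest}
#'   argument of \code{\link{caf_sig}} / \code{\link{build_grid}}.
#' @export
reduced_manifest <- function(kind = c("reduced20", "fast8")) {
  kind <- match.arg(kind)
  switch(kind,
    reduced20 = c(
      "lasso+rf", "lasso+lda", "lasso+stepglm", "lasso+nb",
      "enet+lda", "enet+svm", "enet+glmboost",
      "ridge_rank+stepglm", "ridge_rank+plsglm",
      "stepwise+lda", "stepwise+lasso",
      "boost_imp+lda", "rf_imp+rf", "rf_imp+lasso",
      "xgb_imp+xgb", "pls_load+plsglm", "pls_load+lda",
      "svm_rfe+svm",
      "embedded+lasso", "embedded+enet"
    ),
    fast8 = c(
      "lasso+lda", "enet+lda", "enet+plsglm", "ridge_rank+lda",
      "pls_load+plsglm", "pls_load+lda", "embedded+lasso", "embedded+enet"
    )
  )
}

## --- feature selectors -------------------------------------------------
## each: function(X, y, k, seed) -> character vector of gene names,
## X samples x genes (standardized), y 0/1 (1 = non-responder)

make_selectors <- function(top_k) {
  list(
    lasso = function(X, y, k, seed) {
      local_seed(seed, {
        cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                                nfolds = 5)
        nonzero_coefs(cv, X)
      })
    },
    enet = function(X, y, k, seed) {
      local_seed(seed, {
        cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0.5,
                                nfolds = 5)
        nonzero_coefs(cv, X)
      })
    },
    ridge_rank = function(X, y, k, seed) {
      local_seed(seed, {
        cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                                nfolds = 5)
        b <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
        top_abs(b, k)
      })
    },
    stepwise = function(X, y, k, seed) {
      forward_aic(X, y, max_steps = k)
    },
    boost_imp = function(X, y, k, seed) {
      fit <- cwl_boost(X, y, mstop = 200, nu = 0.1)
      b <- fit$coef[fit$coef != 0]
      top_abs(b, k)
    },
    rf_imp = function(X, y, k, seed) {
      local_seed(seed, {
        rf <- randomForest::randomForest(
          x = X, y = factor(y, levels = c(0, 1)), ntree = 300)
        imp <- randomForest::importance(rf)[, 1]
        top_abs(imp, k)
      })
    },
    xgb_imp = function(X, y, k, seed) {
      local_seed(seed, {
        bst <- xgb_fit(X, y, max_depth = 3, eta = 0.3, nrounds = 50)
        imp <- xgboost::xgb.importance(model = bst)
        g <- as.character(imp$Feature)
        head(g, k)
      })
    },
    pls_load = function(X, y, k, seed) {
      fit <- pls_fit(X, y, ncomp = 2)
      w <- sqrt(rowSums(fit$W^2))
      top_abs(w, k)
    },
    svm_rfe = function(X, y, k, seed) {
      local_seed(seed, svm_rfe_select(X, y, k))
    }
  )
}

nonzero_coefs <- function(cv, X) {
  b <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  names(b)[b != 0]
}

top_abs <- function(v, k) {
  v <- v[order(-abs(v), names(v))]
  names(head(v, k))
}

## forward selection by AIC over univariately prescreened candidates
forward_aic <- function(X, y, max_steps = 20, prescreen = 50) {
  p <- ncol(X)
  if (p > prescreen) {
    tt <- abs(apply(X, 2, function(x) {
      s <- sd(x)
      if (s == 0) return(0)
      (mean(x[y == 1]) - mean(x[y == 0])) / s
    }))
    cand <- names(sort(tt, decreasing = TRUE))[seq_len(prescreen)]
  } else {
    cand <- colnames(X)
  }
  chosen <- character(0)
  cur_aic <- glm_aic(matrix(nrow = length(y), ncol = 0), y)
  repeat {
    if (length(chosen) >= max_steps || length(cand) == 0) break
    aics <- vapply(cand, function(g) {
      glm_aic(X[, c(chosen, g), drop = FALSE], y)
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= cur_aic - 1e-8) break
    cur_aic <- aics[best]
    chosen <- c(chosen, cand[best])
    cand <- cand[-best]
  }
  chosen
}

glm_aic <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    glm.fit(Xd, y, family = binomial())
  )
  fit$aic
}

svm_rfe_select <- function(X, y, k) {
  feats <- colnames(X)
  yf <- factor(y, levels = c(0, 1))
  while (length(feats) > k) {
    fit <- e1071::svm(X[, feats, drop = FALSE], yf, kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    names(w) <- colnames(fit$SV)
    w <- abs(w[feats])
    drop_n <- max(1L, floor(length(feats) / 3))
    drop_n <- min(drop_n, length(feats) - k)
    feats <- setdiff(feats, names(sort(w))[seq_len(drop_n)])
  }
  feats
}

## --- classifiers -------------------------------------------------------
## each entry: grid (list of parameter lists, or function(X, y) -> list),
## fit(X, y, params, seed) -> model, predict(model, X) -> numeric score
## (higher = non-responder), type "linear" (score = linear predictor) or
## "prob" (score = predicted probability of non-response), and for
## self-selecting classifiers a model_genes(model) accessor

make_classifiers <- function() {
  glmnet_grid <- function(alpha) {
    function(X, y) {
      path <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha)
      lam <- path$lambda
      idx <- unique(pmax(1L, round(quantile(seq_along(lam), c(0.3, 0.6, 0.9)))))
      lapply(lam[idx], function(l) list(lambda = l, alpha = alpha))
    }
  }
  glmnet_fit <- function(X, y, params, seed) {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = params$alpha)
    list(fit = fit, lambda = params$lambda, genes = colnames(X))
  }
  # one path fit per LOOCV fold serves every candidate lambda
  glmnet_fit_multi <- function(X, y, grid, seed) {
    glmnet::glmnet(X, y, family = "binomial", alpha = grid[[1]]$alpha)
  }
  glmnet_predict_multi <- function(fit, X, grid) {
    vapply(grid, function(p) {
      as.numeric(predict(fit, newx = X, s = p$lambda, type = "link"))
    }, numeric(nrow(X)))
  }
  glmnet_predict <- function(model, X) {
    as.numeric(predict(model$fit, newx = X[, model$genes, drop = FALSE],
                       s = model$lambda, type = "link"))
  }
  glmnet_genes <- function(model) {
    b <- as.matrix(coef(model$fit, s = model$lambda))[-1, 1]
    names(b)[b != 0]
  }

  list(
    rf = list(
      grid = list(list(ntree = 300)),
      fit = function(X, y, params, seed) {
        local_seed(seed, randomForest::randomForest(
          x = X, y = factor(y, levels = c(0, 1)), ntree = params$ntree))
      },
      predict = function(model, X) {
        predict(model, X, type = "prob")[, "1"]
      },
      type = "prob"
    ),
    lasso = list(
      grid = glmnet_grid(1), fit = glmnet_fit, predict = glmnet_predict,
      fit_multi = glmnet_fit_multi, predict_multi = glmnet_predict_multi,
      model_genes = glmnet_genes, type = "linear"
    ),
    ridge = list(
      grid = glmnet_grid(0), fit = glmnet_fit, predict = glmnet_predict,
      fit_multi = glmnet_fit_multi, predict_multi = glmnet_predict_multi,
      model_genes = function(model) model$genes, type = "linear"
    ),
    enet = list(
      grid = glmnet_grid(0.5), fit = glmnet_fit, predict = glmnet_predict,
      fit_multi = glmnet_fit_multi, predict_multi = glmnet_predict_multi,
      model_genes = glmnet_genes, type = "linear"
    ),
    stepglm = list(
      grid = list(list()),
      fit = function(X, y, params, seed) {
        genes <- forward_aic(X, y, max_steps = min(15, ncol(X)))
        if (length(genes) == 0) genes <- colnames(X)[1]
        Xd <- cbind(`(Intercept)` = 1, X[, genes, drop = FALSE])
        fit <- suppressWarnings(glm.fit(Xd, y, family = binomial()))
        list(coef = coef(fit), genes = genes)
      },
      predict = function(model, X) {
        b <- model$coef
        b[is.na(b)] <- 0
        as.numeric(cbind(1, X[, model$genes, drop = FALSE]) %*% b)
      },
      model_genes = function(model) model$genes,
      type = "linear"
    ),
    glmboost = list(
      grid = list(list(mstop = 50), list(mstop = 150)),
      fit = function(X, y, params, seed) {
        cwl_boost(X, y, mstop = params$mstop, nu = 0.1)
      },
      predict = function(model, X) predict_cwl(model, X),
      model_genes = function(model) names(model$coef)[model$coef != 0],
      type = "linear"
    ),
    lda = list(
      grid = list(list()),
      fit = function(X, y, params, seed) {
        keep <- apply(X, 2, function(v) sd(v) > 0)
        X <- X[, keep, drop = FALSE]
        list(fit = MASS::lda(X, grouping = factor(y, levels = c(0, 1))),
             genes = colnames(X))
      },
      predict = function(model, X) {
        predict(model$fit, X[, model$genes, drop = FALSE])$posterior[, "1"]
      },
      type = "prob"
    ),
    plsglm = list(
      grid = function(X, y) {
        lapply(seq_len(min(3, ncol(X), nrow(X) - 2)), function(nc) {
          list(ncomp = nc)
        })
      },
      fit = function(X, y, params, seed) {
        pf <- pls_fit(X, y, ncomp = params$ncomp)
        scores <- sweep(X[, rownames(pf$R), drop = FALSE], 2, pf$center) %*% pf$R
        gfit <- suppressWarnings(
          glm.fit(cbind(1, scores), y, family = binomial()))
        list(pls = pf, coef = coef(gfit))
      },
      predict = function(model, X) {
        pf <- model$pls
        scores <- sweep(X[, rownames(pf$R), drop = FALSE], 2, pf$center) %*% pf$R
        b <- model$coef
        b[is.na(b)] <- 0
        as.numeric(cbind(1, scores) %*% b)
      },
      type = "linear"
    ),
    gbm = list(
      grid = list(list(max_depth = 2, eta = 0.05, nrounds = 150)),
      fit = function(X, y, params, seed) {
        local_seed(seed, xgb_fit(X, y, max_depth = params$max_depth,
                                 eta = params$eta, nrounds = params$nrounds))
      },
      predict = function(model, X) xgb_predict(model, X),
      type = "prob"
    ),
    xgb = list(
      grid = list(list(max_depth = 3, eta = 0.3, nrounds = 60)),
      fit = function(X, y, params, seed) {
        local_seed(seed, xgb_fit(X, y, max_depth = params$max_depth,
                                 eta = params$eta, nrounds = params$nrounds))
      },
      predict = function(model, X) xgb_predict(model, X),
      type = "prob"
    ),
    svm = list(
      grid = list(list(cost = 0.1), list(cost = 1)),
      fit = function(X, y, params, seed) {
        local_seed(seed, {
          fit <- e1071::svm(X, factor(y, levels = c(0, 1)),
                            kernel = "linear", cost = params$cost,
                            scale = FALSE)
          list(fit = fit, genes = colnames(X))
        })
      },
      predict = function(model, X) {
        dv <- attr(predict(model$fit, X[, model$genes, drop = FALSE],
                           decision.values = TRUE), "decision.values")
        # orient the margin so larger means class "1" (non-responder)
        if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
      },
      type = "linear"
    ),
    nb = list(
      grid = list(list()),
      fit = function(X, y, params, seed) {
        keep <- apply(X, 2, function(v) sd(v) > 0)
        X <- X[, keep, drop = FALSE]
        list(fit = e1071::naiveBayes(X, factor(y, levels = c(0, 1))),
             genes = colnames(X))
      },
      predict = function(model, X) {
        predict(model$fit, X[, model$genes, drop = FALSE],
                type = "raw")[, "1"]
      },
      type = "prob"
    )
  )
}

## --- small in-package learners ----------------------------------------

## componentwise linear gradient boosting with logistic loss: at each step
## the single gene best fitting the current negative gradient receives a
## damped least-squares update (step length nu)
cwl_boost <- function(X, y, mstop = 100, nu = 0.1) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ctr <- attr(Xc, "scaled:center")
  ss <- colSums(Xc^2)
  ok <- ss > 0
  f0 <- qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  f <- rep(f0, length(y))
  coefs <- setNames(numeric(ncol(X)), colnames(X))
  for (m in seq_len(mstop)) {
    g <- y - plogis(f)
    b <- crossprod(Xc, g)[, 1] / pmax(ss, 1e-12)
    score <- b^2 * ss
    score[!ok] <- -Inf
    j <- which.max(score)
    coefs[j] <- coefs[j] + nu * b[j]
    f <- f + nu * b[j] * Xc[, j]
  }
  list(coef = coefs, center = ctr, f0 = f0)
}

predict_cwl <- function(model, X) {
  genes <- names(model$coef)
  as.numeric(model$f0 +
               sweep(X[, genes, drop = FALSE], 2, model$center) %*% model$coef)
}

## NIPALS partial least squares on centered X and y; returns the rotation R
## mapping centered X to latent scores (T = Xc R)
pls_fit <- function(X, y, ncomp = 2) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ctr <- attr(Xc, "scaled:center")
  yc <- y - mean(y)
  p <- ncol(X)
  ncomp <- min(ncomp, p, nrow(X) - 1)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  used <- 0L
  Xd <- Xc
  yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xd, t_)[, 1] / tt
    q <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, pvec)
    yd <- yd - q * t_
    used <- a
    W[, a] <- w
    P[, a] <- pvec
  }
  if (used == 0L) stop("PLS found no usable component", call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  rownames(R) <- colnames(X)
  list(R = R, W = W, center = ctr, ncomp = used)
}

## xgboost wrappers kept in one place (single thread for determinism)
xgb_fit <- function(X, y, max_depth, eta, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(data = X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_predict <- function(model, X) {
  feats <- xgboost::getinfo(model, "feature_name")
  if (is.null(feats) || length(feats) == 0) feats <- colnames(X)
  predict(model, xgboost::xgb.DMatrix(X[, feats, drop = FALSE], nthread = 1))
}
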