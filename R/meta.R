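#' Per-gene odds-ratio meta-analysis across cohorts
#'
#' For each model gene and cohort, non-response is regressed on the
#' standardized expression of that gene by univariate logistic regression,
#' giving a per-cohort log odds ratio and standard error. Cohort estimates
#' are pooled by inverse-variance weighting (fixed effect, the default) or
#' by DerSimonian-Laird random effects; the 95\% CI is pooled log-OR
#' +/- 1.96 SE. Cohorts in which the gene separates the classes perfectly
#' are excluded with a warning. P-values are Benjamini-Hochberg adjusted
#' across genes in the returned table.
#'
#' @param genes character vector of gene ids.
#' @param cohorts named list of cohorts, each a list with \code{expr}
#'   (genes x samples) and \code{labels} (R/NR).
#' @param method \code{"fixed"} (inverse variance) or \code{"random"}
#'   (DerSimonian-Laird).
#' @param standardize scale each gene to unit SD within each cohort before
#'   the logistic fit (default TRUE: ORs are per expression SD). With FALSE
#'   the OR is per raw expression unit, so for a 0/1 gene it equals the
#'   2x2 cross-product ratio.
#' @return data.frame with one row per gene: \code{gene, log_or, se, or,
#'   ci_low, ci_high, p, p_adj, q_het, n_cohorts, method}.
#' @examples
#' sim <- simulate_cohorts(n_cohorts = 2, samples_per_cohort = 60,
#'                         n_genes = 30, n_up = 3, n_down = 3, seed = 2)
#' gene_or_meta(sim$truth$up_genes[1:2], sim$cohorts)
#' @export
gene_or_meta <- function(genes, cohorts, method = c("fixed", "random"),
                         standardize = TRUE) {
  method <- match.arg(method)
  if (!is.list(cohorts) || length(cohorts) == 0) {
    stop("`cohorts` must be a non-empty list", call. = FALSE)
  }
  rows <- lapply(genes, function(g) {
    est <- lapply(names(cohorts), function(ci) {
      co <- cohorts[[ci]]
      if (!g %in% rownames(co$expr)) return(NULL)
      y <- response01(co$labels)
      if (length(unique(y)) < 2) return(NULL)
      x <- co$expr[g, ]
      if (standardize && sd(x) > 0) x <- (x - mean(x)) / sd(x)
      fit <- suppressWarnings(glm(y ~ x, family = binomial()))
      b <- summary(fit)$coefficients
      if (nrow(b) < 2 || !is.finite(b[2, 2]) ||
          abs(b[2, 1]) > 15 || b[2, 2] > 100) {
        warning("gene '", g, "': perfect/near separation in cohort '", ci,
                "'; cohort excluded")
        return(NULL)
      }
      c(yi = b[2, 1], sei = b[2, 2])
    })
    est <- do.call(rbind, Filter(Negate(is.null), est))
    if (is.null(est) || nrow(est) == 0) {
      return(data.frame(gene = g, log_or = NA_real_, se = NA_real_,
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, q_het = NA_real_, n_cohorts = 0L,
                        method = method, stringsAsFactors = FALSE))
    }
    rma <- metafor::rma(yi = est[, "yi"], sei = est[, "sei"],
                        method = if (method == "fixed") "FE" else "DL")
    mu <- as.numeric(rma$beta)
    se <- rma$se
    data.frame(gene = g, log_or = mu, se = se, or = exp(mu),
               ci_low = exp(mu - 1.96 * se), ci_high = exp(mu + 1.96 * se),
               p = 2 * pnorm(-abs(mu / se)), q_het = as.numeric(rma$QE),
               n_cohorts = nrow(est), method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("gene", "log_or", "se", "or", "ci_low", "ci_high", "p", "p_adj",
          "q_het", "n_cohorts", "method")]
}
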