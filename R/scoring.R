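#' Single-sample rank-weighted running-sum gene-set score
#'
#' For each sample, genes are ranked by expression (descending; ties get
#' average ranks, with a deterministic secondary order by gene id). Walking
#' down the ranked list, the enrichment score accumulates the difference
#' between the weighted in-set empirical CDF (weights = magnitude
#' rank^\code{alpha}, normalized over in-set genes) and the uniform
#' out-of-set ECDF; the score is the sum of that difference over all
#' positions. With \code{normalize = TRUE} all scores are divided by the
#' global (max - min) across samples, mirroring cross-sample range
#' normalization.
#'
#' @param expr numeric matrix, genes x samples, with rownames (gene ids) and
#'   colnames (sample ids). Assumed log2 scale; only ranks are used.
#' @param genes character vector of gene ids (the gene set), or a list with
#'   elements \code{name} and \code{genes}.
#' @param alpha rank-weight exponent; default 0.25.
#' @param normalize divide all scores by the global score range.
#' @return named numeric vector of per-sample scores, with attributes
#'   \code{scorer}, \code{alpha} and \code{normalize}.
#' @examples
#' m <- matrix(1:10, 5, 2, dimnames = list(paste0("g", 1:5), c("s1", "s2")))
#' ssgsea_score(m, c("g4", "g5"))
#' @export
ssgsea_score <- function(expr, genes, alpha = 0.25, normalize = FALSE) {
  expr <- check_expr(expr)
  gs <- as_gene_set(genes)
  set_genes <- intersect(gs$genes, rownames(expr))
  if (length(set_genes) == 0) {
    stop("gene set '", gs$name, "' has no genes in the expression matrix",
         call. = FALSE)
  }
  n <- nrow(expr)
  if (length(set_genes) >= n) {
    stop("gene set '", gs$name, "' covers the whole matrix; ",
         "out-of-set ECDF is undefined", call. = FALSE)
  }
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    if (length(unique(x)) == 1L) {
      warning("sample '", colnames(expr)[j],
              "' has constant expression; ties resolved by gene id")
    }
    # descending expression, ties broken by gene id for determinism
    ord <- order(-x, rownames(expr))
    rnk <- rank(x, ties.method = "average")  # top gene ~ rank n
    inset <- rownames(expr)[ord] %in% set_genes
    w <- ifelse(inset, rnk[ord]^alpha, 0)
    cdf_in <- cumsum(w) / sum(w)
    cdf_out <- cumsum(!inset) / (n - length(set_genes))
    sum(cdf_in - cdf_out)
  }, numeric(1))
  names(scores) <- colnames(expr)
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, scorer = "ssgsea", alpha = alpha, normalize = normalize)
}

#' Mean module score with expression-matched controls
#'
#' Per unit (sample or cell): mean expression of the set genes minus the
#' mean of control genes sampled from average-expression bins matched to the
#' set genes. Genes are binned by their average expression across units into
#' \code{n_bins} equal-size rank bins; for each set gene, \code{n_control}
#' control genes are drawn (seeded, without replacement, excluding set
#' genes) from its bin.
#'
#' @inheritParams ssgsea_score
#' @param n_control controls drawn per set gene; clamped with a warning when
#'   a bin's pool is smaller.
#' @param n_bins number of average-expression bins (default 25).
#' @param seed integer seed for control sampling.
#' @return named numeric vector of per-unit scores, attributes as in
#'   \code{\link{ssgsea_score}}.
#' @export
mean_module_score <- function(expr, genes, n_control = 100, n_bins = 25,
                              seed = 1) {
  expr <- check_expr(expr)
  gs <- as_gene_set(genes)
  set_genes <- intersect(gs$genes, rownames(expr))
  if (length(set_genes) == 0) {
    stop("gene set '", gs$name, "' has no genes in the expression matrix",
         call. = FALSE)
  }
  n_control <- check_count(n_control, "n_control")
  n_bins <- check_count(n_bins, "n_bins")
  avg <- rowMeans(expr)
  n_bins <- min(n_bins, nrow(expr))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(expr)
  controls <- local_seed(seed, {
    unlist(lapply(set_genes, function(g) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], set_genes)
      if (length(pool) == 0) return(character(0))
      k <- n_control
      if (k > length(pool)) {
        warning("control pool for bin of gene '", g, "' has only ",
                length(pool), " genes; clamping n_control")
        k <- length(pool)
      }
      sample(pool, k)
    }), use.names = FALSE)
  })
  if (length(controls) == 0) {
    stop("no control genes available outside the set", call. = FALSE)
  }
  set_mean <- colMeans(expr[set_genes, , drop = FALSE])
  ctl_mean <- colMeans(expr[controls, , drop = FALSE])
  structure(set_mean - ctl_mean, scorer = "module",
            n_control = n_control, n_bins = n_bins)
}

#' Caf.Sig score: up-regulated minus down-regulated enrichment
#'
#' The signature score used throughout the package: the single-sample score
#' of the genes up-regulated in non-responders minus that of the
#' down-regulated genes, computed with the same scorer and parameters for
#' both sets. Higher scores indicate predicted non-response.
#'
#' @inheritParams ssgsea_score
#' @param signature list with elements \code{up} and \code{down}, each a
#'   character vector of gene ids (or a GeneSet list); the two sets must be
#'   disjoint unless \code{validate = FALSE}.
#' @param scorer \code{"ssgsea"} (default) or \code{"module"}.
#' @param ... passed on to the scorer (\code{alpha}, \code{normalize},
#'   \code{n_control}, \code{n_bins}, \code{seed}).
#' @param validate check up/down disjointness.
#' @return named numeric vector of per-sample Caf.Sig scores.
#' @examples
#' sim <- simulate_cohorts(n_cohorts = 1, samples_per_cohort = 30,
#'                         n_genes = 100, n_up = 10, n_down = 10, seed = 1)
#' sig <- list(up = sim$truth$up_genes, down = sim$truth$down_genes)
#' sc <- caf_sig_score(sim$cohorts[[1]]$expr, sig)
#' @export
caf_sig_score <- function(expr, signature, scorer = c("ssgsea", "module"),
                          ..., validate = TRUE) {
  scorer <- match.arg(scorer)
  if (!is.list(signature) || !all(c("up", "down") %in% names(signature))) {
    stop("`signature` must be a list with elements `up` and `down`",
         call. = FALSE)
  }
  up <- as_gene_set(signature$up, default_name = "up")
  down <- as_gene_set(signature$down, default_name = "down")
  if (validate && length(intersect(up$genes, down$genes)) > 0) {
    stop("up and down gene sets overlap", call. = FALSE)
  }
  fn <- switch(scorer, ssgsea = ssgsea_score, module = mean_module_score)
  s_up <- fn(expr, up, ...)
  s_down <- fn(expr, down, ...)
  structure(as.numeric(s_up) - as.numeric(s_down),
            names = names(s_up), scorer = scorer,
            orientation = "higher = predicted non-responder")
}

#' Partition candidate genes into up/down signature sets
#'
#' A gene goes to the up set when its mean expression in non-responders
#' exceeds that in responders, to the down set when lower; genes with
#' exactly equal group means are excluded (reported), and genes absent from
#' the matrix are skipped with a warning.
#'
#' @inheritParams ssgsea_score
#' @param labels response labels ("R"/"NR"), one per sample.
#' @param genes candidate gene ids.
#' @return list with \code{up}, \code{down} (character vectors) and
#'   \code{excluded} (equal-means genes).
#' @export
partition_signature <- function(expr, labels, genes) {
  expr <- check_expr(expr)
  labels <- as_response(labels)
  if (length(labels) != ncol(expr)) {
    stop("`labels` must have one entry per sample", call. = FALSE)
  }
  if (!all(c("R", "NR") %in% labels)) {
    stop("both label groups must be non-empty", call. = FALSE)
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    warning("skipping ", length(missing), " gene(s) absent from the matrix: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  }
  genes <- intersect(genes, rownames(expr))
  m_nr <- rowMeans(expr[genes, labels == "NR", drop = FALSE])
  m_r <- rowMeans(expr[genes, labels == "R", drop = FALSE])
  d <- m_nr - m_r
  list(up = genes[d > 0], down = genes[d < 0], excluded = genes[d == 0])
}

#' Filter low-quality cells
#'
#' Removes a cell iff any of the four rules fires (all strict comparisons):
#' \code{umi_count > 40000}, \code{n_genes < 500}, \code{n_genes > 5000}, or
#' \code{pct_mito > 20}. Boundary values (umi = 40000, genes = 500 or 5000,
#' pct_mito = 20) survive. The removal log names every rule each removed
#' cell triggered.
#'
#' @param cells data.frame with columns \code{cell_id}, \code{umi_count},
#'   \code{n_genes}, \code{pct_mito} (percent, 0-100).
#' @param max_umi,min_genes,max_genes,max_pct_mito rule thresholds.
#' @return list: \code{retained} and \code{removed} (row subsets of
#'   \code{cells}) and \code{log} (data.frame \code{cell_id}, \code{rules}
#'   with comma-joined rule names).
#' @examples
#' tab <- data.frame(cell_id = c("a", "b"), umi_count = c(10000, 50000),
#'                   n_genes = c(2000, 2000), pct_mito = c(5, 5))
#' qc_filter(tab)$log
#' @export
qc_filter <- function(cells, max_umi = 40000, min_genes = 500,
                      max_genes = 5000, max_pct_mito = 20) {
  need <- c("cell_id", "umi_count", "n_genes", "pct_mito")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    stop("`cells` must be a data.frame with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(cells$umi_count < 0) || any(cells$n_genes < 0) ||
      any(cells$pct_mito < 0)) {
    stop("QC fields must be non-negative", call. = FALSE)
  }
  hits <- cbind(
    umi_high = cells$umi_count > max_umi,
    gene_low = cells$n_genes < min_genes,
    gene_high = cells$n_genes > max_genes,
    mito_high = cells$pct_mito > max_pct_mito
  )
  removed <- rowSums(hits) > 0
  log <- data.frame(
    cell_id = cells$cell_id[removed],
    rules = apply(hits[removed, , drop = FALSE], 1, function(h) {
      paste(colnames(hits)[h], collapse = ",")
    }),
    stringsAsFactors = FALSE
  )
  rownames(log) <- NULL
  list(retained = cells[!removed, , drop = FALSE],
       removed = cells[removed, , drop = FALSE],
       log = log)
}

## --- internal ---------------------------------------------------------

check_expr <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric genes x samples matrix", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("`expr` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (nrow(expr) < 2) stop("`expr` needs at least 2 genes", call. = FALSE)
  expr
}

as_gene_set <- function(genes, default_name = "geneset") {
  if (is.list(genes) && !is.null(genes$genes)) {
    name <- if (!is.null(genes$name)) genes$name else default_name
    genes <- genes$genes
  } else {
    name <- default_name
  }
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  list(name = name, genes = genes)
}
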