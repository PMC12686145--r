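#' Spatial k-distance between a reference and a target cell type
#'
#' For every reference-type cell of every section, computes the mean
#' Euclidean distance to its k nearest target-type cells within the same
#' section (distances never cross sections). When reference and target type
#' coincide the cell itself is excluded. Sections with fewer than k target
#' cells yield missing values, with a warning.
#'
#' @param cells spatial cell table: data.frame with columns \code{cell_id,
#'   x, y, cell_type, section_id, group}.
#' @param reference_type reference cell-type name (e.g. "iCAF").
#' @param target_types character vector of target types; default all types
#'   other than the reference.
#' @param k number of nearest target cells averaged (default 10).
#' @return data.frame of class \code{"kdist_table"}: one row per (section,
#'   reference cell, target type) with columns \code{section_id, group,
#'   cell_id, target_type, k_distance, k}.
#' @examples
#' tt <- data.frame(type = c("A", "B"), sigma_responder = c(2, 10),
#'                  sigma_nonresponder = c(2, 10))
#' sim <- simulate_sections(tt, n_sections_responder = 1,
#'                          n_sections_nonresponder = 1, seed = 1)
#' kd <- k_distance(sim$cells, "iCAF", k = 5)
#' @export
k_distance <- function(cells, reference_type, target_types = NULL, k = 10) {
  cells <- check_spatial(cells)
  k <- check_count(k, "k")
  if (is.null(target_types)) {
    target_types <- setdiff(unique(cells$cell_type), reference_type)
  }
  if (length(target_types) == 0) stop("no target types", call. = FALSE)
  out <- list()
  for (sec in unique(cells$section_id)) {
    s <- cells[cells$section_id == sec, ]
    ref <- s[s$cell_type == reference_type, ]
    if (nrow(ref) == 0) {
      stop("section '", sec, "' has no '", reference_type, "' cells",
           call. = FALSE)
    }
    for (tt in target_types) {
      tg <- s[s$cell_type == tt, ]
      kd <- rep(NA_real_, nrow(ref))
      for (i in seq_len(nrow(ref))) {
        tx <- tg
        if (tt == reference_type) {
          tx <- tg[tg$cell_id != ref$cell_id[i], , drop = FALSE]
        }
        if (nrow(tx) < k) next
        d <- sqrt((tx$x - ref$x[i])^2 + (tx$y - ref$y[i])^2)
        kd[i] <- mean(sort(d)[seq_len(k)])
      }
      if (all(is.na(kd))) {
        warning("section '", sec, "' has fewer than k=", k, " '", tt,
                "' cells; k-distance missing")
      }
      out[[length(out) + 1L]] <- data.frame(
        section_id = sec, group = ref$group[1], cell_id = ref$cell_id,
        target_type = tt, k_distance = kd, k = k, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("kdist_table", "data.frame")
  res
}

#' Per-section proximity ranking of target types
#'
#' Summarizes each (section, target type) by the median of its per-reference
#' cell k-distances and ranks types within each section from nearest
#' (rank 1) to farthest; ties receive average ranks. Types with no defined
#' distance in a section get that section's worst rank (conservative), so
#' the rank matrix stays rectangular for aggregation.
#'
#' @param ktable a \code{\link{k_distance}} result.
#' @return matrix (sections x target types) of within-section ranks, with a
#'   \code{"group"} attribute giving each section's response group.
#' @export
rank_by_proximity <- function(ktable) {
  if (!all(c("section_id", "target_type", "k_distance") %in% names(ktable))) {
    stop("`ktable` must come from k_distance()", call. = FALSE)
  }
  med <- aggregate(k_distance ~ section_id + target_type, data = ktable,
                   FUN = median, na.action = na.omit, drop = FALSE)
  secs <- unique(ktable$section_id)
  types <- sort(unique(ktable$target_type))
  if (length(types) < 2) warning("fewer than 2 target types to rank")
  M <- matrix(NA_real_, length(secs), length(types),
              dimnames = list(secs, types))
  for (i in seq_len(nrow(med))) {
    M[med$section_id[i], med$target_type[i]] <- med$k_distance[i]
  }
  dropped <- rowSums(!is.na(M)) == 0
  if (any(dropped)) {
    warning("section(s) with no defined distances skipped: ",
            paste(secs[dropped], collapse = ", "))
    M <- M[!dropped, , drop = FALSE]
  }
  R <- t(apply(M, 1, function(v) {
    r <- rank(v, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- length(v)  # missing entries take the worst rank
    r
  }))
  colnames(R) <- types
  grp <- vapply(rownames(R), function(s) {
    ktable$group[ktable$section_id == s][1]
  }, character(1))
  attr(R, "group") <- grp
  R
}

#' Robust rank aggregation of per-section proximity rankings
#'
#' For each target type, the section ranks are normalized to (0, 1] by the
#' number of types, sorted ascending, and scored with the beta/binomial
#' order-statistic tail: for the k-th smallest normalized rank r(k) among m
#' sections, p_k = P(at least k of m independent uniforms <= r(k)); the rho
#' score is the minimum p_k over k, and the reported corrected score is the
#' Bonferroni bound min(1, n_types * rho). Small rho marks a type
#' consistently ranked near the reference across sections. The aggregate
#' ordering is ascending in rho and invariant to section order.
#'
#' @param ranks matrix of within-section ranks (sections x types), e.g. from
#'   \code{\link{rank_by_proximity}}.
#' @return data.frame of class \code{"rra_result"}: \code{type, rho,
#'   corrected, position} ordered ascending by rho (ties by type name).
#' @examples
#' R <- rbind(c(1, 2, 3), c(1, 3, 2), c(1, 2, 3))
#' colnames(R) <- c("A", "B", "C")
#' rra_aggregate(R)
#' @export
rra_aggregate <- function(ranks) {
  if (!is.matrix(ranks) || nrow(ranks) < 1) {
    stop("`ranks` must be a matrix with >= 1 row", call. = FALSE)
  }
  if (is.null(colnames(ranks))) {
    colnames(ranks) <- paste0("type", seq_len(ncol(ranks)))
  }
  n_types <- ncol(ranks)
  if (n_types == 1) warning("single type: aggregation is trivial")
  rho <- vapply(seq_len(n_types), function(j) {
    rra_rho(ranks[, j] / n_types)
  }, numeric(1))
  names(rho) <- colnames(ranks)
  out <- data.frame(type = names(rho), rho = rho,
                    corrected = pmin(1, n_types * rho),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rho, out$type), ]
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("rra_result", "data.frame")
  out
}

## rho for one normalized rank vector: min over k of the binomial tail
## P(Binom(m, r_(k)) >= k)
rra_rho <- function(r) {
  r <- sort(r)
  m <- length(r)
  p <- vapply(seq_len(m), function(k) {
    pbinom(k - 1, m, r[k], lower.tail = FALSE)
  }, numeric(1))
  min(p)
}

#' Compare k-distances between response groups
#'
#' Pools the per-reference-cell k-distances of one target type and compares
#' responder versus non-responder sections with a two-sided Wilcoxon
#' rank-sum test, reporting group medians, their difference and the p-value.
#'
#' @param ktable a \code{\link{k_distance}} result.
#' @param target_type target type to compare.
#' @return list: \code{median_R}, \code{median_NR}, \code{median_diff}
#'   (NR - R), \code{statistic}, \code{p_value}, \code{n_R}, \code{n_NR}.
#' @export
compare_groups <- function(ktable, target_type) {
  d <- ktable[ktable$target_type == target_type & !is.na(ktable$k_distance), ]
  dr <- d$k_distance[d$group == "R"]
  dn <- d$k_distance[d$group == "NR"]
  if (length(dr) == 0 || length(dn) == 0) {
    stop("both response groups need defined k-distances for '",
         target_type, "'", call. = FALSE)
  }
  wt <- wilcox.test(dn, dr, exact = FALSE)
  list(target_type = target_type,
       median_R = median(dr), median_NR = median(dn),
       median_diff = median(dn) - median(dr),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       n_R = length(dr), n_NR = length(dn))
}

check_spatial <- function(cells) {
  need <- c("cell_id", "x", "y", "cell_type", "section_id", "group")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    stop("spatial table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
    stop("non-finite coordinates in spatial table", call. = FALSE)
  }
  cells
}
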