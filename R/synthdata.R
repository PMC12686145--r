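#' Simulate multi-cohort expression data with a planted response signature
#'
#' Generates \code{n_cohorts} log2-scale expression cohorts (genes x samples)
#' with binary response labels. A set of \code{n_up} planted genes is shifted
#' upward and \code{n_down} genes downward in non-responders by
#' \code{effect_size} within-gene noise SDs; every (cohort, gene) pair
#' additionally receives one additive batch shift. The expression model is
#' Gaussian on the log2 scale: per-gene baselines are drawn N(6, 1) and
#' residual noise is N(0, \code{noise_sd}).
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort samples in each cohort.
#' @param n_genes total genes.
#' @param n_up planted genes elevated in non-responders.
#' @param n_down planted genes reduced in non-responders.
#' @param effect_size mean shift in units of the within-gene noise SD
#'   (>= 0; 0 gives a pure null).
#' @param nonresponder_fraction proportion of non-responders per cohort,
#'   in (0, 1).
#' @param batch_sd SD of the per-(cohort, gene) additive batch shift.
#' @param noise_sd residual SD on the log2 scale.
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return A list with class \code{"cohort_sim"}:
#'   \item{cohorts}{named list; each element has \code{expr} (genes x samples
#'     matrix) and \code{labels} (factor with levels R, NR).}
#'   \item{truth}{list with \code{up_genes}, \code{down_genes},
#'     \code{effect_size} and per-cohort label vectors.}
#' @examples
#' sim <- simulate_cohorts(n_cohorts = 2, samples_per_cohort = 20,
#'                         n_genes = 50, n_up = 5, n_down = 5,
#'                         effect_size = 1.5, seed = 1)
#' dim(sim$cohorts[[1]]$expr)
#' @export
simulate_cohorts <- function(n_cohorts = 5, samples_per_cohort = 100,
                             n_genes = 200, n_up = 20, n_down = 20,
                             effect_size = 1.5, nonresponder_fraction = 0.5,
                             batch_sd = 0.5, noise_sd = 1, seed = 1) {
  n_cohorts <- check_count(n_cohorts, "n_cohorts")
  samples_per_cohort <- check_count(samples_per_cohort, "samples_per_cohort", min = 2L)
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_up <- check_count(n_up, "n_up", min = 0L)
  n_down <- check_count(n_down, "n_down", min = 0L)
  if (n_up + n_down > n_genes) {
    stop("`n_up` + `n_down` must not exceed `n_genes`", call. = FALSE)
  }
  effect_size <- check_nonneg(effect_size, "effect_size")
  nonresponder_fraction <- check_fraction(nonresponder_fraction, "nonresponder_fraction")
  batch_sd <- check_nonneg(batch_sd, "batch_sd")
  noise_sd <- check_nonneg(noise_sd, "noise_sd")

  local_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    up_genes <- genes[seq_len(n_up)]
    down_genes <- genes[n_up + seq_len(n_down)]
    baseline <- rnorm(n_genes, mean = 6, sd = 1)
    names(baseline) <- genes
    shift <- setNames(numeric(n_genes), genes)
    shift[up_genes] <- effect_size * noise_sd
    shift[down_genes] <- -effect_size * noise_sd

    cohorts <- vector("list", n_cohorts)
    names(cohorts) <- sprintf("cohort%02d", seq_len(n_cohorts))
    truth_labels <- vector("list", n_cohorts)
    names(truth_labels) <- names(cohorts)

    n_nr <- max(1L, min(samples_per_cohort - 1L,
                        round(samples_per_cohort * nonresponder_fraction)))
    for (ci in seq_len(n_cohorts)) {
      batch <- rnorm(n_genes, 0, batch_sd)
      labels <- as_response(
        sample(c(rep("NR", n_nr), rep("R", samples_per_cohort - n_nr)))
      )
      is_nr <- as.numeric(labels == "NR")
      mu <- outer(baseline + batch, rep(1, samples_per_cohort)) +
        outer(shift, is_nr)
      expr <- mu + matrix(rnorm(n_genes * samples_per_cohort, 0, noise_sd),
                          n_genes, samples_per_cohort)
      dimnames(expr) <- list(genes,
                             sprintf("%s_S%03d", names(cohorts)[ci],
                                     seq_len(samples_per_cohort)))
      cohorts[[ci]] <- list(expr = expr, labels = labels)
      truth_labels[[ci]] <- setNames(as.character(labels), colnames(expr))
    }
    structure(list(
      cohorts = cohorts,
      truth = list(up_genes = up_genes, down_genes = down_genes,
                   effect_size = effect_size, labels = truth_labels)
    ), class = "cohort_sim")
  })
}

#' Simulate spatial tissue sections with a planted proximity ordering
#'
#' Places reference-type cells uniformly in a square section; each
#' target-type cell is then placed at a uniformly chosen reference cell plus
#' an isotropic Gaussian displacement whose SD (sigma) is type- and
#' group-specific (a parent-offspring, Neyman-Scott-like process).
#' Coordinates are clipped to the section box. Smaller sigma means a type
#' truly lies nearer the reference type, so the sigma ordering is the ground
#' truth that downstream k-distance ranking and rank aggregation must
#' recover.
#'
#' @param target_types data.frame with columns \code{type},
#'   \code{sigma_responder}, \code{sigma_nonresponder} (all sigmas > 0,
#'   coordinate units).
#' @param n_sections_responder,n_sections_nonresponder sections per response
#'   group.
#' @param section_extent box width/height in coordinate units.
#' @param reference_type name of the reference cell type (e.g. "iCAF").
#' @param cells_per_type cells placed per type per section.
#' @param seed integer seed.
#'
#' @return list with class \code{"spatial_sim"}: \code{cells} (data.frame
#'   \code{cell_id,x,y,cell_type,section_id,group}) and \code{truth} (per
#'   group, target types ordered nearest-first by sigma).
#' @examples
#' tt <- data.frame(type = c("Tex", "Teff"),
#'                  sigma_responder = c(10, 2),
#'                  sigma_nonresponder = c(2, 10))
#' sim <- simulate_sections(tt, seed = 1)
#' head(sim$cells)
#' @export
simulate_sections <- function(target_types,
                              n_sections_responder = 5,
                              n_sections_nonresponder = 5,
                              section_extent = 100,
                              reference_type = "iCAF",
                              cells_per_type = 50,
                              seed = 1) {
  if (!is.data.frame(target_types) || nrow(target_types) == 0) {
    stop("`target_types` must be a non-empty data.frame", call. = FALSE)
  }
  need <- c("type", "sigma_responder", "sigma_nonresponder")
  if (!all(need %in% names(target_types))) {
    stop("`target_types` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(target_types$type) ||
      reference_type %in% target_types$type) {
    stop("cell-type names must be distinct (and not the reference type)",
         call. = FALSE)
  }
  if (any(target_types$sigma_responder <= 0) ||
      any(target_types$sigma_nonresponder <= 0)) {
    stop("all sigma values must be > 0", call. = FALSE)
  }
  n_sections_responder <- check_count(n_sections_responder,
                                      "n_sections_responder", min = 0L)
  n_sections_nonresponder <- check_count(n_sections_nonresponder,
                                         "n_sections_nonresponder", min = 0L)
  if (n_sections_responder + n_sections_nonresponder == 0) {
    stop("at least one section is required", call. = FALSE)
  }
  cells_per_type <- check_count(cells_per_type, "cells_per_type")
  section_extent <- check_nonneg(section_extent, "section_extent")

  local_seed(seed, {
    groups <- c(rep("R", n_sections_responder), rep("NR", n_sections_nonresponder))
    sections <- sprintf("sec%02d", seq_along(groups))
    out <- vector("list", length(sections))
    for (si in seq_along(sections)) {
      grp <- groups[si]
      rx <- runif(cells_per_type, 0, section_extent)
      ry <- runif(cells_per_type, 0, section_extent)
      rows <- list(data.frame(
        x = rx, y = ry, cell_type = reference_type,
        stringsAsFactors = FALSE))
      for (ti in seq_len(nrow(target_types))) {
        sig <- if (grp == "R") target_types$sigma_responder[ti] else
          target_types$sigma_nonresponder[ti]
        parent <- sample.int(cells_per_type, cells_per_type, replace = TRUE)
        tx <- pmin(pmax(rx[parent] + rnorm(cells_per_type, 0, sig), 0), section_extent)
        ty <- pmin(pmax(ry[parent] + rnorm(cells_per_type, 0, sig), 0), section_extent)
        rows[[ti + 1L]] <- data.frame(
          x = tx, y = ty, cell_type = target_types$type[ti],
          stringsAsFactors = FALSE)
      }
      sec <- do.call(rbind, rows)
      sec$section_id <- sections[si]
      sec$group <- grp
      out[[si]] <- sec
    }
    cells <- do.call(rbind, out)
    cells$cell_id <- sprintf("cell%06d", seq_len(nrow(cells)))
    cells <- cells[, c("cell_id", "x", "y", "cell_type", "section_id", "group")]
    rownames(cells) <- NULL
    truth <- list(
      R = target_types$type[order(target_types$sigma_responder)],
      NR = target_types$type[order(target_types$sigma_nonresponder)]
    )
    structure(list(cells = cells, truth = truth,
                   reference_type = reference_type),
              class = "spatial_sim")
  })
}

#' Simulate a single-cell QC table with planted rule violators
#'
#' Emits per-cell \code{umi_count}, \code{n_genes} and \code{pct_mito} such
#' that designated fractions of cells violate exactly one QC rule each
#' (UMI too high, too few genes, too many genes, mitochondrial fraction too
#' high) while all remaining cells pass every rule. Thresholds match
#' \code{\link{qc_filter}}: remove iff umi > 40000, genes < 500,
#' genes > 5000 or pct_mito > 20.
#'
#' @param n_cells number of cells.
#' @param fail_fractions named numeric vector with entries \code{umi_high},
#'   \code{gene_low}, \code{gene_high}, \code{mito_high}; each in [0, 1],
#'   summing to at most 1.
#' @param seed integer seed.
#' @return list: \code{cells} (data.frame \code{cell_id, umi_count, n_genes,
#'   pct_mito}) and \code{truth} (data.frame \code{cell_id, rule} of planted
#'   violators).
#' @examples
#' tab <- simulate_cell_qc_table(100, c(mito_high = 0.1), seed = 1)
#' nrow(tab$truth)
#' @export
simulate_cell_qc_table <- function(n_cells = 1000,
                                   fail_fractions = c(umi_high = 0.02,
                                                      gene_low = 0.02,
                                                      gene_high = 0.02,
                                                      mito_high = 0.02),
                                   seed = 1) {
  n_cells <- check_count(n_cells, "n_cells")
  rules <- c("umi_high", "gene_low", "gene_high", "mito_high")
  ff <- setNames(numeric(4), rules)
  if (length(fail_fractions) > 0) {
    bad <- setdiff(names(fail_fractions), rules)
    if (length(bad) > 0 || is.null(names(fail_fractions))) {
      stop("`fail_fractions` names must be among: ",
           paste(rules, collapse = ", "), call. = FALSE)
    }
    ff[names(fail_fractions)] <- fail_fractions
  }
  if (any(ff < 0) || any(ff > 1) || sum(ff) > 1) {
    stop("`fail_fractions` must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }

  local_seed(seed, {
    n_fail <- floor(ff * n_cells)
    idx <- sample.int(n_cells)  # shuffle so violators are scattered
    assign_rule <- rep("pass", n_cells)
    pos <- 0L
    for (r in rules) {
      if (n_fail[[r]] > 0) {
        assign_rule[idx[pos + seq_len(n_fail[[r]])]] <- r
        pos <- pos + n_fail[[r]]
      }
    }
    # clean baseline well inside all thresholds
    umi <- round(runif(n_cells, 2000, 30000))
    genes <- round(runif(n_cells, 800, 4500))
    mito <- runif(n_cells, 0, 15)
    umi[assign_rule == "umi_high"] <- round(runif(sum(assign_rule == "umi_high"),
                                                  40001, 80000))
    genes[assign_rule == "gene_low"] <- round(runif(sum(assign_rule == "gene_low"),
                                                    0, 499))
    genes[assign_rule == "gene_high"] <- round(runif(sum(assign_rule == "gene_high"),
                                                     5001, 9000))
    mito[assign_rule == "mito_high"] <- runif(sum(assign_rule == "mito_high"),
                                              20.001, 95)
    cells <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      umi_count = as.integer(umi),
      n_genes = as.integer(genes),
      pct_mito = mito,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(cell_id = cells$cell_id[assign_rule != "pass"],
                        rule = assign_rule[assign_rule != "pass"],
                        stringsAsFactors = FALSE)
    list(cells = cells, truth = truth)
  })
}
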