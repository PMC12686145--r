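#' Read an expression matrix
#'
#' Dense TSV/CSV (gene ids in the first column, sample ids in the header) or
#' MatrixMarket triplet (with companion row/column id files). Duplicate gene
#' ids are collapsed by their mean with a warning; non-numeric cells are an
#' error naming the offending row and column.
#'
#' @param path matrix file; \code{.csv} is comma-separated, \code{.mtx} is
#'   MatrixMarket, anything else is read as TSV.
#' @param rows,cols for MTX input: paths to one-id-per-line gene and sample
#'   id files.
#' @return numeric genes x samples matrix.
#' @export
read_expression <- function(path, rows = NULL, cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(rows) || is.null(cols)) {
      stop("MTX input needs `rows` and `cols` id files", call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rows)
    cn <- readLines(cols)
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("row/column id files do not match the MTX dimensions", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
    return(collapse_dup_genes(m))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty expression file: ", path,
                                          call. = FALSE)
  genes <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(genes, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s'",
                   vals[[j]][bad[1]], bad[1], genes[bad[1]],
                   colnames(vals)[j]), call. = FALSE)
    }
    m[, j] <- v
  }
  collapse_dup_genes(m)
}

collapse_dup_genes <- function(m) {
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    warning("collapsing ", length(dup), " duplicated gene id(s) by mean: ",
            paste(head(dup, 5), collapse = ", "))
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(factor(rownames(m), levels = unique(rownames(m)))))
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Genes in rows (first column \code{gene}), sample ids as header; the
#' format \code{\link{read_expression}} reads back.
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read response labels
#'
#' Two-column CSV \code{sample_id,response} with response values R or NR.
#'
#' @param path CSV path.
#' @return named factor (levels R, NR) keyed by sample id.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "response") %in% names(df))) {
    stop("labels file needs columns sample_id,response", call. = FALSE)
  }
  setNames(as_response(df$response), df$sample_id)
}

#' @rdname read_labels
#' @param labels named R/NR vector.
#' @export
write_labels <- function(labels, path) {
  write.csv(data.frame(sample_id = names(labels),
                       response = as.character(labels)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then gene ids. Lines
#' with fewer than three fields are an error naming the line; duplicate
#' genes within a line are dropped with a warning.
#'
#' @param path GMT path.
#' @return named list of character vectors (gene sets, in file order).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", f[1], "' (line ", i, ") has duplicate genes; dropped")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spatial cell table
#'
#' CSV with columns \code{cell_id,x,y,cell_type,section_id,group}; group
#' values must be R or NR and coordinates finite, otherwise an error names
#' the offending row or value.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_spatial_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", "cell_type", "section_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("spatial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad) > 0) {
    stop("non-finite coordinate at row ", bad[1], " (cell ",
         df$cell_id[bad[1]], ")", call. = FALSE)
  }
  badg <- setdiff(unique(df$group), c("R", "NR"))
  if (length(badg) > 0) {
    stop("unknown group value(s): ", paste(badg, collapse = ", "),
         "; allowed values are R, NR", call. = FALSE)
  }
  df[, need]
}

#' @rdname read_spatial_table
#' @param cells spatial cell data.frame.
#' @export
write_spatial_table <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
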