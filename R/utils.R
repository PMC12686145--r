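## internal helpers shared across modules

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so callers' RNG state is untouched;
#' all exported stochastic functions route their randomness through this.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## derive a reproducible sub-seed from a base seed and a string tag,
## kept within 32-bit integer range
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483587L) + 1L
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a proportion %s", name,
                 if (open) "in (0, 1)" else "in [0, 1]"), call. = FALSE)
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative number", name), call. = FALSE)
  }
  as.numeric(x)
}

## response labels are stored as a factor with levels R (responder) and
## NR (non-responder); NR is the positive class everywhere
as_response <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("R", "NR"))
  if (length(bad) > 0) {
    stop("response labels must be 'R' or 'NR'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(labels, levels = c("R", "NR"))
}

response01 <- function(labels) as.integer(as_response(labels) == "NR")
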