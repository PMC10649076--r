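# Internal helpers shared across the pipeline stages.

#' @import data.table
#' @importFrom stats approx cor dist median optimize predict quantile rbinom
#'   rlnorm rnorm rpois runif sd setNames var
#' @importFrom utils head packageVersion tail
NULL

item_cols <- function() paste0("item", 1:9)
presence_cols <- function() paste0("present", 1:9)
ss_cols <- function() paste0("ss", 1:9)
sp_cols <- function() paste0("sp", 1:9)
prob_cols <- function() paste0("p", 1:9)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Population variance (divide by n). The daily feature "variance" columns use
# this convention throughout.
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assert that a data.frame-like input carries the required columns; the error
# names the first missing one so CSV schema problems are actionable.
check_columns <- function(x, required, what = "input") {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop_config("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

as_dt <- function(x, what = "input") {
  if (!is.data.frame(x)) stop_config("%s must be a data.frame or data.table", what)
  data.table::as.data.table(x)
}
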