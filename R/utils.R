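#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rlnorm glm binomial coef plogis
#'   qlogis qnorm pnorm sd var quantile predict lm vcov median
#' @importFrom utils head tail write.csv read.csv
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_copdct <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "copdct_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x)) ||
      (!is.na(x) && (x < lower || x > upper))) {
    stop_copdct(
      sprintf("invalid value for '%s': must be a number in [%s, %s]",
              name, format(lower), format(upper)),
      "copdct_config_error", field = name
    )
  }
  invisible(x)
}
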