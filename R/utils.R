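#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so seeded helpers do not disturb the caller's stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# linear interpolation in log-log space; x, y on linear scale, y > 0
loglog_interp <- function(x, y, xout) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 2) return(rep(NA_real_, length(xout)))
  stats::approx(log10(x[ok]), log10(y[ok]), xout = log10(xout),
                rule = 1)$y
}
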