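# Internal helpers shared across modules.

#' @importFrom methods as is
#' @importFrom stats complete.cases cor dnorm kmeans median optimize pnorm pt
#'   qt quantile rbinom rgeom rmultinom rnbinom rnorm rpois runif sd setNames
#'   var wilcox.test plogis p.adjust
#' @importFrom utils read.delim write.table read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_tme <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort_tme("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_tme("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    abort_tme("'%s' must be in [%s, %s]", name, lower, upper)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) abort_tme("'%s' must be an integer", name)
  invisible(as.integer(x))
}

# Deterministic named substream seeds: one root seed fans out to independent
# module-level streams (expression, tcr, spatial, ihc, ...) so components can
# be regenerated in isolation. Kept below 2^31 - 1.
substream_seed <- function(root_seed, stream) {
  check_count(root_seed, "seed")
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(root_seed) * 48271 + h) %% 2147483629 + 1)
}

# Evaluate expr under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
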