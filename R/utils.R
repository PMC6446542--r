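#' @importFrom stats rnorm rlnorm rbinom rmultinom rnbinom rgamma runif
#'   binom.test p.adjust pchisq pt t.test cor kmeans sd var median runmed
#'   coef predict complete.cases quantile
#' @importFrom utils head tail
#' @importFrom methods is
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Discrete Gaussian kernel density smoothing of a per-base count vector.
# sd = 0 returns the input unchanged; kernel is truncated at 4 sd and
# renormalized so total signal is preserved.
smooth_gaussian <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- ceiling(4 * sd)
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(half), x, numeric(half))
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x)
is_frac <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1
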