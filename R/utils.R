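#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd var rnorm rlnorm runif aov TukeyHSD pf pt qt
#'   coef vcov fitted residuals predict confint as.dist cutree setNames
#'   quantile
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators route randomness through
# here so no call touches global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Multiplicative lognormal noise with unit mean and coefficient of variation
# `cv` (cv = 0 gives exactly 1). Readings are positive and their spread grows
# with the mean, which this model reproduces.
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Four-parameter log-logistic response at dose d (nM); vehicle (d = 0) sits
# on the bottom plateau by construction.
fourpl_response <- function(d, bottom, emax, hill, ec50) {
  ifelse(d <= 0, bottom,
         bottom + (emax - bottom) / (1 + 10^(hill * (log10(ec50) - log10(d)))))
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}
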