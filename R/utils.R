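#' @importFrom stats coef cor lm median pnorm pt qnorm quantile rbinom rnorm
#'   rpois runif sd setNames t.test ks.test var
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation helpers do not perturb
# the global stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

assertScalarNumber <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

assertFiniteVector <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop(sprintf("'%s' contains %d non-finite value(s); first at index %d",
                 name, length(bad), bad[1L]), call. = FALSE)
  }
  invisible(x)
}

# Deterministic number formatting for CSV output: 15 significant digits round-trips
# doubles; integers stay integral so repeated runs are byte-identical.
formatNumber <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    sprintf("%.15g", v)
  }, character(1))
  out
}

# Write a data.frame as CSV with deterministic float formatting.
writeTableCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- formatNumber(out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
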