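#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats coef glm lm pnorm pt qnorm rbinom rlnorm rnorm rpois
#'   runif sd t.test wilcox.test cor.test binomial predict var plogis qlogis
#'   lm.wfit glm.fit
#' @importFrom utils head write.csv read.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never clobber it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
}

stopifnot_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must lie strictly inside (0, 1)", name), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
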