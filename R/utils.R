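#' @importFrom rlang abort warn %||% .data
#' @importFrom stats median quantile sd var cor optim optimize uniroot qnorm
#'   pchisq qchisq rnorm runif lm residuals coef model.matrix p.adjust
#'   complete.cases setNames t.test var.test
#' @importFrom utils head
NULL

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
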