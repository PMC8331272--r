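#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd quantile
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort
NULL

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_mcdreg <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mcdreg_error"))
}

check_shape_equal <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:3], dim(b)[1:3])) {
    stop_mcdreg(
      sprintf("%s have mismatched spatial shapes: (%s) vs (%s)",
              what, paste(dim(a)[1:3], collapse = ","),
              paste(dim(b)[1:3], collapse = ",")),
      "mcdreg_shape_error"
    )
  }
  invisible(TRUE)
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop_mcdreg(sprintf("%s contains non-finite values", what),
                "mcdreg_value_error")
  }
  invisible(TRUE)
}
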