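#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  code
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("memoryfoam_invalid_input", "error")))
}

stop_singular_time <- function(...) {
  stop(errorCondition(paste0(...), class = c("memoryfoam_singular_time", "error")))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop_invalid(what, " must be finite numeric")
  }
  invisible(x)
}

#' @keywords internal
as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}
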