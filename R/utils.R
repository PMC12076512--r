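#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise
#'   ungroup left_join distinct n row_number across all_of
#' @importFrom stats rnorm runif sd median quantile predict setNames cor
#' @importFrom utils head tail
NULL

profis_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "profis_error"), ...)
}

# seeded RNG scope: runs expr with a private RNG state, restoring the caller's
`with_seed` <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
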