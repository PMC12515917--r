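#' Turn a ctgkit object into a tidy tibble
#'
#' Broom-style generics: `tidy()` returns one row per component
#' (sample, event, ROC point, ...), `glance()` a one-row summary.
#'
#' @param x Object to tidy.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
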