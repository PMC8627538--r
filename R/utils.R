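#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can test errorConditionclasses rather than
# match message text.
rh_stop <- function(type, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("radiohet_", type), "radiohet_error")))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed vocabulary of lesion site classes.
SITE_CLASSES <- c("REGIONAL_LN", "DISTANT_LN", "BONE")

# population moments used throughout the first-order family
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
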