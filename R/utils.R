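#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes programmatically.
ss_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "surgsound_error"),
                      call = call))
}

ss_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "surgsound_warning")))
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one top-level seed. Independent
#' stages (synthesis, splitting, backbone weights, training) draw from named
#' sub-streams so that changing one stage's consumption of random numbers
#' never perturbs another stage.
#'
#' @param seed Integer top-level seed.
#' @param stream Character stream name, e.g. `"synth"`, `"split"`,
#'   `"backbone"`, `"train"`.
#' @return An integer seed, strictly below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97 + 11) %% 2147483629)
}

# Evaluate `expr` with a locally-set RNG state, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# dB <-> linear amplitude helpers (amplitude convention: 20 log10)
db_to_amp <- function(db) 10^(db / 20)
amp_to_db <- function(a) 20 * log10(a)

rms <- function(x) sqrt(mean(x^2))
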