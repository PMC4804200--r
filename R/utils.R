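# Small shared helpers.

# Deterministic derivation of per-stage / per-item seeds from one global
# seed. Kept below 2^31 - 1 so set.seed() always accepts the result.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# char vector <-> string helpers for the simulators
chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
string_of <- function(chars) paste0(chars, collapse = "")
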