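# Internal helpers shared across modules.

DOMAINS <- c("bacteria", "fungi", "archaea")
DOMAIN_PREFIX <- c(bacteria = "bac|", fungi = "fun|", archaea = "arc|")

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's stream. `seed = NULL` uses the current stream (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable per-stage seed derivation: keeps every derived seed a valid 32-bit
# integer and guarantees distinct stages get distinct streams.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + offset) %% .Machine$integer.max)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a group selector of the form "PL:G" (disturbance:surface) or "C"
# (disturbance only) into a named list.
parse_group <- function(selector) {
  abort_if(!is.character(selector) || length(selector) != 1 ||
             !nzchar(selector),
           "group selector must be a single non-empty string like 'PL:G' or 'C'")
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  list(disturbance = parts[[1]],
       surface = if (length(parts) > 1) parts[[2]] else NULL)
}

upper_tri_vec <- function(m) m[upper.tri(m)]
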