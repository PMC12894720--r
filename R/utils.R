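# Internal helpers: RNG stream management and small numeric utilities.

#' Evaluate an expression without disturbing the caller's RNG state
#'
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
#' @noRd
with_preserved_rng <- function(expr) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  expr
}

# L'Ecuyer-CMRG substream states derived from a master seed.  Substream i is a
# pure function of (seed, i), so per-unit results do not depend on how many
# units are simulated or in which order they are visited.
rng_substreams <- function(seed, n, stream_offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(seed))
  s <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  for (k in seq_len(stream_offset)) s <- parallel::nextRNGStream(s)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGSubStream(s)
    out[[i]] <- s
  }
  out
}

set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# deterministic child seeds (for stages that each reseed independently)
derive_seeds <- function(seed, n) {
  with_preserved_rng({
    RNGkind("L'Ecuyer-CMRG")
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, n)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

stop_fk <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
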