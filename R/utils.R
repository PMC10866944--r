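#' Derive a child seed from a parent seed and stream labels
#'
#' One global seed fans out to per-stage / per-fold / per-epoch streams via
#' stable integer hashing; results stay below 2^31.
#'
#' @param seed parent integer seed
#' @param ... integers identifying the stream (e.g. fold, epoch)
#' @return integer seed
#' @export
deriveSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  # multiplier small enough that h * mult stays exactly representable in
  # a double (2^31 * 69069 < 2^53), so every argument perturbs the hash
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 12345) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#' @param seed integer seed
#' @param expr expression
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.onehot <- function(idx, C) {
  # idx: array of 0-based class indices -> array [dim(idx), C]
  d <- dim(idx)
  out <- array(0, dim = c(length(idx), C))
  out[cbind(seq_along(idx), as.integer(idx) + 1L)] <- 1
  dim(out) <- c(d, C)
  out
}
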