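`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. The seed is forced *before* the RNG state is snapshotted, so
# seed expressions that themselves draw from the caller's RNG stream (e.g.
# sample.int()) are not rolled back by the restore.
with_local_seed <- function(seed, code) {
  seed <- as.integer(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), normal.kind = "Kinderman-Ramage")
  force(code)
}

stop_veptime <- function(..., class = "veptime_error") {
  stop(errorCondition(paste0(...), class = c(class, "veptime_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_veptime(name, " must be a single finite number")
  if (positive && x <= 0)
    stop_veptime(name, " must be positive")
  invisible(x)
}

# Centred boxcar smoother with edge replication; width in samples (odd).
boxcar_smooth <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[(h + 1L):(h + length(x))]
}
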