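`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Numeric -> text used by all writers: full double precision, NA as "NA".
formatValues <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, trim = TRUE)
  }, character(1))
  out
}

parseValues <- function(x) {
  x[x %in% c("", "NA", "NaN", "nan")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
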