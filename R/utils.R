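# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Full-precision numeric formatting for lossless text round trips.
fmt_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

stopifnot_len52 <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (length(v) != 52L)
      stop(nm, " must have exactly 52 weekly values (got ", length(v), ")")
    if (anyNA(v))
      stop("gap in weekly series: ", nm, " contains missing values")
  }
  invisible(TRUE)
}
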