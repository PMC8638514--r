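## Internal helpers: seeded evaluation, seed derivation, atomic writes.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package code
#' never perturbs the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and integer keys
#'
#' Splittable seeding: every random component of the package draws from
#' its own derived stream so no global RNG state is shared.  Plain
#' integer mixing (LCG steps keyed by each argument), kept below 2^31.
#' @noRd
derive_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in keys) {
    x <- (x * 69069 + 12345 + 2654435.0 * (as.double(k) %% 65536)) %% 2147483647
  }
  as.integer(floor(x))
}

#' Atomic file write: write to a temp path in the same directory, then rename
#' @noRd
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to move temporary file onto ", path)
  ok <- TRUE
  invisible(path)
}

## FNV-1a string hash, for reproducibility headers in logs.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
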