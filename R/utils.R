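# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generation never
#' perturbs the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive per-unit child seeds from a master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# md5 of a file, used for provenance records.
file_checksum <- function(path) {
  unname(tools::md5sum(path))
}

# md5 of an arbitrary R object (serialized to a temp file).
object_checksum <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(x, tmp, version = 2)
  file_checksum(tmp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
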