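## Content-addressed result cache. Keys hash the *content* of the inputs plus
## the operation name and every parameter, never a path or mtime alone, so a
## stale entry can only be returned for genuinely identical work. Entries are
## .rds files in a dot-directory; the store is size-capped and evicted LRU.

#' Content hash of inputs and parameters
#'
#' Builds a cache key from the data an operation consumes and every parameter
#' that influences its result. Objects are serialized and hashed (128-bit
#' xxHash), so editing a single trajectory value or changing a bin count
#' yields a different key.
#'
#' @param ... the inputs and parameters of the computation, including a string
#'   naming the operation.
#' @return A hex string key.
#' @examples
#' cacheKey("pdfAt", c(1, 2, 3), t = 10, nBins = "auto")
#' @export
cacheKey <- function(...) rlang::hash(list(...))

#' Memoise a computation under a content-derived key
#'
#' Returns the cached result for `key` if present, otherwise evaluates
#' `thunk`, stores the result and returns it. A corrupt cache entry is never
#' allowed to produce a wrong answer: it is discarded with a warning and the
#' computation re-run. With `enabled = FALSE` the thunk is evaluated
#' unconditionally, so caching is transparent to results.
#'
#' @param key a key from [cacheKey()].
#' @param thunk a zero-argument function performing the computation.
#' @param cacheDir directory holding the store (created on demand); defaults
#'   to `.ek-cache` under [tempdir()].
#' @param enabled set `FALSE` to bypass the cache entirely.
#' @param maxBytes size cap for the store; least-recently-used entries are
#'   evicted once it is exceeded (default 256 MiB).
#' @return The computed (or cached) value, identical either way. Whether the
#'   store served the last call can be queried with [cacheLastHit()].
#' @export
cacheGetOrCompute <- function(key, thunk, cacheDir = file.path(tempdir(), ".ek-cache"),
                              enabled = TRUE, maxBytes = 256 * 1024^2) {
  .cacheState$lastHit <- FALSE
  if (!enabled) return(thunk())
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  entry <- file.path(cacheDir, paste0(key, ".rds"))
  if (file.exists(entry)) {
    val <- tryCatch(readRDS(entry), error = function(e) {
      warning(sprintf("corrupt cache entry %s: recomputing", basename(entry)))
      unlink(entry)
      NULL
    })
    if (!is.null(val)) {
      Sys.setFileTime(entry, Sys.time())  # LRU bookkeeping
      .cacheState$lastHit <- TRUE
      return(val)
    }
  }
  val <- thunk()
  saveRDS(val, entry)
  .cacheEvict(cacheDir, maxBytes)
  val
}

.cacheState <- new.env(parent = emptyenv())
.cacheState$lastHit <- FALSE

#' Did the last `cacheGetOrCompute()` call hit the store?
#' @return logical flag.
#' @export
cacheLastHit <- function() .cacheState$lastHit

# Drop least-recently-touched entries until the store fits the cap.
.cacheEvict <- function(cacheDir, maxBytes) {
  info <- file.info(list.files(cacheDir, pattern = "\\.rds$", full.names = TRUE))
  if (!nrow(info) || sum(info$size) <= maxBytes) return(invisible())
  info <- info[order(info$mtime), ]
  drop <- cumsum(rev(info$size))  # keep newest
  keep <- rev(drop <= maxBytes)
  unlink(rownames(info)[!keep])
  invisible()
}
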