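# In-memory result cache for expensive wave-optics computations.
#
# PSFs and Debye radial profiles are deterministic functions of the optical
# configuration and the source position, and the same ones are requested many
# times while building dictionaries and rendering ball volumes (every lattice
# point of every ball).  A small LRU cache keyed on the exact numeric inputs
# makes repeated renders cheap without changing any result.

.lfm_cache <- new.env(parent = emptyenv())

cache_key <- function(...) {
  parts <- lapply(list(...), function(x) paste(format(x, digits = 17), collapse = ","))
  paste(unlist(parts), collapse = "|")
}

cache_get <- function(store, key) {
  env <- cache_env(store)
  if (!exists(key, envir = env, inherits = FALSE)) return(NULL)
  entry <- get(key, envir = env, inherits = FALSE)
  entry$stamp <- .lfm_cache$clock <- (.lfm_cache$clock %||% 0) + 1
  assign(key, entry, envir = env)
  entry$value
}

cache_set <- function(store, key, value, max_entries = getOption("lfmepi.cache_max", 800L)) {
  env <- cache_env(store)
  .lfm_cache$clock <- (.lfm_cache$clock %||% 0) + 1
  assign(key, list(value = value, stamp = .lfm_cache$clock), envir = env)
  keys <- ls(env, all.names = TRUE)
  if (length(keys) > max_entries) {
    stamps <- vapply(keys, function(k) get(k, envir = env)$stamp, numeric(1))
    drop <- keys[order(stamps)][seq_len(length(keys) - max_entries)]
    rm(list = drop, envir = env)
  }
  invisible(value)
}

cache_env <- function(store) {
  if (is.null(.lfm_cache[[store]])) .lfm_cache[[store]] <- new.env(parent = emptyenv())
  .lfm_cache[[store]]
}

#' Clear the internal simulation cache
#'
#' Rendered point-spread functions and Debye radial profiles are cached in
#' memory so that repeated renders of the same geometry (e.g. every lattice
#' point of a ball volume, or the same depth across fixtures) are computed only
#' once.  The cache is transparent; this function empties it.
#'
#' @return Invisibly, `NULL`.
#' @export
clear_lfm_cache <- function() {
  rm(list = ls(.lfm_cache, all.names = TRUE), envir = .lfm_cache)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
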