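# Checkpointing of densities and orbital spaces, so partitioning scans
# (e.g. over the number of active waters) can reuse the initial
# diagonalization. Uses R's native serialization with a small schema
# wrapper; the format is versioned so readers can reject foreign files.

.checkpoint_version <- 1L

#' Save / load calculation checkpoints
#'
#' `save_checkpoint()` stores any of the package's state objects (guess or
#' purified densities, partitioned densities, orbital spaces, frozen terms)
#' with metadata; `load_checkpoint()` restores them, checking the schema
#' version.
#'
#' @param object the object to store.
#' @param path file path (conventionally `.chk.rds`).
#' @param metadata optional named list stored alongside.
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` a
#'   list with `object`, `metadata`, `created`, `version`.
#' @export
save_checkpoint <- function(object, path, metadata = list()) {
  payload <- list(version = .checkpoint_version,
                  created = format(Sys.time(), tz = "UTC"),
                  class = class(object),
                  metadata = metadata,
                  object = object)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  payload <- readRDS(path)
  if (!identical(payload$version, .checkpoint_version)) {
    stop("checkpoint version ", payload$version, " not supported")
  }
  payload
}
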