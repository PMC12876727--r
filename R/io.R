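#' Write / read epoch sets as HDF5
#'
#' Layout: datasets `voltages` (trials x channels x timepoints),
#' `times_ms`, `channels`, and a `trial_keys` compound of subject/block/
#' trial columns; the lock type is stored as an attribute on `voltages`.
#'
#' @param epochs an [epoch_set()].
#' @param path file path (overwritten).
#' @return `read_epochs` returns an [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$voltages, path, "voltages")
  rhdf5::h5write(epochs$times_ms, path, "times_ms")
  rhdf5::h5write(epochs$channels, path, "channels")
  rhdf5::h5write(as.character(epochs$trial_keys$subject_id), path,
                 "key_subject")
  rhdf5::h5write(as.integer(epochs$trial_keys$block), path, "key_block")
  rhdf5::h5write(as.integer(epochs$trial_keys$trial), path, "key_trial")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "voltages")
  rhdf5::h5writeAttribute(epochs$lock, did, "lock")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  v <- rhdf5::h5read(path, "voltages")
  lock <- rhdf5::h5readAttributes(path, "voltages")$lock
  epoch_set(
    v,
    channels = as.character(rhdf5::h5read(path, "channels")),
    times_ms = as.numeric(rhdf5::h5read(path, "times_ms")),
    lock = lock,
    trial_keys = data.frame(
      subject_id = as.character(rhdf5::h5read(path, "key_subject")),
      block = as.integer(rhdf5::h5read(path, "key_block")),
      trial = as.integer(rhdf5::h5read(path, "key_trial")),
      stringsAsFactors = FALSE))
}

#' Write / read fitted parameters as JSON
#'
#' @param params an [rlwm_params()] or a list of them.
#' @param path file path.
#' @return `read_params_json` returns an [rlwm_params()] (or list).
#' @export
write_params_json <- function(params, path) {
  to_rec <- function(p) p[c("alpha", "gamma", "phi", "rho",
                            "capacity", "epsilon")]
  x <- if (inherits(params, "rlwm_params")) to_rec(params)
       else lapply(params, to_rec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_rec <- function(r) rlwm_params(r$alpha, r$gamma, r$phi, r$rho,
                                      r$capacity, r$epsilon)
  if (!is.null(x$alpha)) from_rec(x) else lapply(x, from_rec)
}

#' Write / read latent traces as CSV
#'
#' Keyed by (subject_id, block, trial) for joining onto trial tables.
#'
#' @param latents latent trace data.frame (with `subject_id`).
#' @param path file path.
#' @return `read_latents` returns the data.frame.
#' @export
write_latents <- function(latents, path) {
  utils::write.csv(latents, path, row.names = FALSE)
}

#' @rdname write_latents
#' @export
read_latents <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
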