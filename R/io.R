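#' Read an 8-bit grayscale slice
#'
#' Reads a PNG (first channel, rescaled to 0..255) or a NIfTI file (first
#' slice of the first volume; values clipped to 0..255 and rounded) into the
#' integer matrix form the pipeline works on.
#'
#' @param path file path ending in `.png`, `.nii` or `.nii.gz`.
#' @return integer matrix with values in 0..255.
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    out <- round(img * 255)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    n_slice <- d[1] * d[2]
    vals <- as.numeric(vol)[seq_len(n_slice)]  # first slice of the first volume
    out <- matrix(round(pmin(255, pmax(0, vals))), d[1], d[2])
  } else {
    stop("unsupported image format (use PNG or NIfTI): ", path, call. = FALSE)
  }
  matrix(as.integer(out), nrow(out), ncol(out))
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  mask <- assert_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a binary mask from a PNG
#'
#' Pixels above half intensity are foreground.
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  read_slice(path) > 127
}

#' Read pipeline settings from a YAML config file
#'
#' Keys mirror the arguments of [menseg_config()]; unknown keys are an
#' error. Values given in the file override the defaults.
#'
#' @param path YAML file path.
#' @return a `menseg_config` object.
#' @export
read_menseg_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(menseg_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(menseg_config, vals)
}

#' Write pipeline settings to a YAML config file
#'
#' @param config a `menseg_config` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_menseg_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
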