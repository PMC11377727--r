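# Stack and volume I/O: multi-page 16-bit TIFF intensity stacks with JSON
# sidecar metadata, and 32-bit float TIFF volumes with JSON sidecars.

#' Write an intensity stack
#'
#' Writes one multi-page 16-bit grayscale TIFF (page order = schedule order)
#' plus a JSON sidecar recording wavelengths (nm), defocus distance, pixel
#' pitch, medium index, seed and the quantization scale.  The scale maps
#' intensity 1.0 to a recorded count so normalization is exactly invertible;
#' the 16-bit payload round-trips write/read bit-exactly.
#'
#' @param frames list of \code{\link{intensity_frame}}s.
#' @param path TIFF path.
#' @param sidecar JSON sidecar path (default: \code{path} with .json).
#' @param meta extra metadata list merged into the sidecar.
#' @param scale counts per unit intensity; default fills 90\% of the 16-bit
#'   range at the stack maximum.
#' @return Invisibly, the sidecar list.
#' @export
write_stack <- function(frames, path, sidecar = NULL, meta = list(),
                        scale = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  mx <- max(vapply(frames, function(f) max(f$I), 0))
  if (is.null(scale)) scale <- floor(0.9 * 65535 / max(mx, 1e-12))
  pages <- lapply(frames, function(f) {
    cts <- round(f$I * scale)
    if (any(cts > 65535)) stop("scale overflows the 16-bit range")
    cts / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sc <- utils::modifyList(list(
    wavelengths_nm = vapply(frames, function(f) f$lambda * 1000, 0),
    z_D_um = frames[[1]]$z_D,
    pitch_um = frames[[1]]$pitch,
    scale = scale,
    bit_depth = 16L), meta)
  jsonlite::write_json(sc, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' Read an intensity stack
#'
#' Reads a multi-page 16-bit TIFF and its JSON sidecar back into a list of
#' \code{\link{intensity_frame}}s; sidecar wavelengths in nm are converted
#' to um and the recorded quantization scale is divided out.
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path (default: \code{path} with .json).
#' @return List with \code{frames} and the parsed \code{meta}.
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("wavelengths_nm", "z_D_um", "pitch_um", "scale")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys))
    stop("sidecar is missing keys: ", paste(missing_keys, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$wavelengths_nm))
    stop("page count (", length(pages), ") does not match sidecar wavelength count (",
         length(meta$wavelengths_nm), ")")
  frames <- lapply(seq_along(pages), function(i) {
    intensity_frame(pages[[i]] / meta$scale,
                    lambda = meta$wavelengths_nm[i] / 1000,
                    z_D = meta$z_D_um, pitch = meta$pitch_um,
                    bit_depth = 16L)
  })
  list(frames = frames, meta = meta)
}

#' Write a refractive-index volume
#'
#' Stores the volume as a multi-page 32-bit float TIFF (one page per z
#' slice) with a JSON sidecar carrying pitch, medium index and annotation.
#' A complex volume is stored as interleaved real/imaginary page pairs.
#'
#' @param vol an \code{\link{ri_volume}}.
#' @param path TIFF path.
#' @param sidecar JSON sidecar path (default: \code{path} with .json).
#' @return Invisibly, the sidecar list.
#' @export
write_volume <- function(vol, path, sidecar = NULL) {
  stopifnot(inherits(vol, "ri_volume"))
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  cplx <- is.complex(vol$n)
  nz <- dim(vol$n)[3]
  pages <- if (cplx) {
    unlist(lapply(seq_len(nz), function(k)
      list(Re(vol$n[, , k]), Im(vol$n[, , k]))), recursive = FALSE)
  } else lapply(seq_len(nz), function(k) vol$n[, , k])
  # TIFF float samples are only well-defined inside [0, 1]: store an affine
  # map of the data and record the offset/range in the sidecar
  lo <- min(vapply(pages, min, 0))
  rng <- max(vapply(pages, max, 0)) - lo
  if (rng <= 0) rng <- 1
  pages <- lapply(pages, function(p) (p - lo) / rng)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sc <- list(pitch_um = vol$pitch, n_m = vol$n_m, complex = cplx,
             shape = dim(vol$n), data_min = lo, data_range = rng,
             annotation = vol$annotation)
  jsonlite::write_json(sc, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' Read a refractive-index volume
#'
#' Inverse of \code{\link{write_volume}} (32-bit float precision).
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path (default: \code{path} with .json).
#' @return An \code{\link{ri_volume}}.
#' @export
read_volume <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(meta$data_min) || is.null(meta$data_range))
    stop("sidecar is missing the data_min/data_range scaling keys")
  pages <- lapply(pages, function(p) p * meta$data_range + meta$data_min)
  shape <- as.integer(meta$shape)
  n <- if (isTRUE(meta$complex)) {
    re <- simplify2array(pages[seq(1, length(pages), by = 2)])
    im <- simplify2array(pages[seq(2, length(pages), by = 2)])
    array(complex(real = re, imaginary = im), shape)
  } else array(simplify2array(pages), shape)
  ann <- meta$annotation
  if (is.null(ann)) ann <- list()
  ri_volume(n, as.numeric(meta$pitch_um), meta$n_m, annotation = ann)
}
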