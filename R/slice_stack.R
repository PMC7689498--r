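#' Slice stacks: ordered axial CT-like slices for one case
#'
#' A `slice_stack` holds an ordered list of 2-D numeric matrices (one per
#' axial slice) together with its pixel kind (`"HU"` for raw Hounsfield
#' units, `"GRAY"` for 8-bit grayscale in \[0, 255\]) and the case label.
#' All slices must share the same height and width. Slices are ordered by
#' ascending table position: index 1 is the lowest (most inferior) slice.
#'
#' @param slices List of numeric matrices, all with identical dimensions.
#' @param pixel_kind Either `"HU"` or `"GRAY"`.
#' @param case_id Character scalar identifying the case.
#' @param label `"normal"` or `"ich"`.
#' @param subtype Haemorrhage subtype: `0` (none), `1` (EDH/SDH),
#'   `2` (SAH) or `3` (IPH/IVH).
#' @return An object of class `slice_stack`.
#' @examples
#' s <- slice_stack(list(matrix(0, 4, 4)), pixel_kind = "GRAY")
#' n_slices(s)
#' @export
slice_stack <- function(slices, pixel_kind = c("GRAY", "HU"),
                        case_id = "case", label = c("normal", "ich"),
                        subtype = 0L) {
  pixel_kind <- match.arg(pixel_kind)
  label <- match.arg(label)
  if (!is.list(slices) || length(slices) < 1) {
    abort("`slices` must be a non-empty list of matrices.", class = "ich_empty_input")
  }
  dims <- vapply(slices, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1])) {
    abort("All slices must share identical height x width.", class = "ich_format_error")
  }
  if (pixel_kind == "GRAY") {
    rng <- range(vapply(slices, range, numeric(2)))
    if (rng[1] < 0 || rng[2] > 255) {
      abort("GRAY slices must lie within [0, 255].", class = "ich_range_error")
    }
  }
  if (label == "normal" && subtype != 0L) {
    abort("A normal case cannot carry a haemorrhage subtype.", class = "ich_label_error")
  }
  structure(
    list(slices = slices, pixel_kind = pixel_kind, case_id = case_id,
         label = label, subtype = as.integer(subtype)),
    class = "slice_stack"
  )
}

#' @rdname slice_stack
#' @param x A `slice_stack`.
#' @export
n_slices <- function(x) length(x$slices)

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<slice_stack '%s'> %d slices of %dx%d [%s], label=%s subtype=%d\n",
              x$case_id, n_slices(x), d[1], d[2], x$pixel_kind, x$label, x$subtype))
  invisible(x)
}

#' Brain-window specification
#'
#' A CT display window defined by its centre (`level`) and `width`, both in
#' Hounsfield units. The default 40/90 brain window maps HU in
#' \[level - width/2, level + width/2\] = \[-5, 85\] linearly onto \[0, 255\].
#'
#' @param level Window level (centre) in HU.
#' @param width Window width in HU; must be positive.
#' @return An object of class `window_spec`.
#' @examples
#' window_spec()          # the 40/90 brain window
#' window_spec(600, 2800) # a bone window
#' @export
window_spec <- function(level = 40, width = 90) {
  if (!is.numeric(width) || width <= 0) {
    abort("Window `width` must be > 0.", class = "ich_window_error")
  }
  structure(list(level = level, width = width), class = "window_spec")
}

#' Convert an HU-valued stack to brain-windowed grayscale
#'
#' Applies the linear window mapping
#' `g = round(255 * clamp((v - (level - width/2)) / width, 0, 1))`
#' (half-up rounding) to every pixel of every slice. Values at or below the
#' window floor map to 0, values at or above the ceiling to 255, and a value
#' equal to the window level maps to mid-grey (128 for the 40/90 window).
#'
#' @param stack A `slice_stack` with `pixel_kind == "HU"`.
#' @param window A [window_spec()]; defaults to the 40/90 brain window.
#' @return The same stack with `pixel_kind == "GRAY"` and 8-bit values.
#' @examples
#' hu <- slice_stack(list(matrix(c(-50, 0, 40, 100), 2, 2)), pixel_kind = "HU")
#' apply_window(hu)$slices[[1]]
#' @export
apply_window <- function(stack, window = window_spec()) {
  stopifnot(inherits(stack, "slice_stack"), inherits(window, "window_spec"))
  if (stack$pixel_kind != "HU") {
    abort("apply_window() needs an HU-valued stack.", class = "ich_precondition_error")
  }
  lo <- window$level - window$width / 2
  stack$slices <- lapply(stack$slices, function(m) {
    round_half_up(255 * clamp((m - lo) / window$width, 0, 1))
  })
  stack$pixel_kind <- "GRAY"
  stack
}

#' Read a slice stack from disk
#'
#' Reads one case from a directory of single-slice image files (PNG or TIFF,
#' one file per slice, ordered by their sortable numeric filename suffix) or
#' from a single plain-text stack file written by [write_stack_txt()].
#' Slice order as stored on disk is preserved; the package convention is
#' ascending table position (lowest slice first).
#'
#' @param path Directory of slice images, or a text stack file.
#' @param format `"png_dir"`, `"tiff_dir"` or `"txt"`.
#' @param ... Passed to [slice_stack()] (`case_id`, `label`, `subtype`,
#'   `pixel_kind`).
#' @return A `slice_stack`.
#' @export
read_stack <- function(path, format = c("png_dir", "tiff_dir", "txt"), ...) {
  format <- match.arg(format)
  if (format == "txt") {
    return(read_stack_txt(path, ...))
  }
  ext <- if (format == "png_dir") "\\.png$" else "\\.tiff?$"
  files <- sort(list.files(path, pattern = ext, full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0) {
    abort(sprintf("No slice images found under '%s'.", path), class = "ich_empty_input")
  }
  reader <- if (format == "png_dir") png::readPNG else tiff::readTIFF
  slices <- lapply(files, function(f) {
    m <- reader(f)
    if (length(dim(m)) == 3) m <- m[, , 1]  # grayscale written as first channel
    round_half_up(m * 255)
  })
  slice_stack(slices, pixel_kind = "GRAY", ...)
}

#' Write one 2-D image to disk
#'
#' Writes an 8-bit grayscale image losslessly as PNG or TIFF, so that
#' reading it back reproduces the pixel grid bit-exactly.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#' @param path Output file path; the extension selects PNG vs TIFF.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  if (any(image < 0) || any(image > 255)) {
    abort("Image values must lie within [0, 255].", class = "ich_range_error")
  }
  scaled <- round_half_up(image) / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(scaled, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L, compression = "none")
  } else {
    abort("Unsupported image extension (use .png or .tif/.tiff).",
          class = "ich_format_error")
  }
  invisible(path)
}

#' Plain-text slice-stack round trip
#'
#' A minimal text format for numeric 3-D stacks: a header line
#' `n_slices n_rows n_cols pixel_kind`, then one line of row-major values per
#' slice. Useful for HU-valued fixtures where 8-bit image formats would clip.
#'
#' @param stack A `slice_stack`.
#' @param path Output file.
#' @return `path` invisibly (`write_stack_txt`); a `slice_stack`
#'   (`read_stack_txt`).
#' @export
write_stack_txt <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- dim(stack$slices[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d %s", n_slices(stack), d[1], d[2], stack$pixel_kind), con)
  for (m in stack$slices) {
    writeLines(paste(format(t(m), digits = 17, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_stack_txt
#' @param ... Passed to [slice_stack()].
#' @export
read_stack_txt <- function(path, ...) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  ns <- as.integer(hdr[1]); nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
  slices <- lapply(seq_len(ns), function(i) {
    matrix(as.numeric(strsplit(lines[i + 1], " ")[[1]]), nr, nc, byrow = TRUE)
  })
  slice_stack(slices, pixel_kind = hdr[4], ...)
}
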