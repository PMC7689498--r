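#' Square images with case metadata
#'
#' A `square_image` is one S x S pixel grid produced by subdivision summation
#' and square expansion, tagged with the subdivision it came from and the
#' case label, so downstream steps (flip augmentation, normal-average
#' subtraction, input-vector conversion) can carry labels along.
#'
#' @param pixels Numeric S x S matrix, values in \[0, 255\].
#' @param subdivision Integer 1-10, or `"WHOLE"` for whole-head summation.
#' @param case_id,label,subtype Case metadata (see [slice_stack()]).
#' @return An object of class `square_image`.
#' @export
square_image <- function(pixels, subdivision = "WHOLE", case_id = "case",
                         label = "normal", subtype = 0L) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  structure(
    list(pixels = pixels, subdivision = subdivision, case_id = case_id,
         label = label, subtype = as.integer(subtype)),
    class = "square_image"
  )
}

as_pixels <- function(x) if (inherits(x, "square_image")) x$pixels else x

#' Locate the intracranial extent of a stack
#'
#' Finds the contiguous range of slices that contain cranial content, defined
#' as slices whose count of pixels brighter than `floor` exceeds
#' `min_pixels`. On brain-windowed images the skull ring saturates to 255 and
#' brain tissue sits near mid-grey, so a low fixed floor separates content
#' from air. If several contiguous runs qualify the longest is returned.
#'
#' @param stack A GRAY `slice_stack`.
#' @param floor Grayscale content threshold (default 10 of 255).
#' @param min_pixels Minimum number of above-floor pixels for a slice to
#'   count as intracranial content.
#' @return Integer vector `c(first, last)` of 1-based slice indices.
#' @export
locate_intracranial_extent <- function(stack, floor = 10, min_pixels = 50) {
  stopifnot(inherits(stack, "slice_stack"))
  counts <- vapply(stack$slices, function(m) sum(m > floor), numeric(1))
  ok <- counts > min_pixels
  if (!any(ok)) {
    abort("No slice contains cranial content above the floor.",
          class = "ich_no_content")
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  best <- keep[which.max(runs$lengths[keep])]
  c(first = starts[best], last = ends[best])
}

#' Assign intracranial slices to height-decile subdivisions
#'
#' Partitions the slices between `first` and `last` (inclusive) into `n`
#' bands of relative intracranial height, band 1 being the lowest 0-10%.
#' Slice `i` maps to band `floor(n * (i - first) / (last - first + 1)) + 1`,
#' which guarantees every slice belongs to exactly one band and band sizes
#' differ by at most one. With the typical 30-40 intracranial slices each
#' decile holds 3-4 slices.
#'
#' @param first,last 1-based slice range from [locate_intracranial_extent()].
#' @param n Number of bands (default 10).
#' @return A tibble with columns `slice` and `band`.
#' @export
assign_subdivisions <- function(first, last, n = 10) {
  stopifnot(first <= last, n >= 1)
  idx <- first:last
  band <- floor(n * (idx - first) / (last - first + 1)) + 1
  tibble(slice = idx, band = as.integer(band))
}

#' Sum slices of one subdivision into a single image
#'
#' Pixelwise sum of the selected GRAY slices, linearly rescaled so the
#' maximum maps to 255 (an all-zero sum stays zero). The rescale removes the
#' dependence on how many slices a band happens to hold, so summing k
#' identical slices reproduces the single slice.
#'
#' @param stack A GRAY `slice_stack`.
#' @param slice_indices 1-based indices of the slices to sum.
#' @return A numeric matrix in \[0, 255\].
#' @export
sum_subdivision <- function(stack, slice_indices) {
  stopifnot(inherits(stack, "slice_stack"))
  if (length(slice_indices) == 0) {
    abort("Empty slice index set.", class = "ich_precondition_error")
  }
  if (any(slice_indices < 1) || any(slice_indices > n_slices(stack))) {
    abort("Slice indices out of range.", class = "ich_precondition_error")
  }
  total <- Reduce(`+`, stack$slices[slice_indices])
  m <- max(total)
  if (m > 0) total <- total * (255 / m)
  total
}

#' Sum the whole intracranial extent into one image
#'
#' Equivalent to [sum_subdivision()] over the full intracranial slice range,
#' used for whole-head detection irrespective of lesion height.
#'
#' @inheritParams locate_intracranial_extent
#' @return A numeric matrix in \[0, 255\].
#' @export
sum_whole_head <- function(stack, floor = 10, min_pixels = 50) {
  ext <- locate_intracranial_extent(stack, floor = floor, min_pixels = min_pixels)
  sum_subdivision(stack, ext[1]:ext[2])
}

#' Expand image content to fill a square
#'
#' Crops the tight bounding box of above-threshold content and resizes it
#' anisotropically (aspect ratio deliberately not preserved) to `side` x
#' `side` pixels with bilinear interpolation. Stretching every head to the
#' same square removes inter-case differences in head size and tilt without
#' any registration step, and makes the output invariant to where the head
#' sits in the source frame.
#'
#' @param image Numeric matrix (or `square_image`).
#' @param side Output side length S (default 256).
#' @param threshold Content threshold for the bounding box (default 10).
#' @return A numeric `side` x `side` matrix.
#' @export
expand_to_square <- function(image, side = 256, threshold = 10) {
  img <- as_pixels(image)
  keep <- img > threshold
  if (!any(keep)) {
    abort("Image has no content above the threshold.", class = "ich_no_content")
  }
  rows <- range(which(apply(keep, 1, any)))
  cols <- range(which(apply(keep, 2, any)))
  cropped <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  clamp(resize_bilinear(cropped, side), 0, 255)
}

#' Mirror a square image left-right
#'
#' Horizontal flip used to double the training set; flipping twice is the
#' identity, and labels are carried unchanged.
#'
#' @param image A `square_image` or plain matrix.
#' @return Same type as the input, mirrored.
#' @export
flip_horizontal <- function(image) {
  if (inherits(image, "square_image")) {
    image$pixels <- image$pixels[, ncol(image$pixels):1, drop = FALSE]
    image$case_id <- paste0(image$case_id, "_flip")
    image
  } else {
    image[, ncol(image):1, drop = FALSE]
  }
}

#' Average square image of normal cases
#'
#' Pixelwise arithmetic mean of the normal-case square images of one
#' subdivision, computed from the training set only and then frozen for use
#' on validation cases.
#'
#' @param normals Non-empty list of `square_image`s (or matrices) sharing one
#'   side length and subdivision.
#' @return A numeric matrix.
#' @export
average_normal_image <- function(normals) {
  if (length(normals) == 0) {
    abort("Need at least one normal image.", class = "ich_precondition_error")
  }
  subs <- unique(vapply(normals, function(x) {
    if (inherits(x, "square_image")) as.character(x$subdivision) else NA_character_
  }, character(1)))
  subs <- subs[!is.na(subs)]
  if (length(subs) > 1) {
    abort("Normal images come from different subdivisions.", class = "ich_mismatch_error")
  }
  mats <- lapply(normals, as_pixels)
  d <- unique(vapply(mats, nrow, integer(1)))
  if (length(d) > 1) {
    abort("Normal images have mixed sizes.", class = "ich_mismatch_error")
  }
  Reduce(`+`, mats) / length(mats)
}

#' Subtract the normal-average image
#'
#' Pixelwise `image - avg` with negatives clamped to zero. Because the skull
#' ring and gross brain anatomy are shared across cases, the residual keeps
#' mostly the hyperdense lesion while suppressing everything a normal head
#' also shows.
#'
#' @param image A `square_image` or matrix.
#' @param avg Matrix from [average_normal_image()], same size.
#' @return Same type as `image`, residual pixels in \[0, 255\].
#' @export
subtract_normal_average <- function(image, avg) {
  px <- as_pixels(image)
  avg <- as_pixels(avg)
  if (!all(dim(px) == dim(avg))) {
    abort("Image and average sizes differ.", class = "ich_mismatch_error")
  }
  out <- pmax(px - avg, 0)
  if (inherits(image, "square_image")) {
    image$pixels <- out
    image
  } else {
    out
  }
}

#' Convert a square image to a network input vector
#'
#' Downscales to `resolution` x `resolution` pixels by exact area averaging
#' (box filter — deterministic and alias-resistant for the 4-25x reductions
#' used here), flattens row-major, and divides by 255 so every input node
#' receives a value in \[0, 1\]. The attached `target` is the one-hot vector
#' the network is trained against: `c(1, 0)` positive / `c(0, 1)` negative
#' for detection, or `c(1,0,0)`, `c(0,1,0)`, `c(0,0,1)` for subtypes 1-3.
#'
#' @param image A `square_image` or matrix with values in \[0, 255\].
#' @param resolution Target side R; the network then has R^2 input nodes.
#' @param target One-hot numeric vector of length 2 or 3.
#' @param allow_upscale Permit R larger than the source side (off by default).
#' @return A list with `values` (length R^2, in \[0,1\]), `resolution` and
#'   `target`, of class `input_vector`.
#' @export
to_input_vector <- function(image, resolution, target, allow_upscale = FALSE) {
  px <- as_pixels(image)
  if (resolution > nrow(px) && !allow_upscale) {
    abort("Requested resolution exceeds the source image.",
          class = "ich_resolution_error")
  }
  stopifnot(all(target %in% c(0, 1)), sum(target) == 1, length(target) %in% 2:3)
  small <- resize_area(px, resolution)
  values <- as.vector(t(small)) / 255
  structure(
    list(values = clamp(values, 0, 1), resolution = as.integer(resolution),
         target = as.numeric(target)),
    class = "input_vector"
  )
}

#' One-hot target encodings
#'
#' @param label `"ich"` or `"normal"` for the 2-node detection head.
#' @param subtype 1, 2 or 3 for the 3-node classification head.
#' @return Numeric one-hot vector.
#' @export
detection_target <- function(label) {
  if (label == "ich") c(1, 0) else c(0, 1)
}

#' @rdname detection_target
#' @export
subtype_target <- function(subtype) {
  stopifnot(subtype %in% 1:3)
  as.numeric(seq_len(3) == subtype)
}
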