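#' Synthetic head-phantom configuration
#'
#' Parameters of the phantom generator that stands in for clinical head CT:
#' each case is a stack of axial HU-valued slices showing a bright
#' elliptical skull ring (shrinking toward the cranial vault), a mid-grey
#' brain interior with Gaussian texture, air outside, and — for ICH cases —
#' a hyperdense lesion whose geometry depends on the subtype. Per-case
#' random scale, tilt and offset jitter emulates inter-patient variation in
#' head size and positioning, which is exactly what the square-expansion
#' step has to undo.
#'
#' Default tissue values are clinically plausible for the 40/90 brain
#' window: brain ~35 HU, acute blood 60-80 HU (hyperdense but within the
#' window), skull ~900 HU (saturates to white), air -1000 HU (black).
#'
#' @param image_size Slice side length in pixels.
#' @param n_slices Slices per stack (5-mm axial convention, ~36 per head).
#' @param skull_hu,brain_hu,brain_sd,air_hu Tissue attenuation values (HU).
#' @param lesion_hu Range the lesion HU is drawn from.
#' @param lesion_frac Lesion characteristic size as a fraction of the brain
#'   semi-axis (range; used as blob radius / crescent depth / streak width
#'   scale depending on subtype).
#' @param lesion_band Relative intracranial height interval the lesion
#'   occupies (default centred on the 41-50% decile).
#' @param head_ax,head_ay Base skull outer semi-axes as fractions of
#'   `image_size`.
#' @param ring_frac Skull ring thickness as a fraction of `image_size`.
#' @param scale_range,tilt_range,offset_frac Per-case jitter: global scale,
#'   tilt angle in degrees, and centre offset as a fraction of `image_size`.
#' @param margin_range Range of empty (air-only) slices below and above the
#'   intracranial extent.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128, n_slices = 36,
                           skull_hu = 900, brain_hu = 35, brain_sd = 3,
                           air_hu = -1000,
                           lesion_hu = c(60, 80),
                           lesion_frac = c(0.18, 0.30),
                           lesion_band = c(0.35, 0.55),
                           head_ax = 0.34, head_ay = 0.42,
                           ring_frac = 0.045,
                           scale_range = c(0.85, 1.0),
                           tilt_range = c(-8, 8),
                           offset_frac = 0.05,
                           margin_range = c(2, 4)) {
  stopifnot(image_size >= 32, n_slices >= 4,
            lesion_hu[1] > brain_hu,
            lesion_band[1] >= 0, lesion_band[2] <= 1,
            lesion_band[1] < lesion_band[2])
  structure(as.list(environment()), class = "phantom_config")
}

# Rotated-ellipse squared radius: 1 on the ellipse boundary.
ellipse_r2 <- function(X, Y, cx, cy, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  xr <- (X - cx) * ct + (Y - cy) * st
  yr <- -(X - cx) * st + (Y - cy) * ct
  (xr / a)^2 + (yr / b)^2
}

#' Generate one labelled phantom case
#'
#' Draws per-case jitter and lesion geometry from the current RNG state and
#' renders the full HU-valued slice stack together with ground truth: the
#' true intracranial slice extent and a per-slice lesion mask.
#'
#' Subtype archetypes (deliberately coarse — the goal is pipeline exercise,
#' not radiological realism): type 1 (EDH/SDH) is a crescent hugging the
#' inner skull margin over a random angular sector; type 2 (SAH) is a set of
#' thin curvilinear streaks along the midline and a sulcal-track arc;
#' type 3 (IPH/IVH) is a compact elliptical blob in the brain interior.
#'
#' @param config A [phantom_config()].
#' @param subtype 0 for a normal case, otherwise 1, 2 or 3.
#' @param case_id Case identifier.
#' @return A list of class `phantom_case`: `stack` (HU `slice_stack`),
#'   `extent` (true first/last intracranial slice), `masks` (per-slice
#'   lesion masks, `NULL` where no lesion), `lesion_hu`.
#' @export
generate_phantom_case <- function(config, subtype = 0L, case_id = "case") {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  ns <- config$n_slices
  if (subtype > 0) {
    if (config$lesion_band[2] <= 0 || config$lesion_band[1] >= 1) {
      abort("Lesion band lies outside the intracranial extent.",
            class = "ich_config_error")
    }
  }

  # per-case jitter
  scale <- runif(1, config$scale_range[1], config$scale_range[2])
  theta <- runif(1, config$tilt_range[1], config$tilt_range[2]) * pi / 180
  cx <- n / 2 + runif(1, -1, 1) * config$offset_frac * n
  cy <- n / 2 + runif(1, -1, 1) * config$offset_frac * n
  lo_margin <- sample(config$margin_range[1]:config$margin_range[2], 1)
  hi_margin <- sample(config$margin_range[1]:config$margin_range[2], 1)
  s0 <- lo_margin + 1L
  s1 <- ns - hi_margin
  stopifnot(s1 - s0 >= 3)

  a_out <- config$head_ax * n * scale
  b_out <- config$head_ay * n * scale
  ring <- config$ring_frac * n

  # lesion draws (made even for normals so jitter streams stay aligned)
  lesion_hu <- runif(1, config$lesion_hu[1], config$lesion_hu[2])
  lesion_size <- runif(1, config$lesion_frac[1], config$lesion_frac[2])
  lesion_angle <- runif(1, 0, 2 * pi)
  lesion_side <- sample(c(-1, 1), 1)
  blob_u <- runif(2, -0.35, 0.35)

  grid <- seq_len(n) - 0.5
  X <- matrix(rep(grid, each = n), n, n)    # column coordinate
  Y <- matrix(rep(grid, times = n), n, n)   # row coordinate

  slices <- vector("list", ns)
  masks <- vector("list", ns)
  for (i in seq_len(ns)) {
    if (i < s0 || i > s1) {
      slices[[i]] <- matrix(config$air_hu, n, n)
      next
    }
    h <- (i - s0) / (s1 - s0)                 # relative intracranial height
    zs <- sqrt(max(0.2, 1 - 0.72 * h^2))      # vault shrink toward the top
    ao <- a_out * zs; bo <- b_out * zs
    ai <- ao - ring; bi <- bo - ring
    r2_out <- ellipse_r2(X, Y, cx, cy, ao, bo, theta)
    r2_in <- ellipse_r2(X, Y, cx, cy, ai, bi, theta)
    img <- matrix(config$air_hu, n, n)
    img[r2_out <= 1] <- config$skull_hu
    inside <- r2_in <= 1
    img[inside] <- config$brain_hu +
      stats::rnorm(sum(inside), 0, config$brain_sd)

    if (subtype > 0 && h >= config$lesion_band[1] && h <= config$lesion_band[2]) {
      mask <- lesion_mask(subtype, X, Y, cx, cy, ai, bi, theta,
                          lesion_size, lesion_angle, lesion_side, blob_u)
      mask <- mask & inside
      img[mask] <- lesion_hu
      masks[[i]] <- mask
    }
    slices[[i]] <- img
  }

  label <- if (subtype > 0) "ich" else "normal"
  structure(
    list(stack = slice_stack(slices, pixel_kind = "HU", case_id = case_id,
                             label = label, subtype = subtype),
         extent = c(first = s0, last = s1),
         masks = masks, lesion_hu = if (subtype > 0) lesion_hu else NA_real_),
    class = "phantom_case"
  )
}

# Subtype-specific lesion geometry in the inner-ellipse coordinate frame.
lesion_mask <- function(subtype, X, Y, cx, cy, ai, bi, theta,
                        size, angle, side, blob_u) {
  r2 <- ellipse_r2(X, Y, cx, cy, ai, bi, theta)
  ct <- cos(theta); st <- sin(theta)
  xr <- ((X - cx) * ct + (Y - cy) * st) / ai
  yr <- (-(X - cx) * st + (Y - cy) * ct) / bi
  if (subtype == 1) {
    # crescent between (1 - size) and the inner skull margin, one sector
    phi <- atan2(yr, xr * side)
    r2 >= (1 - size)^2 & r2 <= 1 & abs(phi) < 1.0
  } else if (subtype == 2) {
    # thin midline streak plus a sulcal-track annulus arc
    w <- 0.06 + 0.08 * size
    midline <- abs(xr) < w & r2 <= 0.95
    arc <- r2 >= (0.55 - w)^2 & r2 <= (0.55 + w)^2 &
      atan2(yr, xr) > angle - 1 & atan2(yr, xr) < angle + 1
    midline | arc
  } else {
    # compact blob in the interior
    bx <- blob_u[1]; by <- blob_u[2]
    ((xr - bx) / size)^2 + ((yr - by) / size)^2 <= 1
  }
}

#' Generate a train/validation phantom dataset manifest
#'
#' Builds the case roster for a two-split phantom study. Every case gets its
#' own sub-seed derived deterministically from `seed`, so cases can be
#' regenerated individually (and lazily — a full stack is only rendered
#' when asked for) without holding the whole study in memory. The default
#' composition mirrors a 250-case study: 166 training cases (66 normal,
#' 31/29/40 of subtypes 1-3) and 84 validation cases (34 normal, 13/16/21).
#'
#' @param train_counts,val_counts Named integer vectors with elements
#'   `normal`, `t1`, `t2`, `t3`.
#' @param config A [phantom_config()].
#' @param seed Master seed for the whole dataset.
#' @param materialize If `TRUE`, adds a `case` list-column holding the
#'   generated `phantom_case` objects (only sensible for small rosters).
#' @return A tibble manifest with columns `case_id`, `split`, `label`,
#'   `subtype`, `case_seed` (and `case` when materialised).
#' @export
generate_phantom_dataset <- function(train_counts = c(normal = 66, t1 = 31, t2 = 29, t3 = 40),
                                     val_counts = c(normal = 34, t1 = 13, t2 = 16, t3 = 21),
                                     config = phantom_config(),
                                     seed = 1, materialize = FALSE) {
  stopifnot(all(train_counts >= 0), all(val_counts >= 0))
  roster <- function(counts, split) {
    subtype <- rep(c(0L, 1L, 2L, 3L),
                   times = counts[c("normal", "t1", "t2", "t3")])
    tibble(split = split, subtype = subtype,
           label = c("normal", "ich")[(subtype > 0) + 1L])
  }
  manifest <- dplyr::bind_rows(roster(train_counts, "training"),
                               roster(val_counts, "validation"))
  manifest$case_id <- sprintf("%s_%03d", manifest$split,
                              stats::ave(seq_len(nrow(manifest)),
                                         manifest$split, FUN = seq_along))
  check_seed(seed)
  manifest$case_seed <- sample.int(.Machine$integer.max - 1L, nrow(manifest))
  manifest <- manifest[, c("case_id", "split", "label", "subtype", "case_seed")]
  if (materialize) {
    manifest$case <- purrr::map2(manifest$case_seed, seq_len(nrow(manifest)),
                                 function(s, i) {
                                   set.seed(s)
                                   generate_phantom_case(config, manifest$subtype[i],
                                                         manifest$case_id[i])
                                 })
  }
  attr(manifest, "config") <- config
  attr(manifest, "seed") <- seed
  manifest
}

#' Regenerate one case listed in a manifest
#'
#' @param manifest Result of [generate_phantom_dataset()].
#' @param i Row index.
#' @return The `phantom_case` for that row, bit-identical on every call.
#' @export
manifest_case <- function(manifest, i) {
  config <- attr(manifest, "config")
  set.seed(manifest$case_seed[i])
  generate_phantom_case(config, manifest$subtype[i], manifest$case_id[i])
}

#' Double a training set by horizontal flipping
#'
#' Appends a left-right mirrored copy of every image, carrying labels
#' along, so a 166-case training set becomes 332 cases with the doubled
#' per-class composition.
#'
#' @param images List of `square_image`s.
#' @return List of length `2 * length(images)` (originals then flips).
#' @export
augment_flip <- function(images) {
  c(images, lapply(images, flip_horizontal))
}
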