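## Synthetic phantom cohort: axial CT-like slices with one bright elliptical
## vessel of known geometry, a torso outline and a spine-like blob as
## distractors, per-slice pixel-spacing metadata, and exact ground truth.

#' Ellipse parameters
#'
#' Ellipse in pixel coordinates (see package conventions: 0-based, x = column,
#' y = row, pixel-centre sampling). Semi-axes are ordered `a >= b`; `theta` is
#' the orientation of the major axis, counter-clockwise from +x, in degrees,
#' normalised to `[0, 180)`.
#'
#' @param x0,y0 centre, pixels.
#' @param a,b semi-axes, pixels; reordered so `a >= b`.
#' @param theta orientation of the axis passed as `a`, degrees.
#' @return An object of class `ellipse_params`.
#' @export
ellipse_params <- function(x0, y0, a, b, theta = 0) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("ellipse semi-axes must be positive, got a=", a, ", b=", b)
  if (a < b) {          # keep a >= b; the major axis direction shifts by 90
    tmp <- a; a <- b; b <- tmp
    theta <- theta + 90
  }
  theta <- theta %% 180
  structure(list(x0 = x0, y0 = y0, a = a, b = b, theta = theta),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("ellipse: centre (%.2f, %.2f), semi-axes a=%.2f b=%.2f, theta=%.1f deg\n",
              x$x0, x$y0, x$a, x$b, x$theta))
  invisible(x)
}

#' Single axial slice with metadata
#'
#' @param pixels numeric matrix (grayscale in `[0, 1]`), indexed `[row, col]`.
#' @param subject_id character scalar.
#' @param slice_index integer ordinal, unique within subject.
#' @param pixel_spacing mm per pixel, length-2 `(row, col)`; a scalar is
#'   recycled to both axes.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, subject_id, slice_index, pixel_spacing) {
  stopifnot(is.matrix(pixels))
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing components must be positive")
  structure(list(pixels = pixels,
                 subject_id = as.character(subject_id),
                 slice_index = as.integer(slice_index),
                 pixel_spacing = as.numeric(pixel_spacing),
                 original_size = dim(pixels)),
            class = "ct_slice")
}

#' Phantom cohort specification
#'
#' Defines the study conditions a generated cohort emulates: the number of
#' subjects, 5-25 axial slices per subject, pixel spacings typical of
#' abdominal CT, and vessel minor diameters spanning the hypovolemic-to-normal
#' aortic range (roughly 12-30 mm).
#'
#' @param n_subjects number of subjects.
#' @param slices_per_subject_range integer interval `[low, high]`.
#' @param image_size side of the square slice, pixels (`>= 64`).
#' @param pixel_spacing_range mm/pixel interval.
#' @param vessel_minor_range_mm vessel minor-diameter interval, mm.
#' @param aspect_ratio_range major/minor axis ratio interval (`>= 1`).
#' @param orientation_range degrees, subinterval of `[0, 180)`.
#' @param vessel_intensity,background_intensity,spine_intensity,body_intensity
#'   grayscale levels in `[0, 1]`.
#' @param noise_sd additive Gaussian pixel-noise standard deviation.
#' @param distractor_fraction fraction of slices receiving an extra blob
#'   intensity-matched to the vessel (exercises the rejection rule).
#' @param margin_px minimum distance from the vessel ellipse to the image
#'   border, pixels.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 10,
                         slices_per_subject_range = c(5L, 25L),
                         image_size = 512L,
                         pixel_spacing_range = c(0.6, 0.9),
                         vessel_minor_range_mm = c(12, 30),
                         aspect_ratio_range = c(1.0, 1.6),
                         orientation_range = c(0, 180),
                         vessel_intensity = 0.85,
                         background_intensity = 0.15,
                         spine_intensity = 0.55,
                         body_intensity = 0.35,
                         noise_sd = 0.05,
                         distractor_fraction = 0.1,
                         margin_px = 5,
                         seed = 1L) {
  chk_interval <- function(v, name) {
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2])
      stop("invalid ", name, ": interval bounds must satisfy low <= high")
    v
  }
  chk_interval(slices_per_subject_range, "slices_per_subject_range")
  chk_interval(pixel_spacing_range, "pixel_spacing_range")
  chk_interval(vessel_minor_range_mm, "vessel_minor_range_mm")
  chk_interval(aspect_ratio_range, "aspect_ratio_range")
  chk_interval(orientation_range, "orientation_range")
  if (image_size < 64) stop("image_size must be >= 64, got ", image_size)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (slices_per_subject_range[1] < 1)
    stop("slices_per_subject_range lower bound must be >= 1")
  if (aspect_ratio_range[1] < 1)
    stop("aspect_ratio_range lower bound must be >= 1 (major/minor)")
  if (distractor_fraction < 0 || distractor_fraction > 1)
    stop("distractor_fraction must be in [0, 1]")
  ## feasibility: largest semi-major axis must fit inside the margin box
  a_max <- (vessel_minor_range_mm[2] / 2 / pixel_spacing_range[1]) *
    aspect_ratio_range[2]
  if (2 * (a_max + margin_px) >= image_size)
    stop("infeasible geometry: vessel_minor_range_mm upper bound ",
         vessel_minor_range_mm[2], " mm at pixel spacing ",
         pixel_spacing_range[1], " mm/px with aspect ratio ",
         aspect_ratio_range[2], " needs a semi-major axis of ",
         round(a_max, 1), " px, which cannot fit in a ", image_size,
         "-px image with a ", margin_px, "-px margin")
  structure(list(n_subjects = as.integer(n_subjects),
                 slices_per_subject_range = as.integer(slices_per_subject_range),
                 image_size = as.integer(image_size),
                 pixel_spacing_range = pixel_spacing_range,
                 vessel_minor_range_mm = vessel_minor_range_mm,
                 aspect_ratio_range = aspect_ratio_range,
                 orientation_range = orientation_range,
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 spine_intensity = spine_intensity,
                 body_intensity = body_intensity,
                 noise_sd = noise_sd,
                 distractor_fraction = distractor_fraction,
                 margin_px = margin_px,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Rasterize an ellipse to a binary mask
#'
#' Marks every pixel whose centre lies inside or on the ellipse:
#' `((x-x0)cos(t) + (y-y0)sin(t))^2/a^2 + (-(x-x0)sin(t) + (y-y0)cos(t))^2/b^2 <= 1`.
#'
#' @param params an [ellipse_params] object.
#' @param size image side in pixels (scalar) or `c(rows, cols)`.
#' @return integer 0/1 matrix of dimension `size`.
#' @export
rasterize_ellipse <- function(params, size) {
  if (length(size) == 1) size <- c(size, size)
  if (params$b < 0.5)
    stop("semi-minor axis ", params$b,
         " px is below the half-pixel minimum for rasterization")
  t <- params$theta * pi / 180
  x <- matrix(0:(size[2] - 1), size[1], size[2], byrow = TRUE) - params$x0
  y <- matrix(0:(size[1] - 1), size[1], size[2]) - params$y0
  u <- x * cos(t) + y * sin(t)
  v <- -x * sin(t) + y * cos(t)
  mask <- (u / params$a)^2 + (v / params$b)^2 <= 1
  storage.mode(mask) <- "integer"
  mask
}

## paints `value` over the ellipse interior of an image matrix
paint_ellipse <- function(img, params, value) {
  m <- rasterize_ellipse(params, dim(img)) == 1L
  img[m] <- value
  img
}

#' Generate a phantom cohort
#'
#' Draws, per subject, a slice count uniform in `slices_per_subject_range` and
#' a pixel spacing uniform in `pixel_spacing_range` (spacing is a scanner
#' property, so it is held constant within a subject), then per slice a vessel
#' ellipse with minor diameter uniform in `vessel_minor_range_mm`, aspect
#' ratio and orientation uniform in their ranges, placed uniformly inside the
#' margin box. A torso outline and a spine-like blob are painted as
#' distractors; with probability `distractor_fraction` an extra blob
#' intensity-matched to the vessel is added, disjoint from it. Gaussian pixel
#' noise is added last and intensities clamped to `[0, 1]`.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_cohort`: a list of phantom slices, each
#'   with elements `slice` ([ct_slice]), `truth_mask` (0/1 matrix),
#'   `truth_ellipse` ([ellipse_params]), `truth_aod_mm`, and
#'   `has_distractor`; the spec is attached as an attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    slices <- list()
    sz <- spec$image_size
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%03d", s)
      rng_sl <- spec$slices_per_subject_range
      n_sl <- rng_sl[1] + sample.int(rng_sl[2] - rng_sl[1] + 1L, 1L) - 1L
      spacing <- runif(1, spec$pixel_spacing_range[1], spec$pixel_spacing_range[2])
      for (k in seq_len(n_sl)) {
        slices[[length(slices) + 1]] <-
          phantom_slice_draw(spec, sid, k, spacing, sz)
      }
    }
    structure(slices, class = "phantom_cohort", spec = spec)
  })
}

## one slice; consumes RNG draws in a fixed order for determinism
phantom_slice_draw <- function(spec, sid, k, spacing, sz) {
  minor_mm <- runif(1, spec$vessel_minor_range_mm[1], spec$vessel_minor_range_mm[2])
  b <- minor_mm / 2 / spacing
  a <- b * runif(1, spec$aspect_ratio_range[1], spec$aspect_ratio_range[2])
  theta <- runif(1, spec$orientation_range[1], spec$orientation_range[2])
  lo <- spec$margin_px + a
  hi <- sz - 1 - spec$margin_px - a
  x0 <- runif(1, lo, hi)
  y0 <- runif(1, lo, hi)
  vessel <- ellipse_params(x0, y0, a, b, theta)
  truth_mask <- rasterize_ellipse(vessel, sz)

  img <- matrix(spec$background_intensity, sz, sz)
  body <- ellipse_params(sz / 2, sz / 2, sz * 0.46, sz * 0.40, 0)
  img <- paint_ellipse(img, body, spec$body_intensity)
  spine <- ellipse_params(sz / 2, sz * 0.78, sz * 0.07, sz * 0.05, 90)
  if (!any(rasterize_ellipse(spine, sz) & truth_mask))
    img <- paint_ellipse(img, spine, spec$spine_intensity)

  has_distractor <- runif(1) < spec$distractor_fraction
  if (has_distractor) {
    dpar <- NULL
    for (try in 1:25) {           # rejection-sample a disjoint location
      da <- runif(1, 0.6, 1.0) * a
      db <- runif(1, 0.6, 1.0) * b
      dx <- runif(1, spec$margin_px + da, sz - 1 - spec$margin_px - da)
      dy <- runif(1, spec$margin_px + da, sz - 1 - spec$margin_px - da)
      if (sqrt((dx - x0)^2 + (dy - y0)^2) > a + da + 4) {
        dpar <- ellipse_params(dx, dy, da, db, runif(1, 0, 180))
        break
      }
    }
    if (is.null(dpar)) has_distractor <- FALSE
    else img <- paint_ellipse(img, dpar, spec$vessel_intensity)
  }
  img <- paint_ellipse(img, vessel, spec$vessel_intensity)
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
  ## quantize to 16-bit levels so disk round trips are bit-exact
  img <- round(pmin(pmax(img, 0), 1) * 65535) / 65535

  list(slice = ct_slice(img, sid, k, spacing),
       truth_mask = truth_mask,
       truth_ellipse = vessel,
       truth_aod_mm = 2 * b * spacing,
       has_distractor = has_distractor)
}

#' Cohort metadata table
#'
#' @param cohort a `phantom_cohort`.
#' @return data.frame with one row per slice: subject, slice index, spacing,
#'   truth ellipse parameters and truth diameter.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, function(ph) {
    e <- ph$truth_ellipse
    data.frame(subject_id = ph$slice$subject_id,
               slice_index = ph$slice$slice_index,
               pixel_spacing_mm = ph$slice$pixel_spacing[1],
               x0 = e$x0, y0 = e$y0, a = e$a, b = e$b, theta = e$theta,
               truth_aod_mm = ph$truth_aod_mm,
               has_distractor = ph$has_distractor,
               stringsAsFactors = FALSE)
  }))
}

#' Write a phantom cohort to disk
#'
#' Slices are written as 16-bit grayscale PNG, truth masks as 8-bit PNG
#' (values 0/255), plus a `metadata.csv` table with per-slice pixel spacing
#' and truth parameters.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return the metadata data.frame, invisibly (with file name columns added).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort_metadata(cohort)
  meta$image_file <- sprintf("%s_slice%03d.png", meta$subject_id, meta$slice_index)
  meta$mask_file <- sprintf("%s_slice%03d_mask.png", meta$subject_id, meta$slice_index)
  for (i in seq_along(cohort)) {
    write_png16(cohort[[i]]$slice$pixels, file.path(dir, meta$image_file[i]))
    write_mask_png(cohort[[i]]$truth_mask, file.path(dir, meta$mask_file[i]))
  }
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}
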