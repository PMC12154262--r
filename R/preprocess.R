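## Preprocessing into the network working space: per-image intensity
## normalization, display windowing into three replicated channels, paired
## resize with the scale ratio recorded, and training-time augmentation.

#' Per-image intensity normalization
#'
#' Standardizes an image to mean 0, sd 1 using its own statistics.
#'
#' @param x numeric matrix, or a [ct_slice] (its pixels are used).
#' @return numeric matrix with mean 0 and sd 1.
#' @export
normalize_intensity <- function(x) {
  if (inherits(x, "ct_slice")) x <- x$pixels
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot normalize a constant image (zero variance)")
  (x - mean(x)) / s
}

#' Window an image into three replicated channels
#'
#' Clamps to the display window, rescales to `[0, 1]`, and replicates the
#' result across three channels (the network consumes 3-channel input).
#'
#' @param img numeric matrix.
#' @param window `c(center, width)` display window; `NULL` uses the full
#'   image range.
#' @return `nrow x ncol x 3` array with identical channels, values in `[0, 1]`.
#' @export
to_three_channel <- function(img, window = NULL) {
  if (is.null(window)) {
    lo <- min(img); hi <- max(img)
  } else {
    lo <- window[1] - window[2] / 2
    hi <- window[1] + window[2] / 2
  }
  if (hi <= lo) stop("display window has non-positive width")
  v <- (pmin(pmax(img, lo), hi) - lo) / (hi - lo)
  array(v, dim = c(dim(img), 3))
}

resize_matrix <- function(mat, out_rows, out_cols, filter = "bilinear") {
  out <- EBImage::resize(EBImage::Image(t(mat)), w = out_cols, h = out_rows,
                         filter = filter)
  t(EBImage::imageData(out))
}

#' Resize an image/mask pair into the working resolution
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour (so it stays binary). The per-axis scale ratio
#' `original / working` is recorded for mapping measurements back.
#'
#' @param image `rows x cols x 3` array (or a matrix, treated as one channel
#'   replicated).
#' @param mask optional 0/1 matrix at the same resolution.
#' @param working_size target side, pixels (default 352).
#' @return a `working_sample`: list with `image` (`working x working x 3`),
#'   `mask` (or `NULL`), and `scale_ratio` `(row, col)`.
#' @export
resize_pair <- function(image, mask = NULL, working_size = 352L) {
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 3))
  orig <- dim(image)[1:2]
  out <- array(0, c(working_size, working_size, 3))
  if (all(orig == working_size)) {
    out <- image
  } else {
    for (ch in 1:3)
      out[, , ch] <- resize_matrix(image[, , ch], working_size, working_size)
  }
  m <- NULL
  if (!is.null(mask)) {
    if (all(dim(mask) == working_size)) m <- mask
    else m <- resize_matrix(mask, working_size, working_size, filter = "none")
    m <- (m > 0.5) * 1L
  }
  structure(list(image = out, mask = m,
                 scale_ratio = orig / working_size),
            class = "working_sample")
}

#' Build a working sample from a slice
#'
#' Normalize, window into three channels, and resize; carries provenance and
#' pixel spacing through for downstream calibration.
#'
#' @param slice a [ct_slice].
#' @param mask optional ground-truth 0/1 matrix at original resolution.
#' @param working_size working resolution side (default 352).
#' @param window display window `c(center, width)` applied after
#'   normalization; `NULL` = full range.
#' @return a `working_sample` with `provenance` and `pixel_spacing` fields.
#' @export
make_working_sample <- function(slice, mask = NULL, working_size = 352L,
                                window = NULL) {
  img3 <- to_three_channel(normalize_intensity(slice), window)
  ws <- resize_pair(img3, mask, working_size)
  ws$provenance <- list(subject_id = slice$subject_id,
                        slice_index = slice$slice_index)
  ws$pixel_spacing <- slice$pixel_spacing
  ws
}

flip_h <- function(mat) mat[, rev(seq_len(ncol(mat))), drop = FALSE]
flip_v <- function(mat) mat[rev(seq_len(nrow(mat))), , drop = FALSE]

rotate_matrix <- function(mat, angle, filter) {
  out <- EBImage::rotate(EBImage::Image(t(mat)), angle, filter = filter,
                         output.dim = rev(dim(mat)), bg.col = 0)
  t(EBImage::imageData(out))
}

#' Training-time augmentation
#'
#' Horizontal flip, vertical flip, and rotation are each applied
#' independently with probability `p`; the identical spatial transform is
#' applied to image and mask (mask with nearest-neighbour resampling). The
#' rotation angle is uniform in `[-rotation_limit_deg, rotation_limit_deg]`.
#'
#' @param sample a `working_sample` with a mask.
#' @param p per-transform application probability (default 0.5).
#' @param rotation_limit_deg rotation half-range, degrees (default 30).
#' @param plan optional forced decisions, a list with logical `hflip`,
#'   `vflip`, `rotate` and numeric `angle`; when given no random draws are
#'   made (used to make augmentation reproducible or to force branches).
#' @return the augmented `working_sample`; the decisions actually applied are
#'   attached as the `plan` field.
#' @export
augment <- function(sample, p = 0.5, rotation_limit_deg = 30, plan = NULL) {
  if (is.null(plan)) {
    u <- runif(3)
    plan <- list(hflip = u[1] < p, vflip = u[2] < p, rotate = u[3] < p,
                 angle = runif(1, -rotation_limit_deg, rotation_limit_deg))
  }
  img <- sample$image
  msk <- sample$mask
  tx <- function(mat, filter) {
    if (plan$hflip) mat <- flip_h(mat)
    if (plan$vflip) mat <- flip_v(mat)
    if (plan$rotate && plan$angle != 0) mat <- rotate_matrix(mat, plan$angle, filter)
    mat
  }
  for (ch in 1:3) img[, , ch] <- tx(img[, , ch], "bilinear")
  if (!is.null(msk)) msk <- (tx(msk, "none") > 0.5) * 1L
  sample$image <- img
  sample$mask <- msk
  sample$plan <- plan
  sample
}
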