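## Ellipse-based calibration: contour extraction from the predicted mask,
## direct least-squares ellipse fitting, the minor-axis diameter, the
## quality-rejection rule (zero or multiple candidate regions, or a failed
## fit), and conversion to millimetres via pixel spacing and the
## working-resolution scale ratio.

#' Extract candidate region contours from a binary mask
#'
#' Connected foreground components (8-connectivity) with at least `min_area`
#' pixels each contribute one closed outer boundary; smaller components are
#' discarded before counting, so specks never trigger the multiple-candidate
#' rejection.
#'
#' @param mask 0/1 matrix.
#' @param min_area minimum component area in pixels (default 10).
#' @return list of contours, each a matrix with columns `x`, `y` (0-based
#'   pixel coordinates of boundary pixel centres); empty list allowed.
#' @export
extract_candidates <- function(mask, min_area = 10) {
  if (!any(mask > 0)) return(list())
  lab <- EBImage::bwlabel(mask > 0)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(list())
  contours <- EBImage::ocontour(lab)
  lapply(keep, function(i) {
    oc <- contours[[i]]          # (dim1, dim2) 0-based = (row, col) = (y, x)
    m <- cbind(x = oc[, 2], y = oc[, 1])
    attr(m, "area") <- areas[i]
    m
  })
}

#' Fit an ellipse to a contour by direct least squares
#'
#' Fits the conic `Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0` constrained to an
#' ellipse (`4AC - B^2 > 0`) by the direct least-squares method (generalized
#' eigenproblem of the scatter matrix against the ellipticity constraint),
#' then converts to centre, semi-axes and orientation.
#'
#' @param contour matrix with columns `x`, `y`; at least 5 points.
#' @return an [ellipse_params]; a contour with fewer than 5 points or a
#'   degenerate (e.g. collinear) point set raises an error of class
#'   `fit_failed`.
#' @export
fit_ellipse <- function(contour) {
  fail <- function(msg) stop(errorCondition(msg, class = c("fit_failed", "error")))
  pts <- as.matrix(contour)
  if (nrow(pts) < 5) fail("ellipse fit needs at least 5 contour points")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  x <- pts[, 1] - mx; y <- pts[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) fail("degenerate contour: singular scatter matrix")
  M <- S1 + S2 %*% Tm
  ## premultiply by the inverse of the constraint matrix C1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) fail("degenerate contour: eigen decomposition failed")
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) fail("no elliptical solution for this contour")
  a1 <- V[, ok[1]]
  coef <- c(a1, Tm %*% a1)           # A B C D E F in centred coordinates
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) fail("fitted conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * Fc)
  disc <- sqrt((A - C)^2 + B^2)
  r1 <- num * (A + C + disc)
  r2 <- num * (A + C - disc)
  if (r1 < 0 || r2 < 0) fail("degenerate ellipse axes")
  a_ax <- -sqrt(r1) / den
  b_ax <- -sqrt(r2) / den
  theta <- if (abs(B) < 1e-12 && A <= C) 0
  else if (abs(B) < 1e-12) 90
  else atan2(C - A - disc, B) * 180 / pi
  if (!all(is.finite(c(x0, y0, a_ax, b_ax))) || a_ax <= 0 || b_ax <= 0)
    fail("degenerate ellipse axes")
  ellipse_params(x0 + mx, y0 + my, a_ax, b_ax, theta)
}

## effective scalar from a (row, col) pair; hard error when anisotropy
## exceeds 5% — the minor axis has no fixed image-axis alignment, so strong
## anisotropy cannot be converted exactly
effective_scalar <- function(v, what, tol = 0.05) {
  if (length(v) == 1) return(v)
  if (any(v <= 0)) stop(what, " components must be positive")
  if (abs(v[1] - v[2]) / mean(v) > tol)
    stop(what, " is anisotropic by more than ", tol * 100,
         "% (", v[1], " vs ", v[2], "); cannot form a scalar conversion")
  mean(v)
}

#' Measure the aortic diameter from a predicted mask
#'
#' Applies the rejection rule, then fits an ellipse to the single candidate
#' contour and reports the minor-axis diameter: `diameter_px = 2 b` at
#' working resolution and
#' `diameter_mm = diameter_px * scale_ratio * pixel_spacing`, where both
#' factors are the effective (mean) scalar of their (row, col) pair.
#'
#' Rejection reasons: `empty_mask` (no candidate component of at least
#' `min_area` pixels), `multiple_candidates` (two or more candidates —
#' decided on the count before any fitting), `fit_failed` (the single
#' candidate's ellipse fit failed).
#'
#' Because the fitted contour consists of outer-boundary pixel centres,
#' which lie about half a pixel inside the true region edge, both semi-axes
#' are inflated by `boundary_offset_px` before the diameter is formed.
#'
#' @param mask 0/1 matrix at working resolution.
#' @param pixel_spacing mm/pixel, scalar or `(row, col)` pair.
#' @param scale_ratio original/working size ratio, scalar or pair.
#' @param min_area candidate area floor, pixels.
#' @param boundary_offset_px half-pixel boundary compensation added to each
#'   fitted semi-axis (default 0.5).
#' @param provenance optional `list(subject_id, slice_index)`.
#' @return an `aod_measurement`: list with `provenance`, `accepted`,
#'   `rejection_reason` (`"none"` when accepted), and — when accepted —
#'   `diameter_px`, `diameter_mm`, `ellipse`.
#' @export
measure_aod <- function(mask, pixel_spacing, scale_ratio = 1,
                        min_area = 10, boundary_offset_px = 0.5,
                        provenance = NULL) {
  spacing <- effective_scalar(as.numeric(pixel_spacing), "pixel_spacing")
  ratio <- effective_scalar(as.numeric(scale_ratio), "scale_ratio")
  if (spacing <= 0) stop("pixel_spacing must be positive")
  if (ratio <= 0) stop("scale_ratio must be positive")
  res <- function(accepted, reason, dpx = NA_real_, dmm = NA_real_, ell = NULL)
    structure(list(provenance = provenance, accepted = accepted,
                   rejection_reason = reason, diameter_px = dpx,
                   diameter_mm = dmm, ellipse = ell),
              class = "aod_measurement")
  cands <- extract_candidates(mask, min_area)
  if (length(cands) == 0) return(res(FALSE, "empty_mask"))
  if (length(cands) >= 2) return(res(FALSE, "multiple_candidates"))
  ell <- tryCatch(fit_ellipse(cands[[1]]), fit_failed = function(e) NULL)
  if (is.null(ell)) return(res(FALSE, "fit_failed"))
  ell <- ellipse_params(ell$x0, ell$y0, ell$a + boundary_offset_px,
                        ell$b + boundary_offset_px, ell$theta)
  dpx <- 2 * ell$b
  res(TRUE, "none", dpx, dpx * ratio * spacing, ell)
}

#' Batch measurement with a rejection report
#'
#' @param masks list of 0/1 matrices at working resolution.
#' @param pixel_spacings list/vector of spacings (scalar or pair each).
#' @param scale_ratios list/vector of ratios, recycled if length 1.
#' @param provenance optional list of `list(subject_id, slice_index)`.
#' @param min_area candidate area floor.
#' @return list with `measurements` (all, in input order), `accepted`
#'   (the accepted subset) and `report` (a [rejection_report]).
#' @export
batch_measure <- function(masks, pixel_spacings, scale_ratios = 1,
                          provenance = NULL, min_area = 10) {
  n <- length(masks)
  if (!is.list(pixel_spacings)) pixel_spacings <- as.list(pixel_spacings)
  if (length(pixel_spacings) == 1) pixel_spacings <- rep(pixel_spacings, n)
  if (!is.list(scale_ratios)) scale_ratios <- as.list(scale_ratios)
  if (length(scale_ratios) == 1) scale_ratios <- rep(scale_ratios, n)
  ms <- lapply(seq_len(n), function(i) {
    measure_aod(masks[[i]], pixel_spacings[[i]], scale_ratios[[i]],
                min_area = min_area,
                provenance = if (!is.null(provenance)) provenance[[i]])
  })
  reasons <- vapply(ms, function(m) m$rejection_reason, "")
  rep <- rejection_report(n_processed = n, n_accepted = sum(reasons == "none"),
                          by_reason = table(factor(reasons[reasons != "none"],
                                                   levels = c("empty_mask",
                                                              "multiple_candidates",
                                                              "fit_failed"))))
  list(measurements = ms, accepted = ms[reasons == "none"], report = rep)
}

#' Rejection report
#'
#' Totals of processed and accepted images with the retained fraction and
#' rejection rate; the by-reason breakdown is optional (a report can also be
#' formed from bare counts, e.g. to re-derive a published rejection rate).
#'
#' @param n_processed,n_accepted counts.
#' @param by_reason optional named counts of rejection reasons.
#' @return object of class `rejection_report` with fields `retained_fraction`
#'   and `rejection_rate_percent`.
#' @export
rejection_report <- function(n_processed, n_accepted, by_reason = NULL) {
  if (n_accepted > n_processed) stop("n_accepted cannot exceed n_processed")
  structure(list(n_processed = n_processed, n_accepted = n_accepted,
                 n_rejected = n_processed - n_accepted,
                 retained_fraction = n_accepted / n_processed,
                 rejection_rate_percent = 100 * (1 - n_accepted / n_processed),
                 by_reason = by_reason),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("rejection report: %d processed, %d accepted (%.1f%% rejected)\n",
              x$n_processed, x$n_accepted, x$rejection_rate_percent))
  if (!is.null(x$by_reason)) {
    b <- x$by_reason[x$by_reason > 0]
    if (length(b))
      cat("  by reason:", paste(names(b), b, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Measurement table
#'
#' @param measurements list of `aod_measurement`s.
#' @return data.frame with columns subject_id, slice_index, accepted,
#'   rejection_reason, diameter_px, diameter_mm, x0, y0, a, b, theta.
#' @export
measurement_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m) {
    e <- m$ellipse
    data.frame(subject_id = if (!is.null(m$provenance)) m$provenance$subject_id else NA,
               slice_index = if (!is.null(m$provenance)) m$provenance$slice_index else NA,
               accepted = m$accepted, rejection_reason = m$rejection_reason,
               diameter_px = m$diameter_px, diameter_mm = m$diameter_mm,
               x0 = if (!is.null(e)) e$x0 else NA_real_,
               y0 = if (!is.null(e)) e$y0 else NA_real_,
               a = if (!is.null(e)) e$a else NA_real_,
               b = if (!is.null(e)) e$b else NA_real_,
               theta = if (!is.null(e)) e$theta else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
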