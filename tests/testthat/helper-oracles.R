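## Independent oracle implementations used to cross-check the package:
## deliberately written by a different route than the code under test
## (explicit loops and per-pixel scans, no im2col, no scanline fill).

## minimum caliper width of a mask: extent of foreground pixel centres
## projected onto each of 180 sampled directions, plus one pixel for the
## half-pixel footprint on each side
oracle_caliper_min_width <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  widths <- vapply(seq(0, 179) * pi / 180, function(t) {
    pr <- x * cos(t) + y * sin(t)
    max(pr) - min(pr)
  }, 1)
  min(widths) + 1
}

## brute-force even-odd point-in-polygon over every pixel centre (ray cast
## to the left; a crossing exactly at the centre counts, matching the
## left-boundary-inclusive fill convention)
oracle_polygon_mask <- function(vertices, size) {
  if (length(size) == 1) size <- c(size, size)
  n <- nrow(vertices)
  x1 <- vertices[, 1]; y1 <- vertices[, 2]
  x2 <- x1[c(2:n, 1)]; y2 <- y1[c(2:n, 1)]
  mask <- matrix(0L, size[1], size[2])
  for (r in 0:(size[1] - 1)) for (cc in 0:(size[2] - 1)) {
    crossings <- 0L
    for (e in seq_len(n)) {
      if ((y1[e] <= r && y2[e] > r) || (y2[e] <= r && y1[e] > r)) {
        xint <- x1[e] + (r - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
        if (xint <= cc) crossings <- crossings + 1L
      }
    }
    if (crossings %% 2L == 1L) mask[r + 1, cc + 1] <- 1L
  }
  mask
}

## plain shifted-add 3x3 'same' cross-correlation from a kernel array
oracle_conv3x3 <- function(x, kern, bias) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]; cout <- dim(kern)[4]
  xp <- array(0, c(H + 2, W + 2, cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  y <- array(0, c(H, W, cout))
  for (o in seq_len(cout)) {
    acc <- matrix(bias[o], H, W)
    for (c in seq_len(cin)) for (kj in 1:3) for (ki in 1:3)
      acc <- acc + kern[ki, kj, c, o] * xp[(ki):(ki + H - 1), (kj):(kj + W - 1), c]
    y[, , o] <- acc
  }
  y
}

## unrolled cascade of the multi-scale residual block
oracle_res2net <- function(blk, x) {
  s <- blk$scale; C <- blk$channels; w <- C %/% s
  relu <- function(a) pmax(a, 0)
  kern <- function(nm) array(blk[[nm]]$val, c(3, 3, w, w))
  groups <- vector("list", max(s, 1))
  if (s == 1) {
    groups[[1]] <- relu(oracle_conv3x3(x, array(blk$W1$val, c(3, 3, w, w)),
                                       blk$b1$val))
  } else {
    groups[[1]] <- x[, , 1:w, drop = FALSE]
    for (i in 2:s) {
      xi <- x[, , ((i - 1) * w + 1):(i * w), drop = FALSE] + groups[[i - 1]]
      groups[[i]] <- relu(oracle_conv3x3(xi, kern(paste0("W", i)),
                                         blk[[paste0("b", i)]]$val))
    }
  }
  cat <- array(0, dim(x))
  for (i in seq_along(groups)) cat[, , ((i - 1) * w + 1):(i * w)] <- groups[[i]]
  d <- dim(x)
  fm <- matrix(cat, d[1] * d[2], C) %*% blk$fuseW$val
  fused <- array(fm, d) + array(rep(blk$fuseb$val, each = d[1] * d[2]), d)
  relu(x + fused)
}

## explicit per-pixel loop counts for the overlap metrics
oracle_overlap_counts <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] > 0; g <- gt[i, j] > 0
    if (p && g) tp <- tp + 1L
    else if (p) fp <- fp + 1L
    else if (g) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

## small phantom spec used across tests (64 px slices keep everything fast)
tiny_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 3, slices_per_subject_range = c(3L, 5L),
         image_size = 64L, pixel_spacing_range = c(0.7, 0.8),
         vessel_minor_range_mm = c(10, 16), aspect_ratio_range = c(1.0, 1.4),
         seed = 42L),
    list(...))
  do.call(phantom_spec, args)
}
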