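## The shallow-attention segmentation network: a multi-stage convolutional
## encoder with Res2Net-style multi-scale blocks, per-stage 1x1 conv + BN +
## ReLU heads, shallow-attention gating of upsampled deeper features, and a
## concatenating decoder ending in a 1x1 convolution and sigmoid.
##
## Index reading of the attention recursion (the published form mixes stage
## indices): at every stage the SHALLOW stage's attention map — ReLU of a 1x1
## convolution of that stage's feature map — gates the upsampled deeper
## shallow-attention feature elementwise. The deepest stage seeds the
## recursion with its own head output.

#' Segmentation model configuration
#'
#' @param backbone `"res2net"` (multi-scale blocks + shallow-attention
#'   decoder) or `"unet"` (plain convolutional blocks, no attention gating —
#'   the encoder-decoder baseline).
#' @param working_size input resolution (square); must be divisible by
#'   `2^length(channels)`. Default 352.
#' @param channels encoder channel widths per stage (each stage halves the
#'   spatial resolution). Each must be divisible by `res2net_scale`.
#' @param res2net_scale Res2Net group count `s` (default 4, the canonical
#'   setting for this backbone family).
#' @param decoder_channels width of the per-stage heads and attention maps.
#' @param learning_rate Adam learning rate. The default mirrors the published
#'   training protocol (0.4); in practice that value destabilizes Adam and
#'   the recommended setting is `1e-4` (the tiny preset uses `1e-3`; see the
#'   methods vignette).
#' @param batch_size images per optimization step (default 16).
#' @param epochs training epochs (default 100).
#' @param seed RNG seed for weight initialization and data order.
#' @param loss loss name; `"bce_dice"` (weighted binary cross-entropy plus
#'   soft Dice) is the only built-in.
#' @param bce_weight,dice_weight loss-term weights.
#' @param threshold probability cutoff for [binarize], in `(0, 1)`.
#' @return object of class `model_config`.
#' @export
model_config <- function(backbone = c("res2net", "unet"),
                         working_size = 352L,
                         channels = c(16L, 32L, 64L),
                         res2net_scale = 4L,
                         decoder_channels = 16L,
                         learning_rate = 0.4,
                         batch_size = 16L,
                         epochs = 100L,
                         seed = 1L,
                         loss = "bce_dice",
                         bce_weight = 1,
                         dice_weight = 1,
                         threshold = 0.5) {
  backbone <- match.arg(backbone)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly inside (0, 1)")
  if (epochs < 1) stop("epochs must be >= 1")
  n_stages <- length(channels)
  if (working_size %% (2^n_stages) != 0)
    stop("working_size must be divisible by 2^n_stages = ", 2^n_stages)
  if (backbone == "res2net" && any(channels %% res2net_scale != 0))
    stop("every stage channel count must be divisible by res2net_scale = ",
         res2net_scale)
  structure(list(backbone = backbone, working_size = as.integer(working_size),
                 channels = as.integer(channels),
                 res2net_scale = as.integer(res2net_scale),
                 decoder_channels = as.integer(decoder_channels),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = loss, bce_weight = bce_weight,
                 dice_weight = dice_weight, threshold = threshold),
            class = "model_config")
}

#' Tiny model preset for CPU-scale experiments
#'
#' Reduced channel widths and 96x96 inputs; used by the package's phantom
#' experiments and tests.
#'
#' @param ... overrides passed to [model_config].
#' @return a `model_config`.
#' @export
tiny_model_config <- function(...) {
  defaults <- list(backbone = "res2net", working_size = 96L,
                   channels = c(8L, 16L, 32L), res2net_scale = 4L,
                   decoder_channels = 8L, learning_rate = 1e-3,
                   batch_size = 16L, epochs = 30L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

conv_init <- function(k, cin, cout, sd = sqrt(2 / (k * k * cin))) {
  ag_param(matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout))
}
bias_init <- function(cout, value = 0) ag_param(rep(value, cout))

#' Create a Res2Net-style block's parameters
#'
#' The block splits its `channels` input channels into `scale` groups of
#' equal width. Group 1 passes through untouched; each group `i >= 2` is
#' passed through a 3x3 convolution + ReLU after adding the previous group's
#' output, so later groups see increasingly large receptive fields. The
#' groups are concatenated, fused by a 1x1 convolution, residual-added to
#' the block input, and ReLU-activated. With `scale = 1` the block reduces
#' to a standard residual block (one 3x3 convolution + ReLU, 1x1 fuse,
#' residual add).
#'
#' @param channels input/output channel count; divisible by `scale`.
#' @param scale group count `s >= 1`.
#' @return list of parameter tensors (weights drawn from the current RNG).
#' @export
new_res2net_block <- function(channels, scale = 4L) {
  if (channels %% scale != 0)
    stop("channels (", channels, ") not divisible by res2net scale (", scale, ")")
  w <- channels %/% scale
  blk <- list(channels = channels, scale = scale)
  conv_groups <- if (scale == 1) 1L else 2:scale
  for (i in conv_groups) {
    blk[[paste0("W", i)]] <- conv_init(3, w, w)
    blk[[paste0("b", i)]] <- bias_init(w)
  }
  blk$fuseW <- conv_init(1, channels, channels)
  blk$fuseb <- bias_init(channels)
  blk
}

res2net_forward <- function(tape, x, blk) {
  s <- blk$scale
  C <- blk$channels
  w <- C %/% s
  if (s == 1) {
    groups <- list(ag_relu(tape, ag_conv2d(tape, x, blk$W1, blk$b1)))
  } else {
    groups <- vector("list", s)
    groups[[1]] <- ag_slice_c(tape, x, 1:w)
    for (i in 2:s) {
      xi <- ag_slice_c(tape, x, ((i - 1) * w + 1):(i * w))
      xi <- ag_add(tape, xi, groups[[i - 1]])
      groups[[i]] <- ag_relu(tape, ag_conv2d(tape, xi,
                                             blk[[paste0("W", i)]],
                                             blk[[paste0("b", i)]]))
    }
  }
  cat <- if (length(groups) == 1) groups[[1]] else ag_concat_c(tape, groups)
  fused <- ag_conv1x1(tape, cat, blk$fuseW, blk$fuseb)
  ag_relu(tape, ag_add(tape, x, fused))
}

#' Apply a Res2Net block to a feature map
#'
#' Functional forward pass over a plain array (no training state), provided
#' so the block can be exercised and cross-checked in isolation.
#'
#' @param blk a block from [new_res2net_block] (its parameter `$val` fields
#'   may be set by hand).
#' @param x `H x W x C` array with `C = blk$channels`.
#' @return `H x W x C` array.
#' @export
res2net_apply <- function(blk, x) {
  tape <- ag_tape()
  res2net_forward(tape, ag_const(x), blk)$val
}

#' Shallow-attention gating of a deeper feature map
#'
#' The attention map is the ReLU of a 1x1 convolution of the shallow
#' feature; the enhanced feature is the deeper shallow-attention feature,
#' upsampled to the shallow resolution, multiplied elementwise by the
#' attention map. All attention entries are non-negative by construction.
#'
#' @param f_shallow `H x W x C` array, the shallow stage's feature map.
#' @param f_deep_sa array at the same or coarser resolution with
#'   `decoder_channels` channels, the deeper stage's SA feature.
#' @param W,b 1x1-convolution weight matrix (`C x decoder_channels`) and bias.
#' @return list with `attention` (same `H x W`, `decoder_channels` channels)
#'   and `output` (same shape as `attention`).
#' @export
shallow_attention <- function(f_shallow, f_deep_sa, W, b) {
  dd <- dim(f_deep_sa)
  ds <- dim(f_shallow)
  if (dd[1] > ds[1] || dd[2] > ds[2])
    stop("deeper feature map must be spatially coarser than or equal to the shallow one")
  if (ncol(W) != dd[3])
    stop("attention channels (", ncol(W), ") must match deeper feature channels (",
         dd[3], ")")
  tape <- ag_tape()
  att <- ag_relu(tape, ag_conv1x1(tape, ag_const(f_shallow),
                                  ag_param(W), ag_param(b)))
  up <- ag_upsample(tape, ag_const(f_deep_sa),
                    interp_matrix(dd[1], ds[1]), interp_matrix(dd[2], ds[2]))
  out <- ag_mul(tape, up, att)
  list(attention = att$val, output = out$val)
}

#' Build a segmentation model
#'
#' Initializes all parameters deterministically from `config$seed`.
#'
#' @param config a [model_config].
#' @return object of class `aod_model` (mutable: parameters are updated in
#'   place by [train_model]).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_local_seed(config$seed, {
    P <- list()
    blocks <- list()
    K <- length(config$channels)
    cin <- 3L
    for (k in seq_len(K)) {
      ck <- config$channels[k]
      P[[paste0("stage", k, ".conv.W")]] <- conv_init(3, cin, ck)
      P[[paste0("stage", k, ".conv.b")]] <- bias_init(ck)
      P[[paste0("stage", k, ".bn.gamma")]] <- ag_param(rep(1, ck))
      P[[paste0("stage", k, ".bn.beta")]] <- ag_param(numeric(ck))
      scale <- if (config$backbone == "res2net") config$res2net_scale else 1L
      blocks[[k]] <- new_res2net_block(ck, scale)
      for (nm in setdiff(names(blocks[[k]]), c("channels", "scale")))
        P[[paste0("stage", k, ".block.", nm)]] <- blocks[[k]][[nm]]
      cin <- ck
    }
    D <- config$decoder_channels
    for (k in seq_len(K)) {
      ck <- config$channels[k]
      P[[paste0("head", k, ".conv.W")]] <- conv_init(1, ck, D)
      P[[paste0("head", k, ".conv.b")]] <- bias_init(D)
      P[[paste0("head", k, ".bn.gamma")]] <- ag_param(rep(1, D))
      P[[paste0("head", k, ".bn.beta")]] <- ag_param(numeric(D))
    }
    if (config$backbone == "res2net") {
      for (k in seq_len(K - 1)) {
        P[[paste0("att", k, ".conv.W")]] <- conv_init(1, config$channels[k], D)
        ## bias 1 starts the gate near pass-through so gradients flow early
        P[[paste0("att", k, ".conv.b")]] <- bias_init(D, 1)
      }
    }
    dec_in <- K * D + if (config$backbone == "res2net") D else 0L
    P[["final.conv.W"]] <- conv_init(1, dec_in, 1L)
    ## negative bias: the foreground is a small fraction of the image
    P[["final.conv.b"]] <- bias_init(1L, -2)
    structure(list(config = config, params = P, blocks = blocks,
                   opt = adam_state()),
              class = "aod_model")
  })
}

up_mat <- function(model, n_in, n_out, method = "bilinear") {
  ## interpolation matrices are deterministic; cheap enough to rebuild
  interp_matrix(n_in, n_out, method)
}

#' Forward pass of the segmentation network
#'
#' The normalization layers use per-sample spatial statistics with learned
#' affine parameters, so the training and inference paths are identical and
#' the forward pass is a deterministic function of the weights and input.
#'
#' @param model an `aod_model`.
#' @param image `working_size x working_size x 3` array.
#' @return list with `prob` (matrix of per-pixel probabilities in `[0, 1]` at
#'   working resolution), `logits` (the pre-sigmoid output node), `tape`
#'   (for backpropagation), and `attention` (list of attention-map arrays,
#'   all entries `>= 0`).
#' @export
model_forward <- function(model, image) {
  cfg <- model$config
  if (length(dim(image)) != 3 || dim(image)[3] != 3 ||
      dim(image)[1] != cfg$working_size || dim(image)[2] != cfg$working_size)
    stop("input must be ", cfg$working_size, "x", cfg$working_size, "x3, got ",
         paste(dim(image), collapse = "x"))
  P <- model$params
  tape <- ag_tape()
  K <- length(cfg$channels)
  feats <- vector("list", K)
  x <- ag_const(image)
  for (k in seq_len(K)) {
    x <- ag_conv2d(tape, x, P[[paste0("stage", k, ".conv.W")]],
                   P[[paste0("stage", k, ".conv.b")]], stride = 2L)
    x <- ag_bn(tape, x, P[[paste0("stage", k, ".bn.gamma")]],
               P[[paste0("stage", k, ".bn.beta")]])
    x <- ag_relu(tape, x)
    x <- res2net_forward(tape, x, model$blocks[[k]])
    feats[[k]] <- x
  }
  heads <- vector("list", K)
  for (k in seq_len(K)) {
    h <- ag_conv1x1(tape, feats[[k]], P[[paste0("head", k, ".conv.W")]],
                    P[[paste0("head", k, ".conv.b")]])
    h <- ag_bn(tape, h, P[[paste0("head", k, ".bn.gamma")]],
               P[[paste0("head", k, ".bn.beta")]])
    heads[[k]] <- ag_relu(tape, h)
  }
  att_maps <- list()
  sizes <- cfg$working_size %/% 2^seq_len(K)
  dec <- vector("list", K)
  for (k in seq_len(K)) {
    dec[[k]] <- if (k == 1) heads[[1]]
    else ag_upsample(tape, heads[[k]],
                     up_mat(model, sizes[k], sizes[1]),
                     up_mat(model, sizes[k], sizes[1]))
  }
  if (cfg$backbone == "res2net") {
    ## shallow-attention stream: the deepest head seeds the recursion; at
    ## each shallower stage its attention map gates the upsampled stream
    sa <- heads[[K]]
    for (k in rev(seq_len(K - 1))) {
      m <- ag_relu(tape, ag_conv1x1(tape, feats[[k]],
                                    P[[paste0("att", k, ".conv.W")]],
                                    P[[paste0("att", k, ".conv.b")]]))
      att_maps[[paste0("stage", k)]] <- m$val
      up <- ag_upsample(tape, sa,
                        up_mat(model, sizes[k + 1], sizes[k]),
                        up_mat(model, sizes[k + 1], sizes[k]))
      sa <- ag_mul(tape, up, m)
    }
    dec[[K + 1]] <- sa
  }
  cat <- ag_concat_c(tape, dec)
  logits <- ag_conv1x1(tape, cat, P[["final.conv.W"]], P[["final.conv.b"]])
  logits <- ag_upsample(tape, logits,
                        up_mat(model, sizes[1], cfg$working_size),
                        up_mat(model, sizes[1], cfg$working_size))
  list(prob = plogis(logits$val[, , 1]), logits = logits, tape = tape,
       attention = att_maps)
}

#' Predict a probability map for a working sample
#'
#' @param model an `aod_model`.
#' @param sample a `working_sample` (or a bare `HxWx3` array).
#' @return matrix of probabilities at working resolution.
#' @export
predict_prob <- function(model, sample) {
  img <- if (inherits(sample, "working_sample")) sample$image else sample
  model_forward(model, img)$prob
}

#' Threshold a probability map into a binary mask
#'
#' @param prob probability matrix.
#' @param threshold cutoff in `(0, 1)`; foreground is `prob > threshold`.
#' @return integer 0/1 matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly inside (0, 1)")
  m <- prob > threshold
  storage.mode(m) <- "integer"
  m
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: they carry the full configuration and
#' every weight, so a reloaded model reproduces probability maps
#' bit-identically.
#'
#' @param model an `aod_model`.
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(config = unclass(model$config),
             weights = lapply(model$params, function(p) p$val))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `aod_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "model_config")
  model <- build_model(cfg)
  for (nm in names(ck$weights)) model$params[[nm]]$val <- ck$weights[[nm]]
  model
}
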