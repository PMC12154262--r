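## Training loop: weighted binary cross-entropy + soft Dice, Adam, gradient
## accumulation over a mini-batch, deterministic given the config seed.

## loss value and its gradient with respect to the logits
bce_dice_loss <- function(logits, y, bce_weight = 1, dice_weight = 1,
                          eps = 1e-7) {
  p <- plogis(logits)
  n <- length(p)
  bce <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  denom <- sp + sy + eps
  dice <- (2 * spy + eps) / denom
  loss <- bce_weight * bce + dice_weight * (1 - dice)
  ## d(dice)/dp_i = (2 y_i * denom - (2 spy + eps)) / denom^2
  ddice_dp <- (2 * y * denom - (2 * spy + eps)) / denom^2
  dbce_dz <- (p - y) / n
  grad <- bce_weight * dbce_dz - dice_weight * ddice_dp * p * (1 - p)
  list(loss = loss, grad = grad, dice = dice)
}

#' Train a segmentation model
#'
#' Runs mini-batch Adam on the weighted BCE + soft-Dice loss. Gradients are
#' accumulated over each batch and averaged. The whole run — shuffling
#' included — is a deterministic function of the model's config seed, so the
#' same configuration trained twice yields identical weights. A non-finite
#' loss aborts with an error naming the epoch.
#'
#' @param model an `aod_model` from [build_model]; updated in place.
#' @param train_samples list of `working_sample`s with masks.
#' @param val_samples optional held-out list; per-epoch mean Dice on it is
#'   logged when supplied.
#' @param epochs,batch_size,learning_rate overrides of the config values.
#' @param verbose print a line per epoch.
#' @return the training log: data.frame with `epoch`, `loss`, `train_dice`
#'   (mean per-image soft Dice), and `val_dice` when validation data is
#'   given. The trained model is returned as the `model` attribute.
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        epochs = NULL, batch_size = NULL,
                        learning_rate = NULL, verbose = FALSE) {
  cfg <- model$config
  if (length(train_samples) == 0) stop("empty training set")
  epochs <- if (is.null(epochs)) cfg$epochs else epochs
  batch_size <- if (is.null(batch_size)) cfg$batch_size else batch_size
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate
  n <- length(train_samples)
  log <- vector("list", epochs)
  with_local_seed(cfg$seed + 1L, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c(); dices <- c()
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        ag_zero_grad(model$params)
        for (i in idx) {
          s <- train_samples[[i]]
          fw <- model_forward(model, s$image)
          lg <- bce_dice_loss(fw$logits$val[, , 1], s$mask,
                              cfg$bce_weight, cfg$dice_weight)
          if (!is.finite(lg$loss))
            stop("training diverged (non-finite loss) at epoch ", e)
          losses <- c(losses, lg$loss)
          dices <- c(dices, lg$dice)
          seed <- array(lg$grad / length(idx), dim(fw$logits$val))
          ag_backward(fw$tape, fw$logits, seed)
        }
        adam_step(model$params, model$opt, lr)
      }
      row <- data.frame(epoch = e, loss = mean(losses),
                        train_dice = mean(dices))
      if (!is.null(val_samples)) {
        vd <- vapply(val_samples, function(s) {
          dice_coef(binarize(predict_prob(model, s), cfg$threshold), s$mask)
        }, 1)
        row$val_dice <- mean(vd)
      }
      log[[e]] <- row
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  dice %.4f%s\n", e, row$loss,
                    row$train_dice,
                    if (!is.null(row$val_dice))
                      sprintf("  val_dice %.4f", row$val_dice) else ""))
    }
  })
  out <- do.call(rbind, log)
  attr(out, "model") <- model
  out
}
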