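# Train / predict / evaluate orchestration: paired-PNG dataset loading,
# Adam optimization of the expanded U-Net under the expanded cross-entropy
# (or per-channel binary cross-entropy) loss, grey-map prediction, and
# grey-mass evaluation reports.

#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size N.
#' @param learning_rate Adam step size.
#' @param loss `"ece"` — the expanded (ternary) cross-entropy, channel sums
#'   over the 3 output channels — or `"bce"` — per-channel binary
#'   cross-entropy averaged over channels (the deployment-compatible
#'   variant; same minimizer, 1/3 the magnitude and update rate).
#' @param label_mode `"grey"` — grey-level probability targets (0 / 0.5 / 1
#'   on all three channels) — or `"ordinary"` — conventional one-hot class
#'   targets. The two modes are the compared training conditions.
#' @param seed Seed applied at the start of training (weight init when a
#'   fresh model is built, shuffling, dropout).
#' @param augment Apply a random geometric augmentation to each pair at
#'   every epoch.
#' @param checkpoint Optional path: save the final model there.
#' @param history Optional path: per-epoch loss appended as TSV.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 20L, batch_size = 4L, learning_rate = 1e-3,
                         loss = c("ece", "bce"),
                         label_mode = c("grey", "ordinary"),
                         seed = 42L, augment = FALSE,
                         checkpoint = NULL, history = NULL) {
  loss <- match.arg(loss); label_mode <- match.arg(label_mode)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 label_mode = label_mode, seed = as.integer(seed),
                 augment = augment, checkpoint = checkpoint,
                 history = history),
            class = "train_config")
}

#' Load a paired image/mask dataset from a directory
#'
#' Expects `img_*.png` with matching `msk_*.png` (same numeric suffix), as
#' written by [generate_phantom_dataset()].
#'
#' @param dir Dataset directory.
#' @param remap Passed to [read_mask_png()].
#' @return `list(images = list of matrices, masks = list of matrices,
#'   names = suffixes)`.
#' @export
load_paired_dataset <- function(dir, remap = FALSE) {
  imgs <- sort(list.files(dir, pattern = "^img_.*\\.png$"))
  if (length(imgs) == 0) stop("no img_*.png files in ", dir)
  msks <- sub("^img_", "msk_", imgs)
  missing <- msks[!file.exists(file.path(dir, msks))]
  if (length(missing) > 0)
    stop("masks missing for ", length(missing), " image(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  list(images = lapply(file.path(dir, imgs), read_image_png),
       masks = lapply(file.path(dir, msks), read_mask_png, remap = remap),
       names = sub("^img_(.*)\\.png$", "\\1", imgs))
}

# masks -> (B*H*W) x 3 target matrix for the configured label mode
build_targets <- function(masks, label_mode) {
  cls <- unlist(lapply(masks, as.vector), use.names = FALSE)
  if (label_mode == "grey") {
    y <- CLASS_PROB[cls + 1L]
    cbind(y, y, y, deparse.level = 0)
  } else {
    onehot <- diag(3)[cls + 1L, , drop = FALSE]
    unname(onehot)
  }
}

# ---- Adam over the nested parameter lists ------------------------------

zeros_like <- function(g) {
  if (is.null(g)) return(NULL)
  if (!is.list(g)) return(g * 0)
  lapply(g, zeros_like)
}

adam_apply <- function(params, grads, m, v, lr, t,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(grads)) return(list(p = params, m = m, v = v))
  if (!is.list(grads)) {
    m <- b1 * m + (1 - b1) * grads
    v <- b2 * v + (1 - b2) * grads^2
    mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
    return(list(p = params - lr * mhat / (sqrt(vhat) + eps), m = m, v = v))
  }
  keys <- if (is.null(names(grads))) seq_along(grads) else names(grads)
  for (k in keys) {
    r <- adam_apply(params[[k]], grads[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps)
    params[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
  }
  list(p = params, m = m, v = v)
}

#' Train the expanded U-Net
#'
#' Runs mini-batch gradient descent (Adam) on the configured loss, records
#' the per-epoch mean training loss, and optionally writes the history file
#' and a final checkpoint. With a fixed seed the run — weight
#' initialization, shuffling, dropout, augmentation — is reproducible.
#'
#' @param data A directory of paired PNGs (see [load_paired_dataset()]) or a
#'   list with `images` and `masks`.
#' @param cfg A [train_config()].
#' @param model An existing `"expanded_unet"` to continue training, or an
#'   [unet_config()] from which a fresh model is built (default
#'   configuration sized to the data if omitted).
#' @param verbose Print per-epoch loss.
#' @return `list(model, history)` where `history` is a data frame with
#'   columns `epoch`, `loss`, `seconds`.
#' @export
train_unet <- function(data, cfg = train_config(), model = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.character(data)) data <- load_paired_dataset(data)
  images <- data$images; masks <- data$masks
  if (length(images) != length(masks))
    stop("image/mask count mismatch: ", length(images), " vs ", length(masks))
  hw <- dim(images[[1]])

  set.seed(cfg$seed)
  if (is.null(model)) model <- build_expanded_unet(unet_config(input_size = hw))
  if (inherits(model, "unet_config")) model <- build_expanded_unet(model)
  stopifnot(inherits(model, "expanded_unet"))
  if (!all(model$cfg$input_size == hw))
    stop("model input_size ", paste(model$cfg$input_size, collapse = "x"),
         " does not match data ", paste(hw, collapse = "x"))

  n <- length(images)
  npix <- prod(hw)
  scale3 <- if (cfg$loss == "bce") 3 else 1   # bce = channel mean, not sum
  mstate <- NULL; vstate <- NULL; t_step <- 0
  history <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[3]
    order <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- order[start:min(start + cfg$batch_size - 1, n)]
      B <- length(idx)
      ims <- images[idx]; mks <- masks[idx]
      if (cfg$augment) {
        for (j in seq_len(B)) {
          a <- augment(ims[[j]], mks[[j]])
          ims[[j]] <- a$image; mks[[j]] <- a$mask
        }
      }
      X <- stack_images(ims, hw)
      Y <- build_targets(mks, cfg$label_mode)

      fw <- unet_apply(model, X, B, training = TRUE, keep_cache = TRUE)
      P <- clip_prob(fw$P)
      loss <- -sum(Y * log(P) + (1 - Y) * log(1 - P)) / (B * npix * scale3)
      dP <- (-Y / P + (1 - Y) / (1 - P)) / (B * npix * scale3)
      if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch)

      grads <- unet_backprop(model, fw$cache, dP, B)
      model <- bn_commit(model, fw$cache)
      if (is.null(mstate)) { mstate <- zeros_like(grads); vstate <- zeros_like(grads) }
      t_step <- t_step + 1
      upd <- adam_apply(model$params, grads, mstate, vstate,
                        cfg$learning_rate, t_step)
      model$params <- upd$p; mstate <- upd$m; vstate <- upd$v
      losses <- c(losses, loss)
    }
    history[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                   seconds = proc.time()[3] - t0)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  (%.1fs)", epoch, mean(losses),
                      history[[epoch]]$seconds))
  }
  history <- do.call(rbind, history)
  rownames(history) <- NULL
  if (!is.null(cfg$history))
    utils::write.table(history, cfg$history, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(cfg$checkpoint)) save_checkpoint(model, cfg$checkpoint)
  list(model = model, history = history)
}

#' Predict a grey output map for one image
#'
#' Inference is deterministic (dropout off, batch-norm running statistics).
#'
#' @param model An `"expanded_unet"` or a checkpoint path.
#' @param image `H x W` matrix in `[0, 1]`.
#' @return `list(pred = H x W x 3 probability array, grey = H x W grey map
#'   in [0, 255])`.
#' @export
predict_unet <- function(model, image) {
  if (is.character(model)) model <- load_checkpoint(model)
  pred <- unet_forward(model, image, training = FALSE)
  list(pred = pred, grey = prediction_to_grey_map(pred))
}

#' Predict grey maps for a directory of images
#'
#' Writes `pred_<suffix>.png` (8-bit grey) for every `img_<suffix>.png`;
#' with `keep_raw = TRUE` the raw 3-channel probability maps are saved as
#' `pred_<suffix>.rds` alongside.
#'
#' @param model An `"expanded_unet"` or checkpoint path.
#' @param in_dir Directory of `img_*.png` inputs.
#' @param out_dir Output directory (created if missing).
#' @param keep_raw Also save raw probability arrays.
#' @return Character vector of written PNG paths, invisibly.
#' @export
predict_dir <- function(model, in_dir, out_dir, keep_raw = FALSE) {
  if (is.character(model)) model <- load_checkpoint(model)
  imgs <- sort(list.files(in_dir, pattern = "^img_.*\\.png$"))
  if (length(imgs) == 0) stop("no img_*.png files in ", in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(length(imgs))
  for (i in seq_along(imgs)) {
    image <- read_image_png(file.path(in_dir, imgs[i]))
    res <- predict_unet(model, image)
    stem <- sub("^img_(.*)\\.png$", "\\1", imgs[i])
    out[i] <- file.path(out_dir, paste0("pred_", stem, ".png"))
    write_grey_png(res$grey, out[i])
    if (keep_raw) saveRDS(res$pred, file.path(out_dir, paste0("pred_", stem, ".rds")))
  }
  invisible(out)
}

#' Evaluate predicted grey maps against ground-truth masks
#'
#' Matches `pred_<suffix>.png` in `pred_dir` to `msk_<suffix>.png` in
#' `truth_dir` and scores each pair with the grey-mass Dice/IOU for every
#' tumour class present in the truth.
#'
#' @param pred_dir Directory of predicted grey maps.
#' @param truth_dir Directory of ordinary masks.
#' @param report_path Optional TSV path passed to [write_grey_report()].
#' @return A list from [summarize_grey_report()]: `per_image` rows (grey
#'   masses, delta, Dice%, IOU%) and a per-class `summary` with mean and
#'   standard deviation.
#' @export
evaluate_dir <- function(pred_dir, truth_dir, report_path = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "^pred_.*\\.png$"))
  if (length(preds) == 0) stop("no pred_*.png files in ", pred_dir)
  stems <- sub("^pred_(.*)\\.png$", "\\1", preds)
  msks <- paste0("msk_", stems, ".png")
  missing <- msks[!file.exists(file.path(truth_dir, msks))]
  if (length(missing) > 0)
    stop("ground-truth masks missing: ", paste(utils::head(missing, 5), collapse = ", "))
  rows <- lapply(seq_along(preds), function(i) {
    grey <- read_image_png(file.path(pred_dir, preds[i])) * 255
    mask <- read_mask_png(file.path(truth_dir, msks[i]))
    r <- grey_overlap_report(mask, grey)
    r$image <- stems[i]
    r
  })
  report <- do.call(rbind, rows)
  if (!is.null(report_path)) write_grey_report(report, report_path)
  summarize_grey_report(report)
}
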