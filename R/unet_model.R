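# The expanded U-Net: a symmetric encoder-decoder with skip fusions, seven
# dropout layers at the default depth, batch normalization after every
# convolution and deconvolution, leaky-ReLU activations, and a 1x1
# convolution head mapping the 8-channel feature vector to the 3-channel
# grey-level output map.

#' Architecture configuration for the expanded U-Net
#'
#' @param depth Number of down-sampling (max-pool) steps; the decoder
#'   mirrors it. Default 4.
#' @param base_channels Feature channels at the first encoder level; they
#'   double at each deeper level. Default 8, so the last decoder level emits
#'   the 8-channel feature vector consumed by the output head.
#' @param dropout_rate Shielding probability P of each dropout layer during
#'   training. Default 0.5.
#' @param leaky_slope Negative-slope coefficient of the leaky-ReLU
#'   activations. Default 0.01.
#' @param head Output activation: `"softmax"` (per-pixel channel sum 1) or
#'   `"sigmoid"` (channels independent). Default softmax.
#' @param input_size `c(H, W)`; both must be divisible by `2^depth`.
#' @param batch_norm Apply batch normalization after each convolution /
#'   deconvolution. Default `TRUE`.
#' @return A validated configuration list of class `"unet_config"`.
#' @export
unet_config <- function(depth = 4L, base_channels = 8L, dropout_rate = 0.5,
                        leaky_slope = 0.01, head = c("softmax", "sigmoid"),
                        input_size = c(64L, 64L), batch_norm = TRUE) {
  head <- match.arg(head)
  stopifnot(depth >= 1, base_channels >= 1,
            dropout_rate >= 0, dropout_rate < 1, leaky_slope >= 0)
  if (length(input_size) != 2 || any(input_size %% 2^depth != 0))
    stop("input_size (", paste(input_size, collapse = "x"),
         ") must have both dimensions divisible by 2^depth = ", 2^depth)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope,
                 head = head, input_size = as.integer(input_size),
                 batch_norm = batch_norm),
            class = "unet_config")
}

# dropout placement: one after each of the `depth` decoder fusion
# (concatenation) layers, plus after the two deepest encoder blocks and the
# bottleneck block -> depth + 3 layers (7 at the default depth 4)
dropout_plan <- function(depth) {
  list(encoder = seq_len(depth) >= depth - 1,
       bottleneck = TRUE,
       decoder = rep(TRUE, depth))
}

#' Build an expanded U-Net model
#'
#' Constructs the network graph and initializes its weights (He
#' initialization, driven by the current RNG state — seed beforehand for
#' reproducible initialization). Per encoder level: two 3x3 same-padding
#' convolutions, each followed by batch normalization and leaky ReLU, then
#' 2x2 max pooling; feature channels double per level. The decoder mirrors
#' this with 2x2 stride-2 transposed convolutions and skip concatenation
#' ("fusion") at each level. Dropout layers sit after each fusion, after the
#' two deepest encoder blocks and after the bottleneck — 7 in total at the
#' default depth. The head is a 1x1 convolution from `base_channels`
#' features to 3 output channels with a softmax (default) or sigmoid
#' activation.
#'
#' @param cfg An [unet_config()].
#' @return An object of class `"expanded_unet"`; see [model_graph()],
#'   [dropout_layer_count()], [n_parameters()], [unet_forward()].
#' @examples
#' set.seed(1)
#' net <- build_expanded_unet(unet_config(input_size = c(32, 32)))
#' dropout_layer_count(net)   # 7
#' @export
build_expanded_unet <- function(cfg = unet_config()) {
  stopifnot(inherits(cfg, "unet_config"))
  D <- cfg$depth
  ch <- cfg$base_channels * 2^(0:D)      # ch[l] = channels at level l; ch[D+1] = bottleneck
  drop <- dropout_plan(D)

  graph <- list()
  note <- function(name, kind, c_in, c_out, level) {
    graph[[length(graph) + 1]] <<- data.frame(
      name = name, kind = kind, c_in = c_in, c_out = c_out, level = level)
  }
  conv_block <- function(c_in, c_out, tag, level) {
    note(paste0(tag, "_conv1"), "conv3x3", c_in, c_out, level)
    note(paste0(tag, "_conv2"), "conv3x3", c_out, c_out, level)
    list(conv1 = conv3_init(c_in, c_out), bn1 = bn_init(c_out),
         conv2 = conv3_init(c_out, c_out), bn2 = bn_init(c_out))
  }

  enc <- vector("list", D)
  c_prev <- 1L
  for (l in seq_len(D)) {
    enc[[l]] <- conv_block(c_prev, ch[l], paste0("enc", l), l)
    if (drop$encoder[l]) note(paste0("enc", l, "_dropout"), "dropout", ch[l], ch[l], l)
    note(paste0("pool", l), "maxpool2x2", ch[l], ch[l], l)
    c_prev <- ch[l]
  }
  bott <- conv_block(ch[D], ch[D + 1], "bottleneck", D + 1)
  if (drop$bottleneck) note("bottleneck_dropout", "dropout", ch[D + 1], ch[D + 1], D + 1)

  dec <- vector("list", D)
  for (l in rev(seq_len(D))) {
    c_above <- if (l == D) ch[D + 1] else ch[l + 1]
    note(paste0("up", l), "upconv2x2", c_above, ch[l], l)
    note(paste0("fuse", l), "concat", 2 * ch[l], 2 * ch[l], l)
    if (drop$decoder[l]) note(paste0("fuse", l, "_dropout"), "dropout", 2 * ch[l], 2 * ch[l], l)
    dec[[l]] <- c(list(up = upconv_init(c_above, ch[l]), upbn = bn_init(ch[l])),
                  conv_block(2 * ch[l], ch[l], paste0("dec", l), l))
  }
  note("head", "conv1x1", ch[1], 3L, 0L)
  note("head_activation", cfg$head, 3L, 3L, 0L)

  structure(list(cfg = cfg,
                 params = list(enc = enc, bott = bott, dec = dec,
                               head = conv1_init(ch[1], 3L)),
                 graph = do.call(rbind, graph),
                 geom_cache = new.env(parent = emptyenv())),
            class = "expanded_unet")
}

#' Inspect the model graph
#'
#' @param model An `"expanded_unet"`.
#' @return `model_graph()`: data frame of layers (name, kind, in/out
#'   channels, level). `dropout_layer_count()`: number of dropout layers.
#'   `n_parameters()`: total trainable parameter count.
#' @export
model_graph <- function(model) model$graph

#' @rdname model_graph
#' @export
dropout_layer_count <- function(model) sum(model$graph$kind == "dropout")

#' @rdname model_graph
#' @export
n_parameters <- function(model) {
  # running batch-norm statistics (rmean/rvar) are buffers, not parameters
  count <- function(x) {
    if (!is.list(x)) return(length(x))
    nm <- names(x)
    keep <- if (is.null(nm)) seq_along(x) else which(!nm %in% c("rmean", "rvar"))
    sum(vapply(x[keep], count, numeric(1)))
  }
  count(model$params)
}

#' @export
print.expanded_unet <- function(x, ...) {
  cat("Expanded U-Net (depth ", x$cfg$depth, ", base ", x$cfg$base_channels,
      " channels, head ", x$cfg$head, ")\n", sep = "")
  cat(" layers: ", nrow(x$graph), " (", dropout_layer_count(x),
      " dropout, rate ", x$cfg$dropout_rate, ")\n", sep = "")
  cat(" input ", paste(x$cfg$input_size, collapse = "x"),
      " -> output ", paste(x$cfg$input_size, collapse = "x"), "x3\n", sep = "")
  invisible(x)
}

#' Write a plain-text architecture summary
#'
#' @param model An `"expanded_unet"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_summary <- function(model, path) {
  g <- model$graph
  lines <- c(sprintf("expanded_unet depth=%d base=%d head=%s dropout=%.2f",
                     model$cfg$depth, model$cfg$base_channels, model$cfg$head,
                     model$cfg$dropout_rate),
             sprintf("%-20s %-12s %4s %4s %5s", "layer", "kind", "in", "out", "level"),
             sprintf("%-20s %-12s %4d %4d %5d", g$name, g$kind, g$c_in, g$c_out, g$level))
  writeLines(lines, path)
  invisible(path)
}

# geometry per batch size, cached on the model by reference
model_geoms <- function(model, B) {
  key <- paste0("B", B)
  if (is.null(model$geom_cache[[key]])) {
    hw <- model$cfg$input_size
    model$geom_cache[[key]] <- lapply(0:model$cfg$depth, function(l)
      nn_geometry(B, hw[1] %/% 2^l, hw[2] %/% 2^l))
  }
  model$geom_cache[[key]]
}

# images -> (B*H*W) x 1 matrix in the engine layout
stack_images <- function(images, hw) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(b) images[, , b])
  for (im in images)
    if (!all(dim(im) == hw))
      stop("image size ", paste(dim(im), collapse = "x"),
           " does not match configured input_size ", paste(hw, collapse = "x"))
  matrix(unlist(images, use.names = FALSE), ncol = 1)
}

# ---- forward / backward ------------------------------------------------

cbact_forward <- function(X, pars, geom, slope, use_bn, training) {
  c1 <- conv3_forward(X, pars$conv1, geom)
  b1 <- if (use_bn) bn_forward(c1$out, pars$bn1, training) else list(out = c1$out)
  a1 <- lrelu_forward(b1$out, slope)
  c2 <- conv3_forward(a1$out, pars$conv2, geom)
  b2 <- if (use_bn) bn_forward(c2$out, pars$bn2, training) else list(out = c2$out)
  a2 <- lrelu_forward(b2$out, slope)
  list(out = a2$out, c1 = c1, b1 = b1, a1 = a1, c2 = c2, b2 = b2, a2 = a2)
}

cbact_backward <- function(dY, cache, pars, geom, slope, use_bn, c_in, c_mid) {
  d <- lrelu_backward(dY, cache$a2, slope)
  if (use_bn) {
    bb <- bn_backward(d, cache$b2, pars$bn2); d <- bb$dX
    g_bn2 <- list(gamma = bb$dgamma, beta = bb$dbeta)
  } else g_bn2 <- NULL
  cb2 <- conv3_backward(d, cache$c2, pars$conv2, geom, c_mid)
  d <- lrelu_backward(cb2$dX, cache$a1, slope)
  if (use_bn) {
    bb <- bn_backward(d, cache$b1, pars$bn1); d <- bb$dX
    g_bn1 <- list(gamma = bb$dgamma, beta = bb$dbeta)
  } else g_bn1 <- NULL
  cb1 <- conv3_backward(d, cache$c1, pars$conv1, geom, c_in)
  list(dX = cb1$dX,
       grads = list(conv1 = list(W = cb1$dW, b = cb1$db), bn1 = g_bn1,
                    conv2 = list(W = cb2$dW, b = cb2$db), bn2 = g_bn2))
}

unet_apply <- function(model, X, B, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  D <- cfg$depth
  geoms <- model_geoms(model, B)
  drop <- dropout_plan(D)
  slope <- cfg$leaky_slope
  bn <- cfg$batch_norm
  cache <- list(enc = vector("list", D), dec = vector("list", D))

  skips <- vector("list", D)
  cur <- X
  for (l in seq_len(D)) {
    cb <- cbact_forward(cur, model$params$enc[[l]], geoms[[l]], slope, bn, training)
    out <- cb$out
    dr <- if (drop$encoder[l]) dropout_forward(out, cfg$dropout_rate, training)
          else list(out = out, mask = NULL)
    skips[[l]] <- dr$out
    pl <- pool_forward(dr$out, geoms[[l]])
    cur <- pl$out
    cache$enc[[l]] <- list(cb = cb, dr = dr, pl = pl)
  }
  cbb <- cbact_forward(cur, model$params$bott, geoms[[D + 1]], slope, bn, training)
  drb <- dropout_forward(cbb$out, cfg$dropout_rate, training)
  cur <- drb$out
  cache$bott <- list(cb = cbb, dr = drb)

  for (l in rev(seq_len(D))) {
    pars <- model$params$dec[[l]]
    up <- upconv_forward(cur, pars$up, geoms[[l]])
    ub <- if (bn) bn_forward(up$out, pars$upbn, training) else list(out = up$out)
    ua <- lrelu_forward(ub$out, slope)
    fused <- cbind(skips[[l]], ua$out)
    dr <- dropout_forward(fused, cfg$dropout_rate, training)
    cb <- cbact_forward(dr$out, pars, geoms[[l]], slope, bn, training)
    cur <- cb$out
    cache$dec[[l]] <- list(up = up, ub = ub, ua = ua, dr = dr, cb = cb)
  }

  hd <- conv1_forward(cur, model$params$head)
  P <- if (cfg$head == "softmax") softmax_rows(hd$out) else sigmoid_rows(hd$out)
  cache$head <- hd
  cache$P <- P
  list(P = P, cache = if (keep_cache) cache else NULL)
}

# Backward pass: dP is the loss gradient w.r.t. the head probabilities.
# Returns a grads structure parallel to model$params, plus updated
# batch-norm running statistics gathered from the forward cache.
unet_backprop <- function(model, cache, dP, B) {
  cfg <- model$cfg
  D <- cfg$depth
  geoms <- model_geoms(model, B)
  slope <- cfg$leaky_slope
  bn <- cfg$batch_norm
  ch <- cfg$base_channels * 2^(0:D)

  dZ <- if (cfg$head == "softmax") softmax_backward(dP, cache$P)
        else sigmoid_backward(dP, cache$P)
  hb <- conv1_backward(dZ, cache$head, model$params$head)
  grads <- list(enc = vector("list", D), dec = vector("list", D),
                head = list(W = hb$dW, b = hb$db))
  d <- hb$dX

  dskips <- vector("list", D)
  for (l in seq_len(D)) {
    cc <- cache$dec[[l]]
    pars <- model$params$dec[[l]]
    bk <- cbact_backward(d, cc$cb, pars, geoms[[l]], slope, bn,
                         c_in = 2 * ch[l], c_mid = ch[l])
    dfused <- dropout_backward(bk$dX, cc$dr)
    dskips[[l]] <- dfused[, seq_len(ch[l]), drop = FALSE]
    dua <- dfused[, ch[l] + seq_len(ch[l]), drop = FALSE]
    dub <- lrelu_backward(dua, cc$ua, slope)
    if (bn) {
      bb <- bn_backward(dub, cc$ub, pars$upbn)
      dup <- bb$dX
      g_upbn <- list(gamma = bb$dgamma, beta = bb$dbeta)
    } else { dup <- dub; g_upbn <- NULL }
    ub2 <- upconv_backward(dup, cc$up, pars$up, geoms[[l]])
    grads$dec[[l]] <- c(list(up = list(W = ub2$dW, b = ub2$db), upbn = g_upbn),
                        bk$grads)
    d <- ub2$dX
  }

  d <- dropout_backward(d, cache$bott$dr)
  bkb <- cbact_backward(d, cache$bott$cb, model$params$bott, geoms[[D + 1]],
                        slope, bn, c_in = ch[D], c_mid = ch[D + 1])
  grads$bott <- bkb$grads
  d <- bkb$dX

  for (l in rev(seq_len(D))) {
    cc <- cache$enc[[l]]
    d <- pool_backward(d, cc$pl, geoms[[l]], geoms[[l]]$n)
    d <- d + dskips[[l]]
    d <- dropout_backward(d, cc$dr)
    bk <- cbact_backward(d, cc$cb, model$params$enc[[l]], geoms[[l]], slope, bn,
                         c_in = if (l == 1) 1L else ch[l - 1], c_mid = ch[l])
    grads$enc[[l]] <- bk$grads
    d <- bk$dX
  }
  grads
}

# collect updated running statistics from a training forward cache into the
# model's batch-norm parameter blocks
bn_commit <- function(model, cache) {
  upd <- function(pars, bncache) {
    if (!is.null(bncache$new_rmean)) {
      pars$rmean <- bncache$new_rmean
      pars$rvar <- bncache$new_rvar
    }
    pars
  }
  D <- model$cfg$depth
  for (l in seq_len(D)) {
    model$params$enc[[l]]$bn1 <- upd(model$params$enc[[l]]$bn1, cache$enc[[l]]$cb$b1)
    model$params$enc[[l]]$bn2 <- upd(model$params$enc[[l]]$bn2, cache$enc[[l]]$cb$b2)
    model$params$dec[[l]]$bn1 <- upd(model$params$dec[[l]]$bn1, cache$dec[[l]]$cb$b1)
    model$params$dec[[l]]$bn2 <- upd(model$params$dec[[l]]$bn2, cache$dec[[l]]$cb$b2)
    model$params$dec[[l]]$upbn <- upd(model$params$dec[[l]]$upbn, cache$dec[[l]]$ub)
  }
  model$params$bott$bn1 <- upd(model$params$bott$bn1, cache$bott$cb$b1)
  model$params$bott$bn2 <- upd(model$params$bott$bn2, cache$bott$cb$b2)
  model
}

#' Run the expanded U-Net forward
#'
#' @param model An `"expanded_unet"`.
#' @param images A single `H x W` matrix, an `H x W x B` array, or a list of
#'   matrices, values in `[0, 1]`; `H`, `W` must equal the configured
#'   `input_size`.
#' @param training Enable dropout and batch-statistics normalization (used
#'   by the training loop); at the default `FALSE`, inference is
#'   deterministic.
#' @return An `H x W x 3` prediction array (single image) or `H x W x 3 x B`
#'   (batch); with the softmax head, per-pixel channel sums are 1.
#' @export
unet_forward <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "expanded_unet"))
  hw <- model$cfg$input_size
  single <- is.matrix(images)
  X <- stack_images(images, hw)
  if (min(X) < 0 || max(X) > 1)
    stop("image values must lie in [0, 1]")
  B <- nrow(X) / prod(hw)
  P <- unet_apply(model, X, B, training = training)$P
  out <- array(P, dim = c(hw[1], hw[2], B, 3))
  out <- aperm(out, c(1, 2, 4, 3))
  if (single) out[, , , 1] else out
}

#' Save / load a model checkpoint
#'
#' Checkpoints are written with R's native serialization and carry the
#' configuration, weights and batch-norm running statistics.
#'
#' @param model An `"expanded_unet"`.
#' @param path Checkpoint file path (conventionally `.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "expanded_unet"))
  slim <- model
  slim$geom_cache <- NULL
  saveRDS(slim, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "expanded_unet"))
    stop("file does not contain an expanded_unet checkpoint: ", path)
  model$geom_cache <- new.env(parent = emptyenv())
  model
}
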