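# Shared fixtures: tiny configurations and masks used across test files.

tiny_unet <- function(head = "softmax", dropout_rate = 0.5, size = c(16, 16),
                      depth = 2, base = 2, seed = 11) {
  set.seed(seed)
  build_expanded_unet(unet_config(depth = depth, base_channels = base,
                                  dropout_rate = dropout_rate, head = head,
                                  input_size = size))
}

random_mask <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:2, h * w, replace = TRUE), h, w)
}

# all 3^(h*w) ordinary masks on an h x w grid
all_masks <- function(h, w) {
  n <- h * w
  grid <- expand.grid(rep(list(0:2), n))
  lapply(seq_len(nrow(grid)), function(i) matrix(as.integer(grid[i, ]), h, w))
}

# numeric central-difference derivative
num_deriv <- function(f, x, eps = 1e-6) (f(x + eps) - f(x - eps)) / (2 * eps)
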