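# Ternary (expanded) cross-entropy loss: per-pixel entropy terms, batch loss
# with gradients, the per-pixel case analysis, and the constrained benign
# optimum under a softmax (sum-to-one) head.

LOSS_EPS <- 1e-7

clip_prob <- function(p, eps = LOSS_EPS) pmin(pmax(p, eps), 1 - eps)

#' Per-pixel information entropy terms of the expanded cross-entropy
#'
#' For one pixel with three-channel target `y` and prediction `p`, computes
#' the two channel sums
#' \deqn{E = \sum_{k=1}^{3} y^{(k)} \log p^{(k)}, \qquad
#'       E' = \sum_{k=1}^{3} (1 - y^{(k)}) \log(1 - p^{(k)}),}
#' with natural logarithms. The per-pixel expanded cross-entropy is
#' `-(E + E')`.
#'
#' @param y Numeric vector of 3 per-channel targets in `{0, 0.5, 1}`.
#' @param p Numeric vector of 3 per-channel predicted probabilities; clipped
#'   into `(eps, 1 - eps)` before the logs.
#' @param eps Clipping constant, `0 < eps < 1e-3`.
#' @return `list(E = ..., Eprime = ...)`.
#' @examples
#' pixel_entropy_terms(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))  # both 3*0.5*log(0.5)
#' @export
pixel_entropy_terms <- function(y, p, eps = LOSS_EPS) {
  if (length(y) != 3 || length(p) != 3)
    stop("y and p must each have exactly 3 channels")
  stopifnot(eps > 0, eps < 1e-3)
  p <- clip_prob(p, eps)
  list(E = sum(y * log(p)), Eprime = sum((1 - y) * log(1 - p)))
}

#' Expanded (ternary) cross-entropy loss
#'
#' The training criterion for grey-level probability labels:
#' \deqn{ECE = -\frac{1}{N} \sum_{i=1}^{N} \overline{\sum_{k=1}^{3}
#'   \left[ y_i^{(k)} \log p_i^{(k)} + (1-y_i^{(k)}) \log(1-p_i^{(k)}) \right]}}
#' where the inner channel sum is averaged over the pixels of batch element
#' `i` (so the loss magnitude is independent of image resolution) and the
#' outer sum over the `N` batch elements is divided by `N`.
#'
#' Because the channel sum runs over all three output channels, the loss —
#' and its gradient — at identical per-channel `(y, p)` is exactly 3 times
#' the single-channel binary cross-entropy, which is what speeds up the
#' update rate of the grey prediction during training.
#'
#' @param targets,preds Matching numeric arrays: `H x W x 3` for a single
#'   image or `H x W x 3 x N` for a batch; `targets` in `{0, 0.5, 1}`,
#'   `preds` in `[0, 1]`.
#' @param eps Clipping constant applied to `preds` before the logarithms.
#' @param reduce `"mean_pixels"` (default; the batch criterion above) or
#'   `"sum_pixels"` (channel sums summed, not averaged, over pixels).
#' @param gradient If `TRUE`, attach the gradient with respect to `preds`
#'   (same shape) as attribute `"gradient"`.
#' @return Scalar loss (non-negative for valid inputs).
#' @seealso [per_pixel_case_loss()] for the single-channel case analysis,
#'   [binary_cross_entropy()] for the one-channel baseline.
#' @export
expanded_cross_entropy <- function(targets, preds, eps = LOSS_EPS,
                                   reduce = c("mean_pixels", "sum_pixels"),
                                   gradient = FALSE) {
  reduce <- match.arg(reduce)
  if (!identical(dim(targets), dim(preds)))
    stop("targets and preds must have identical dimensions")
  if (anyNA(targets) || anyNA(preds)) stop("NaN/NA in loss inputs")
  d <- dim(targets)
  if (is.null(d) || !(length(d) %in% c(3, 4)) || d[3] != 3)
    stop("expected H x W x 3 (single image) or H x W x 3 x N (batch) arrays")
  n_batch <- if (length(d) == 4) d[4] else 1L
  n_pix <- if (reduce == "mean_pixels") prod(d[1:2]) else 1L

  p <- clip_prob(preds, eps)
  loss <- -sum(targets * log(p) + (1 - targets) * log(1 - p)) / (n_batch * n_pix)
  if (gradient) {
    g <- (-targets / p + (1 - targets) / (1 - p)) / (n_batch * n_pix)
    g[preds < eps | preds > 1 - eps] <- 0   # clipped region: flat
    attr(loss, "gradient") <- g
  }
  loss
}

#' Single-channel binary cross-entropy
#'
#' The ordinary one-channel criterion `-y log p - (1 - y) log(1 - p)`, used
#' as the comparison baseline for the expanded loss's update-rate property.
#'
#' @param y Target value(s) in `[0, 1]`.
#' @param p Predicted probability(ies); clipped into `(eps, 1 - eps)`.
#' @param eps Clipping constant.
#' @param gradient If `TRUE`, attach `d loss / d p` as attribute
#'   `"gradient"` (mean over elements, matching the loss reduction).
#' @return Mean binary cross-entropy over the supplied elements.
#' @export
binary_cross_entropy <- function(y, p, eps = LOSS_EPS, gradient = FALSE) {
  pc <- clip_prob(p, eps)
  loss <- mean(-y * log(pc) - (1 - y) * log(1 - pc))
  if (gradient) {
    g <- (-y / pc + (1 - y) / (1 - pc)) / length(pc)
    g[p < eps | p > 1 - eps] <- 0
    attr(loss, "gradient") <- g
  }
  loss
}

#' Per-pixel, per-channel loss case analysis
#'
#' For one channel with grey-level probability target `y` the loss
#' `-y log p - (1 - y) log(1 - p)` specializes to three cases:
#' * `y = 1` (malignant): `loss = -log p`, minimized as `p -> 1`;
#' * `y = 0.5` (benign): `loss = -0.5 log[p (1 - p)]`, minimized at
#'   `p = 0.5` with minimum `-0.5 log(1/4) = log 2`;
#' * `y = 0` (normal): `loss = -log(1 - p)`, minimized as `p -> 0`.
#'
#' The case form and the direct evaluation of the general formula agree to
#' machine precision; the benign case is symmetric under `p <-> 1 - p`.
#'
#' @param y_value One of `0`, `0.5`, `1`.
#' @param p Predicted probability (vectorized), in `(0, 1)`.
#' @return Loss value(s), same length as `p`.
#' @examples
#' per_pixel_case_loss(0.5, 0.5)   # log(2) ~= 0.6931
#' @export
per_pixel_case_loss <- function(y_value, p) {
  if (!(length(y_value) == 1 && y_value %in% c(0, 0.5, 1)))
    stop("y_value must be one of 0, 0.5, 1")
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly inside (0, 1)")
  if (y_value == 1) -log(p)
  else if (y_value == 0) -log(1 - p)
  else -0.5 * log(p * (1 - p))
}

#' Minimize the three-channel benign loss under a softmax head
#'
#' With a softmax output head the three per-pixel channel probabilities are
#' constrained to sum to one. For a benign pixel (target 0.5 on every
#' channel) the reachable optimum is found by minimizing
#' `sum_k [-0.5 log p_k - 0.5 log(1 - p_k)]` subject to
#' `p_1 + p_2 + p_3 = 1`. The objective is strictly convex on the open
#' simplex (each term has second derivative `0.5/p^2 + 0.5/(1-p)^2 > 0`), so
#' the optimum is unique; numeric constrained optimization recovers it.
#'
#' The resulting per-channel optimum converts to an output grey level of
#' `mean(p) * 255` and to a grey reduction rate `alpha = grey / 127.5`
#' relative to the benign ground-truth grey 127.5 — the mechanism behind the
#' benign output band around grey 85 and `alpha ~ 2/3`.
#'
#' @param eps Numerical safety margin keeping the optimizer inside the open
#'   simplex.
#' @param tol Convergence tolerance passed to the optimizer.
#' @return A list with `p` (the per-channel optimum), `grey`
#'   (`mean(p) * 255`), `alpha` (`grey / 127.5`), `value` (the minimized
#'   three-channel loss) and `convergence` (0 for success).
#' @examples
#' constrained_benign_minimum()$alpha   # ~ 0.667
#' @export
constrained_benign_minimum <- function(eps = LOSS_EPS, tol = 1e-14) {
  # softmax reparametrization p = softmax(z1, z2, 0) keeps the iterate on
  # the open simplex, so the sum-to-one constraint is intrinsic
  to_simplex <- function(z) {
    e <- exp(c(z, 0) - max(z, 0))
    e / sum(e)
  }
  obj <- function(z) sum(per_pixel_case_loss(0.5, clip_prob(to_simplex(z), eps)))
  fit <- stats::optim(c(0.4, -0.3), obj, method = "BFGS",
                      control = list(reltol = tol, maxit = 500))
  if (fit$convergence != 0)
    stop("constrained optimization did not converge: code ", fit$convergence,
         " (", fit$message, ")")
  p <- to_simplex(fit$par)
  grey <- mean(p) * 255
  list(p = p, grey = grey, alpha = grey / 127.5, value = fit$value,
       convergence = fit$convergence)
}
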