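# Synthetic ultrasound-like phantoms: hypoechoic lesions on a multiplicative
# speckle background, with benign (smooth ellipse, blurred boundary) and
# malignant (irregular radial polygon with internal bright spots)
# morphologies, plus paired geometric augmentation.

#' Configuration of the phantom generator
#'
#' The generator emulates B-mode appearance at desk scale: a mid-grey
#' background carrying spatially correlated multiplicative speckle, and one
#' hypoechoic lesion per image. Defaults follow the intended training
#' conditions: 64 images of 64 x 64 pixels with a strong benign majority
#' (benign fraction 0.885, the clinical 177:23 class ratio).
#'
#' @param image_size `c(H, W)` in pixels; keep divisible by `2^depth` of the
#'   paired network configuration.
#' @param n_images Number of image/mask pairs.
#' @param benign_fraction Proportion of lesions that are benign.
#' @param speckle_strength Scale of the multiplicative speckle noise.
#' @param lesion_size_range Lesion radius range in pixels.
#' @param seed Base random seed; image `i` uses `seed + i`.
#' @return A validated list of class `"phantom_config"`.
#' @export
phantom_config <- function(image_size = c(64L, 64L), n_images = 64L,
                           benign_fraction = 177 / 200,
                           speckle_strength = 0.15,
                           lesion_size_range = c(8, 16), seed = 20260101L) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            n_images >= 1, benign_fraction >= 0, benign_fraction <= 1,
            speckle_strength >= 0, length(lesion_size_range) == 2,
            lesion_size_range[1] > 0,
            lesion_size_range[2] >= lesion_size_range[1])
  if (2 * lesion_size_range[2] >= min(image_size))
    stop("lesion diameter ", 2 * lesion_size_range[2],
         " exceeds image size ", min(image_size))
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 benign_fraction = benign_fraction,
                 speckle_strength = speckle_strength,
                 lesion_size_range = lesion_size_range,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# separable 1-2-1 blur with edge replication, `passes` times
blur121 <- function(m, passes = 1) {
  for (i in seq_len(passes)) {
    p <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    m <- (p[1:nrow(m), , drop = FALSE] + 2 * p[2:(nrow(m) + 1), , drop = FALSE] +
            p[3:(nrow(m) + 2), , drop = FALSE]) / 4
    p <- cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
    m <- (p[, 1:ncol(m), drop = FALSE] + 2 * p[, 2:(ncol(m) + 1), drop = FALSE] +
            p[, 3:(ncol(m) + 2), drop = FALSE]) / 4
  }
  m
}

speckle_field <- function(H, W, strength) {
  z <- blur121(matrix(stats::rnorm(H * W), H, W), passes = 1)
  z <- z / stats::sd(z)
  1 + strength * z
}

#' Generate one synthetic phantom
#'
#' @param cfg A [phantom_config()].
#' @param class `"benign"` or `"malignant"`; default drawn with probability
#'   `benign_fraction`.
#' @param seed Seed for this image (overrides the RNG state).
#' @return `list(image = H x W matrix in [0,1], mask = ordinary label
#'   matrix, class = lesion class)`; every nonzero label lies inside the
#'   rendered lesion footprint, and the lesion interior is darker than the
#'   background (hypoechoic).
#' @examples
#' ph <- generate_phantom(phantom_config(), seed = 7)
#' mean(ph$image[ph$mask > 0]) < mean(ph$image[ph$mask == 0])
#' @export
generate_phantom <- function(cfg = phantom_config(), class = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  if (is.null(class))
    class <- if (stats::runif(1) < cfg$benign_fraction) "benign" else "malignant"

  img <- 0.45 * speckle_field(H, W, cfg$speckle_strength)

  rmax <- cfg$lesion_size_range[2]
  margin <- ceiling(rmax) + 2
  cy <- stats::runif(1, margin, H - margin)
  cx <- stats::runif(1, margin, W - margin)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx

  if (class == "benign") {
    a <- stats::runif(1, cfg$lesion_size_range[1], rmax)
    b <- stats::runif(1, cfg$lesion_size_range[1], rmax)
    phi <- stats::runif(1, 0, pi)
    u <- cos(phi) * xx + sin(phi) * yy
    v <- -sin(phi) * xx + cos(phi) * yy
    inside <- (u / a)^2 + (v / b)^2 <= 1
    label_value <- 1L
  } else {
    r0 <- stats::runif(1, cfg$lesion_size_range[1], rmax)
    modes <- 2:5
    amp <- stats::runif(length(modes), 0.03, 0.12)
    pha <- stats::runif(length(modes), 0, 2 * pi)
    theta <- atan2(yy, xx)
    rboundary <- r0 * (1 + Reduce(`+`, Map(function(m, a, p)
      a * cos(m * theta + p), modes, amp, pha)))
    inside <- sqrt(xx^2 + yy^2) <= rboundary
    label_value <- 2L
  }

  # hypoechoic core with a blurred boundary
  atten <- blur121(inside * 1, passes = 2)
  img <- img * (1 - 0.55 * atten)

  if (class == "malignant") {
    # small echogenic (bright) internal spots
    n_spots <- sample(2:4, 1)
    r0in <- max(cfg$lesion_size_range[1] * 0.4, 2)
    for (s in seq_len(n_spots)) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, r0in)
      sy <- cy + rad * sin(ang); sx <- cx + rad * cos(ang)
      rs <- stats::runif(1, 1, 2.2)
      spot <- exp(-(((matrix(seq_len(H), H, W) - sy)^2 +
                       (matrix(seq_len(W), H, W, byrow = TRUE) - sx)^2) / (2 * rs^2)))
      img <- img + 0.5 * spot * inside
    }
  }

  mask <- matrix(0L, H, W)
  mask[inside] <- label_value
  list(image = pmin(pmax(img, 0), 1), mask = mask, class = class)
}

#' Generate a phantom dataset on disk
#'
#' Writes paired 8-bit PNGs (`img_0001.png`, `msk_0001.png`, ...) and a
#' tab-delimited `manifest.tsv` (filename pair, lesion class, per-image
#' seed). Classes are drawn per image with probability `benign_fraction`.
#'
#' @param cfg A [phantom_config()].
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
generate_phantom_dataset <- function(cfg = phantom_config(), dir) {
  stopifnot(inherits(cfg, "phantom_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(cfg$n_images), function(i) {
    ph <- generate_phantom(cfg, seed = cfg$seed + i)
    img_file <- sprintf("img_%04d.png", i)
    msk_file <- sprintf("msk_%04d.png", i)
    write_image_png(ph$image, file.path(dir, img_file))
    write_mask_png(ph$mask, file.path(dir, msk_file))
    data.frame(image = img_file, mask = msk_file, class = ph$class,
               seed = cfg$seed + i)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Geometric augmentation of a paired image and mask
#'
#' Applies one randomly sampled combination of horizontal/vertical flip,
#' rotation (+/- 15 degrees), translation (+/- 10% per axis) and zoom
#' (0.9-1.1) — the same geometric transform to image and mask. The image is
#' resampled bilinearly; the mask with nearest-neighbour interpolation, so
#' labels stay in `{0,1,2}`. Coordinates outside the frame are edge-clamped.
#'
#' @param image `H x W` matrix in `[0, 1]`.
#' @param mask Ordinary label matrix, same size.
#' @param seed Optional seed for the sampled transform.
#' @param params Optional explicit transform, a list with `hflip`, `vflip`
#'   (logical), `angle` (degrees), `translate` (`c(dy, dx)` in pixels) and
#'   `zoom`; overrides sampling. `identity_transform()` gives the identity.
#' @return `list(image, mask, params)`.
#' @examples
#' ph <- generate_phantom(seed = 3)
#' aug <- augment(ph$image, ph$mask, seed = 4)
#' all(aug$mask %in% c(0, 1, 2))
#' @export
augment <- function(image, mask, seed = NULL, params = NULL) {
  if (!identical(dim(image), dim(mask))) stop("image/mask dimensions differ")
  validate_ordinary_mask(mask)
  if (is.null(params)) {
    if (!is.null(seed)) set.seed(seed)
    H <- nrow(image); W <- ncol(image)
    params <- list(hflip = stats::runif(1) < 0.5,
                   vflip = stats::runif(1) < 0.5,
                   angle = stats::runif(1, -15, 15),
                   translate = c(stats::runif(1, -0.1, 0.1) * H,
                                 stats::runif(1, -0.1, 0.1) * W),
                   zoom = stats::runif(1, 0.9, 1.1))
  }
  list(image = warp_affine(image, params, interp = "bilinear"),
       mask = warp_affine(mask, params, interp = "nearest"),
       params = params)
}

#' @rdname augment
#' @export
identity_transform <- function() {
  list(hflip = FALSE, vflip = FALSE, angle = 0, translate = c(0, 0), zoom = 1)
}

# inverse-map each output pixel to its source location and resample;
# forward transform order: flip -> rotate -> zoom -> translate (about the
# image centre)
warp_affine <- function(m, params, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  v <- matrix(seq_len(H), H, W) - cy          # down
  u <- matrix(seq_len(W), H, W, byrow = TRUE) - cx  # right
  u <- u - params$translate[2]; v <- v - params$translate[1]
  u <- u / params$zoom; v <- v / params$zoom
  th <- -params$angle * pi / 180
  us <- cos(th) * u - sin(th) * v
  vs <- sin(th) * u + cos(th) * v
  if (params$hflip) us <- -us
  if (params$vflip) vs <- -vs
  sx <- us + cx; sy <- vs + cy
  clamp <- function(z, lo, hi) pmin(pmax(z, lo), hi)
  if (interp == "nearest") {
    iy <- clamp(round(sy), 1, H); ix <- clamp(round(sx), 1, W)
    out <- m[cbind(c(iy), c(ix))]
  } else {
    y0 <- clamp(floor(sy), 1, H); x0 <- clamp(floor(sx), 1, W)
    y1 <- clamp(y0 + 1, 1, H); x1 <- clamp(x0 + 1, 1, W)
    wy <- clamp(sy - y0, 0, 1); wx <- clamp(sx - x0, 0, 1)
    f00 <- m[cbind(c(y0), c(x0))]; f10 <- m[cbind(c(y1), c(x0))]
    f01 <- m[cbind(c(y0), c(x1))]; f11 <- m[cbind(c(y1), c(x1))]
    out <- (1 - wy) * (1 - wx) * f00 + wy * (1 - wx) * f10 +
      (1 - wy) * wx * f01 + wy * wx * f11
  }
  matrix(out, H, W)
}
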