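# Grey-mass Dice/IOU evaluation of greyscale output maps, per-class grey
# bands, grey histograms, and the classical set-overlap coefficients.

#' Per-class grey models for grey-mass evaluation
#'
#' The grey-mass metrics compare the total grey value of a tumour class in
#' the ground truth against the grey value accumulated inside a per-class
#' grey band of the output map. Each class carries:
#' * `alpha` — the grey reduction rate, the expected ratio of output grey to
#'   ground-truth grey (benign ~ 0.667 because the softmax-constrained
#'   optimum sits at grey 85 against ground truth 127.5; malignant 1);
#' * `delta` — the per-pixel grey tolerance (benign 5, malignant 85);
#' * `band` — the accepted grey interval of predicted tumour pixels,
#'   generated by `alpha` and `delta`: benign `85 +/- 5 = (80, 90)`,
#'   malignant `255 - 85 = (170, 255)`.
#'
#' @param class_id `"benign"` or `"malignant"`.
#' @param alpha,delta,band Override the defaults above; `band` is
#'   `c(low, high)` within `[0, 255]`, interpreted as `(low, high]`.
#' @return A list of class `"class_grey_model"`.
#' @examples
#' class_grey_model("benign")$band      # (80, 90)
#' class_grey_model("malignant")$alpha  # 1
#' @export
class_grey_model <- function(class_id = c("benign", "malignant"),
                             alpha = NULL, delta = NULL, band = NULL) {
  class_id <- match.arg(class_id)
  defaults <- list(
    benign    = list(alpha = 85 / 127.5, delta = 5, band = c(80, 90),
                     label = 1L, truth_grey = 127.5),
    malignant = list(alpha = 1, delta = 85, band = c(170, 255),
                     label = 2L, truth_grey = 255)
  )[[class_id]]
  m <- list(class_id = class_id,
            alpha = if (is.null(alpha)) defaults$alpha else alpha,
            delta = if (is.null(delta)) defaults$delta else delta,
            band = if (is.null(band)) defaults$band else band,
            label = defaults$label, truth_grey = defaults$truth_grey)
  stopifnot(m$alpha > 0, m$alpha <= 1, m$delta > 0,
            length(m$band) == 2, m$band[1] >= 0, m$band[2] <= 255,
            m$band[1] < m$band[2])
  structure(m, class = "class_grey_model")
}

#' Grey histogram of an output map
#'
#' @param map Numeric matrix of grey values in `[0, 255]`.
#' @return Integer vector of 256 bin counts (bin `g` counts pixels with
#'   `floor(grey) == g`, 255 inclusive); counts sum to the pixel count.
#' @export
grey_histogram <- function(map) {
  if (length(map) == 0) stop("empty image: grey histogram is undefined")
  if (any(map < 0) || any(map > 255))
    stop("grey values must lie in [0, 255]; range found: [",
         format(min(map)), ", ", format(max(map)), "]")
  bins <- pmin(floor(map), 255)
  tabulate(bins + 1L, nbins = 256L)
}

#' Extract the predicted tumour region of one class from a grey map
#'
#' Selects the pixels whose grey value falls in the class's grey band
#' (`(low, high]`) and accumulates their grey mass.
#'
#' @param map Numeric matrix of grey values in `[0, 255]`.
#' @param model A [class_grey_model()].
#' @return `list(mask = logical matrix, x_p = summed grey over the mask)`.
#' @examples
#' img <- matrix(0, 10, 10); img[3:4, 3:7] <- 85
#' extract_class_region(img, class_grey_model("benign"))$x_p   # 850
#' @export
extract_class_region <- function(map, model) {
  stopifnot(inherits(model, "class_grey_model"))
  if (any(map < 0) || any(map > 255)) stop("grey values must lie in [0, 255]")
  mask <- map > model$band[1] & map <= model$band[2]
  list(mask = mask, x_p = sum(map[mask]))
}

grey_mass_scores <- function(a, b) {
  # scalar-mass analogue of the set-overlap coefficients:
  # dice = 2 min / (a + b), iou = min / max; preserves dice = 2 iou/(1+iou)
  if (a == 0 && b == 0) return(c(dice = 1, iou = 1))
  m <- min(a, b); M <- max(a, b)
  c(dice = 2 * m / (a + b), iou = m / M)
}

#' Grey-mass Dice and IOU of one class on one image
#'
#' Computes the ground-truth grey mass `x_t` of the class region (Table-
#' encoded grey: 127.5 for benign, 255 for malignant), the predicted grey
#' mass `x_p` inside the class's grey band of the output map, their
#' difference `delta_x = alpha * x_t - x_p`, and the grey-mass overlap
#' coefficients
#' \deqn{Dice = \frac{2\,\min(\alpha x_t, x_p)}{\alpha x_t + x_p}, \qquad
#'       IOU = \frac{\min(\alpha x_t, x_p)}{\max(\alpha x_t, x_p)}.}
#' `within_tolerance` flags whether the per-pixel mean deviation
#' `delta_x / n_t` (with `n_t` the true region's pixel count) lies in
#' `[-delta, delta]` for benign or `[0, delta]` for malignant.
#'
#' @param truth_mask Ordinary class mask (`{0,1,2}` matrix).
#' @param pred_map Numeric matrix of predicted grey values in `[0, 255]`,
#'   same dimensions.
#' @param model A [class_grey_model()].
#' @return A one-row data frame (class, `x_t`, `x_p`, `delta_x`, `dice`,
#'   `iou`, `within_tolerance`).
#' @examples
#' truth <- matrix(0, 8, 8); truth[3:5, 3:5] <- 2
#' pred <- ordinary_to_grey_map(truth)
#' grey_dice_iou(truth, pred, class_grey_model("malignant"))
#' @export
grey_dice_iou <- function(truth_mask, pred_map, model) {
  stopifnot(inherits(model, "class_grey_model"))
  validate_ordinary_mask(truth_mask)
  if (!identical(dim(truth_mask), dim(pred_map)))
    stop("truth and prediction dimensions differ")
  n_t <- sum(truth_mask == model$label)
  x_t <- n_t * model$truth_grey
  x_p <- extract_class_region(pred_map, model)$x_p
  a <- model$alpha * x_t
  if (x_t == 0) {
    warning("no ", model$class_id, " tumour in ground truth; degenerate scores")
    s <- if (x_p == 0) c(dice = 1, iou = 1) else c(dice = 0, iou = 0)
  } else {
    s <- grey_mass_scores(a, x_p)
  }
  delta_x <- a - x_p
  wt <- if (n_t == 0) NA else {
    dbar <- delta_x / n_t
    if (model$class_id == "malignant") dbar >= 0 && dbar <= model$delta
    else abs(dbar) <= model$delta
  }
  data.frame(class = model$class_id, x_t = x_t, x_p = x_p, delta_x = delta_x,
             dice = unname(s["dice"]), iou = unname(s["iou"]),
             within_tolerance = wt)
}

#' Render the expected output grey map of a mask
#'
#' The grey map an ideally trained network would emit: each class region at
#' its grey-reduced level `alpha * truth_grey` — benign at
#' `0.667 * 127.5 = 85`, malignant at `255`, background 0. Useful as a
#' perfect-prediction reference when exercising the evaluation pipeline
#' (scoring it against its own mask gives Dice = IOU = 1 by construction).
#'
#' @param mask Ordinary class mask (`{0,1,2}` matrix).
#' @return Numeric matrix of grey values in `[0, 255]`.
#' @export
render_expected_output <- function(mask) {
  validate_ordinary_mask(mask)
  b <- class_grey_model("benign"); m <- class_grey_model("malignant")
  grey <- c(0, b$alpha * b$truth_grey, m$alpha * m$truth_grey)
  matrix(grey[mask + 1L], nrow(mask), ncol(mask))
}

#' Classical set-overlap Dice and IOU
#'
#' @param truth_mask,pred_mask Logical (or 0/1) matrices of equal size.
#' @return `c(dice = ..., iou = ...)`; two empty masks score 1 with a
#'   warning.
#' @export
classical_dice_iou <- function(truth_mask, pred_mask) {
  if (!identical(dim(truth_mask), dim(pred_mask)))
    stop("mask dimensions differ")
  a <- as.logical(truth_mask); b <- as.logical(pred_mask)
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  if (na == 0 && nb == 0) {
    warning("both masks empty; overlap coefficients defined as 1")
    return(c(dice = 1, iou = 1))
  }
  c(dice = 2 * ni / (na + nb), iou = ni / (na + nb - ni))
}

#' Grey-overlap report for one image over the classes it contains
#'
#' @param truth_mask Ordinary class mask.
#' @param pred_map Predicted grey map in `[0, 255]`.
#' @param classes Classes to score; default: those present in the truth.
#' @return Data frame with one [grey_dice_iou()] row per class.
#' @export
grey_overlap_report <- function(truth_mask, pred_map,
                                classes = NULL) {
  if (is.null(classes)) {
    classes <- c("benign", "malignant")[c(any(truth_mask == 1), any(truth_mask == 2))]
    if (length(classes) == 0)
      stop("ground truth contains no tumour; specify classes explicitly")
  }
  do.call(rbind, lapply(classes, function(cl)
    grey_dice_iou(truth_mask, pred_map, class_grey_model(cl))))
}

#' Summarize a grey-overlap evaluation across images
#'
#' Aggregates per-image, per-class rows into the layout of a quantitative
#' results table: Dice and IOU as percentages with per-class and overall
#' mean and standard deviation.
#'
#' @param report Data frame of [grey_dice_iou()] rows, with an `image`
#'   column identifying the image.
#' @return List with `per_image` (Dice/IOU in percent per row) and
#'   `summary` (mean and sd of Dice% and IOU% per class and overall).
#' @export
summarize_grey_report <- function(report) {
  per_image <- report
  per_image$dice_pct <- 100 * report$dice
  per_image$iou_pct <- 100 * report$iou
  one <- function(rows, label) data.frame(
    class = label, n = nrow(rows),
    dice_pct_mean = mean(rows$dice_pct), dice_pct_sd = stats::sd(rows$dice_pct),
    iou_pct_mean = mean(rows$iou_pct), iou_pct_sd = stats::sd(rows$iou_pct))
  parts <- lapply(split(per_image, per_image$class), function(r) one(r, r$class[1]))
  summary <- rbind(do.call(rbind, parts), one(per_image, "overall"))
  rownames(summary) <- NULL
  list(per_image = per_image, summary = summary)
}

#' Write an evaluation report as delimited text
#'
#' @param report Per-image data frame (see [summarize_grey_report()]).
#' @param path Output TSV path; a `.summary.tsv` companion is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_grey_report <- function(report, path) {
  s <- summarize_grey_report(report)
  utils::write.table(s$per_image, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(s$summary, sub("\\.tsv$", "", path, ignore.case = TRUE) %+% ".summary.tsv",
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
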