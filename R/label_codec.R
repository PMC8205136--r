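# Conversions between ordinary class masks, grey label maps, and grey-level
# probability labels, plus PNG I/O for paired image/mask datasets.

#' Grey values and probability targets of the three tissue classes
#'
#' The three-class label encoding used throughout the package: ordinary
#' integer labels 0/1/2 (normal tissue / benign tumour / malignant tumour)
#' correspond to three-channel grey values (0, 127.5, 255) and, after
#' normalization by 255, to grey-level probability targets (0, 0.5, 1).
#' All three channels of a pixel carry the same value.
#'
#' @return A data frame with one row per class: `class_id`, `class_name`,
#'   `grey` (the 8-bit-scale grey value) and `probability` (`grey / 255`).
#' @examples
#' label_table()
#' @export
label_table <- function() {
  data.frame(
    class_id    = c(0L, 1L, 2L),
    class_name  = c("normal", "benign", "malignant"),
    grey        = c(0, 127.5, 255),
    probability = c(0, 0.5, 1)
  )
}

CLASS_PROB <- c(0, 0.5, 1)   # indexed by class_id + 1
CLASS_GREY <- c(0, 127.5, 255)

#' Validate an ordinary label mask
#'
#' @param mask Integer-valued matrix with entries in `{0, 1, 2}`.
#' @return The mask, invisibly, after validation.
#' @keywords internal
validate_ordinary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a 2-D matrix")
  bad <- which(matrix(!(mask %in% c(0, 1, 2)), nrow(mask)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    stop(sprintf(
      "invalid class value %s at pixel (row %d, col %d); ordinary labels must be 0, 1 or 2 (%d offending pixel%s)",
      format(mask[i[1], i[2]]), i[1], i[2], nrow(bad), if (nrow(bad) > 1) "s" else ""
    ))
  }
  invisible(mask)
}

#' Convert an ordinary class mask to a grey-level probability label map
#'
#' Encodes the per-pixel class IDs as soft three-channel targets: normal
#' tissue (class 0) maps to (0,0,0), benign tumour (class 1) to
#' (0.5,0.5,0.5) and malignant tumour (class 2) to (1,1,1). The values are
#' the three-channel grey levels 0 / 127.5 / 255 normalized by 255, so 0.5
#' is exact.
#'
#' @param mask Matrix of class IDs in `{0,1,2}` (normal/benign/malignant).
#' @return A numeric `H x W x 3` array with values in `{0, 0.5, 1}`; every
#'   channel of a pixel is equal.
#' @examples
#' m <- matrix(c(0, 1, 2, 1), 2, 2)
#' ordinary_to_grey_probability(m)[1, 2, ]   # class 2 -> (1, 1, 1)
#' @seealso [grey_probability_to_ordinary()] for the inverse,
#'   [ordinary_to_grey_map()] for the 8-bit-scale grey rendering.
#' @export
ordinary_to_grey_probability <- function(mask) {
  validate_ordinary_mask(mask)
  probs <- CLASS_PROB[mask + 1L]
  array(probs, dim = c(nrow(mask), ncol(mask), 3L))
}

#' Convert a grey-level probability label map back to an ordinary mask
#'
#' Exact inverse of [ordinary_to_grey_probability()]: (0,0,0) -> 0,
#' (0.5,0.5,0.5) -> 1, (1,1,1) -> 2. Inputs that are not valid label maps
#' (channel values outside `{0, 0.5, 1}`, or unequal channels) are rejected.
#'
#' @param label `H x W x 3` array with per-pixel channel values in
#'   `{0, 0.5, 1}` and all three channels equal.
#' @return Matrix of class IDs in `{0,1,2}`.
#' @export
grey_probability_to_ordinary <- function(label) {
  if (length(dim(label)) != 3 || dim(label)[3] != 3)
    stop("label must be an H x W x 3 array")
  if (!all(label %in% c(0, 0.5, 1)))
    stop("grey-level probability values must be 0, 0.5 or 1; found ",
         paste(utils::head(setdiff(unique(c(label)), c(0, 0.5, 1)), 3), collapse = ", "))
  if (any(label[, , 1] != label[, , 2]) || any(label[, , 1] != label[, , 3]))
    stop("all three channels of a grey-level probability label must be equal")
  matrix(match(label[, , 1], CLASS_PROB) - 1L,
         nrow = dim(label)[1], ncol = dim(label)[2])
}

#' Render an ordinary mask as a grey label map
#'
#' Ground-truth rendering on the 8-bit grey scale: class 0 -> grey 0,
#' class 1 -> grey 127.5, class 2 -> grey 255. This is the single-channel
#' view of the three-channel grey label (all channels are equal); it is what
#' the grey-mass metrics integrate over the true tumour region.
#'
#' @param mask Matrix of class IDs in `{0,1,2}`.
#' @return Numeric matrix of grey values in `{0, 127.5, 255}`.
#' @export
ordinary_to_grey_map <- function(mask) {
  validate_ordinary_mask(mask)
  matrix(CLASS_GREY[mask + 1L], nrow(mask), ncol(mask))
}

#' Collapse a 3-channel prediction map to a displayable grey map
#'
#' The network head emits three per-pixel probabilities; the displayed (and
#' evaluated) grey map is the channel mean scaled to the 8-bit range:
#' `grey = mean(p) * 255`. Under equal channels this is the only convention
#' consistent with the observed benign output band around grey 85
#' (mean(1/3) * 255 = 85).
#'
#' @param pred `H x W x 3` array of per-channel probabilities in `[0,1]`.
#' @return Numeric matrix of grey values in `[0, 255]`.
#' @examples
#' p <- array(1 / 3, dim = c(2, 2, 3))
#' prediction_to_grey_map(p)   # all 85
#' @export
prediction_to_grey_map <- function(pred) {
  if (length(dim(pred)) != 3 || dim(pred)[3] != 3)
    stop("pred must be an H x W x 3 array")
  if (any(pred < 0) || any(pred > 1))
    stop("prediction channels must lie in [0, 1]; range found: [",
         format(min(pred)), ", ", format(max(pred)), "]")
  matrix((pred[, , 1] + pred[, , 2] + pred[, , 3]) / 3 * 255,
         dim(pred)[1], dim(pred)[2])
}

# ---- PNG I/O -----------------------------------------------------------

#' Read / write 8-bit greyscale images and class masks as PNG
#'
#' Images are stored as standard 8-bit single-channel PNGs and returned as
#' matrices in `[0, 1]`. Masks store the ordinary labels `{0,1,2}` directly
#' in the 8-bit values; `remap = TRUE` additionally accepts the visual
#' convention `{0, 128, 255}` and remaps it to `{0, 1, 2}`.
#'
#' @param path File path.
#' @param remap For `read_mask_png()`: accept `{0,128,255}`-coded masks.
#' @param image Numeric matrix in `[0,1]` (for `write_image_png()`) or in
#'   `[0,255]` (for `write_grey_png()`, e.g. a grey output map).
#' @param mask Integer-valued matrix in `{0,1,2}`.
#' @return Readers return a numeric matrix; writers return `path` invisibly.
#' @name mask_png
NULL

#' @rdname mask_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]   # collapse grey stored as RGB(A)
  img
}

#' @rdname mask_png
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname mask_png
#' @export
write_grey_png <- function(image, path) {
  write_image_png(image / 255, path)
}

#' @rdname mask_png
#' @export
read_mask_png <- function(path, remap = FALSE) {
  raw <- round(read_image_png(path) * 255)
  if (remap) {
    if (!all(raw %in% c(0, 128, 255)))
      stop("remap = TRUE expects mask values {0, 128, 255}; found ",
           paste(utils::head(setdiff(unique(c(raw)), c(0, 128, 255)), 3), collapse = ", "))
    raw <- matrix(match(raw, c(0, 128, 255)) - 1, nrow(raw), ncol(raw))
  }
  validate_ordinary_mask(raw)
  raw
}

#' @rdname mask_png
#' @export
write_mask_png <- function(mask, path) {
  validate_ordinary_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}
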