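#' Patch-level classification metrics
#'
#' Accuracy, support-weighted F1, sensitivity (recall of the cancer class)
#' and AU-ROC. AU-ROC uses the rank (Mann-Whitney) statistic with midrank
#' tie correction and is therefore invariant to any strictly monotone
#' transform of the scores. With a single-class label vector AU-ROC is
#' undefined and returned as `NA` with a warning.
#'
#' @param labels true binary labels (0 = normal, 1 = cancer, or
#'   `"normal"`/`"cancer"` strings).
#' @param predicted predicted labels, same coding.
#' @param scores cancer-class scores (higher = more cancer-like); optional,
#'   AU-ROC is `NA` when absent.
#' @return list with `accuracy`, `weighted_f1`, `per_class_f1`,
#'   `sensitivity`, `auroc`.
#' @export
classification_metrics <- function(labels, predicted, scores = NULL) {
  y <- label_index(labels) - 1L
  p <- label_index(predicted) - 1L
  stopifnot(length(y) == length(p), all(y %in% 0:1), all(p %in% 0:1))
  acc <- mean(y == p)
  f1_of <- function(cls) {
    tp <- sum(y == cls & p == cls)
    fp <- sum(y != cls & p == cls)
    fn <- sum(y == cls & p != cls)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }
  f1 <- c(normal = f1_of(0), cancer = f1_of(1))
  support <- c(sum(y == 0), sum(y == 1))
  wf1 <- sum(ifelse(is.na(f1), 0, f1) * support) / length(y)
  sens <- if (sum(y == 1) == 0) NA_real_ else
    sum(y == 1 & p == 1) / sum(y == 1)
  auroc <- NA_real_
  if (!is.null(scores)) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) {
      warning("AU-ROC undefined for a single-class label vector")
    } else {
      r <- rank(scores, ties.method = "average")
      auroc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(accuracy = acc, weighted_f1 = wf1, per_class_f1 = f1,
       sensitivity = sens, auroc = auroc)
}

#' Patch-grid binary slide mask
#'
#' A whole-slide margin map at patch-grid resolution. The default cell
#' pitch is 0.139 mm: 250 px tiles at 0.556 um/pixel.
#'
#' @param grid binary (0/1) matrix, rows = grid rows.
#' @param cell_pitch_mm physical size of one grid cell in mm.
#' @return object of class `slide_mask`.
#' @export
slide_mask <- function(grid, cell_pitch_mm = 0.139) {
  grid <- as.matrix(grid)
  if (!all(grid %in% c(0, 1))) stop("mask values must be 0/1")
  stopifnot(cell_pitch_mm > 0)
  structure(list(grid = grid, cell_pitch_mm = cell_pitch_mm),
            class = "slide_mask")
}

#' Assemble patch predictions into a slide mask
#'
#' Places each patch's predicted label at its (0-based) grid cell; cells
#' with no prediction default to 0 (normal). Duplicate or out-of-range
#' cells are an error.
#'
#' @param preds data.frame with columns `grid_row`, `grid_col` (0-based)
#'   and `pred` (0/1, 1 = cancer).
#' @param n_rows,n_cols declared grid shape (defaults: tight bounding box).
#' @param cell_pitch_mm grid cell pitch in mm.
#' @return a [slide_mask].
#' @export
assemble_slide_mask <- function(preds, n_rows = NULL, n_cols = NULL,
                                cell_pitch_mm = 0.139) {
  if (nrow(preds) > 0) {
    stopifnot(all(c("grid_row", "grid_col", "pred") %in% names(preds)))
    if (anyDuplicated(preds[, c("grid_row", "grid_col")]))
      stop("duplicate grid cell in predictions")
    if (any(preds$grid_row < 0) || any(preds$grid_col < 0))
      stop("negative grid index")
  }
  if (is.null(n_rows)) n_rows <- max(preds$grid_row) + 1L
  if (is.null(n_cols)) n_cols <- max(preds$grid_col) + 1L
  if (nrow(preds) > 0 &&
      (max(preds$grid_row) >= n_rows || max(preds$grid_col) >= n_cols))
    stop("grid index outside the declared grid shape")
  m <- matrix(0, n_rows, n_cols)
  if (nrow(preds) > 0)
    m[cbind(preds$grid_row + 1L, preds$grid_col + 1L)] <- preds$pred
  slide_mask(m, cell_pitch_mm)
}

#' Morphological opening of a slide mask
#'
#' Erosion followed by dilation with a disc structuring element of the
#' given radius (in grid cells), removing isolated speckle predictions.
#' `radius = 0` returns the input unchanged.
#'
#' @param mask a [slide_mask].
#' @param radius disc radius in cells.
#' @return cleaned [slide_mask].
#' @export
clean_mask <- function(mask, radius = 1) {
  stopifnot(inherits(mask, "slide_mask"), radius >= 0)
  if (radius == 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  g <- EBImage::opening(mask$grid, brush)
  slide_mask(matrix(as.numeric(g > 0.5), nrow(mask$grid)), mask$cell_pitch_mm)
}

#' Jaccard index of two slide masks
#'
#' `|A intersect B| / |A union B|`; two empty masks are identical and score
#' 1 by convention.
#'
#' @param A,B [slide_mask]s of the same shape.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  stopifnot(inherits(A, "slide_mask"), inherits(B, "slide_mask"))
  if (!identical(dim(A$grid), dim(B$grid))) stop("mask shape mismatch")
  inter <- sum(A$grid == 1 & B$grid == 1)
  uni <- sum(A$grid == 1 | B$grid == 1)
  if (uni == 0) 1.0 else inter / uni
}

#' Hausdorff distance between two slide masks, in millimetres
#'
#' The symmetric Hausdorff distance
#' `max(max_a min_b d(a, b), max_b min_a d(a, b))` between the foreground
#' cell-center coordinate sets, with Euclidean distance in cell units
#' scaled by the cell pitch.
#'
#' @param A,B non-empty [slide_mask]s with equal pitch.
#' @return distance in mm (0 iff identical foregrounds).
#' @export
hausdorff_mm <- function(A, B) {
  stopifnot(inherits(A, "slide_mask"), inherits(B, "slide_mask"))
  if (!isTRUE(all.equal(A$cell_pitch_mm, B$cell_pitch_mm)))
    stop("cell pitch mismatch")
  pa <- which(A$grid == 1, arr.ind = TRUE)
  pb <- which(B$grid == 1, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))) * A$cell_pitch_mm
}

#' Margin assessment of a predicted mask against ground truth
#'
#' Applies morphological opening to the prediction and reports the Jaccard
#' index and the Hausdorff distance in mm.
#'
#' @param pred,truth [slide_mask]s.
#' @param open_radius opening radius in cells (0 = none).
#' @return list with `jaccard` and `hausdorff_mm`.
#' @export
margin_assessment <- function(pred, truth, open_radius = 1) {
  pred <- clean_mask(pred, open_radius)
  list(jaccard = jaccard(pred, truth),
       hausdorff_mm = hausdorff_mm(pred, truth))
}

#' Read / write a binary mask as 8-bit PNG (0/255)
#' @param path PNG file path.
#' @param cell_pitch_mm pitch attached to the mask on read.
#' @return a [slide_mask].
#' @export
read_mask_png <- function(path, cell_pitch_mm = 0.139) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  slide_mask(matrix(as.numeric(img > 0.5), nrow(img)), cell_pitch_mm)
}

#' @rdname read_mask_png
#' @param mask a [slide_mask] to write.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask$grid), nrow(mask$grid)), path)
  invisible(path)
}
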