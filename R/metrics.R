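#' Symmetrized soft dice loss
#'
#' The soft dice term for a prediction `x` in `[0,1]` and a binary truth `t`
#' is `T(x, t) = 1 - 2 * sum(x*t) / (sum(x^2) + sum(t^2))`.  Because the
#' foreground term alone ignores agreement on the background, the roles of
#' object and background are swapped and the two terms averaged:
#' `L = (T(x, t) + T(1 - x, 1 - t)) / 2`.  The loss is 0 when `x == t`
#' (for binary `x`) and lies in `[0, 1]`.
#'
#' A term whose numerator and denominator both vanish (prediction and truth
#' identically zero) is defined as 0 -- perfect agreement on "nothing" --
#' by an explicit branch rather than a smoothing epsilon.
#'
#' @param prediction Numeric array in `[0, 1]` (a probability map).
#' @param truth Binary array (0/1) of the same dimensions.
#' @param gradient If `TRUE`, also return the gradient with respect to
#'   `prediction`.
#' @return The scalar loss, or (with `gradient = TRUE`) a list
#'   `list(loss, grad)`.
#' @export
soft_dice_loss <- function(prediction, truth, gradient = FALSE) {
  if (!identical(dim_or_len(prediction), dim_or_len(truth)))
    stop("prediction and truth must have identical dimensions")
  if (isTRUE(any(prediction < 0 | prediction > 1)))
    stop("prediction must lie in [0, 1]")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  term <- function(x, t) {
    A <- sum(x * t)
    B <- sum(x^2) + sum(t^2)
    if (is.na(B)) return(list(v = NaN, A = A, B = B, degenerate = TRUE))
    if (B == 0) return(list(v = 0, A = 0, B = 0, degenerate = TRUE))
    list(v = 1 - 2 * A / B, A = A, B = B, degenerate = FALSE)
  }
  f <- term(prediction, truth)
  g <- term(1 - prediction, 1 - truth)
  loss <- (f$v + g$v) / 2
  if (!gradient) return(loss)
  gr <- array(0, dim = dim_or_len(prediction))
  if (!f$degenerate)
    gr <- gr + 0.5 * (-2 * truth / f$B + 4 * f$A * prediction / f$B^2)
  if (!g$degenerate)
    gr <- gr + 0.5 * (2 * (1 - truth) / g$B - 4 * g$A * (1 - prediction) / g$B^2)
  list(loss = loss, grad = gr)
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' Pixel-count intersection over union.  Two identical masks give 1,
#' disjoint non-empty masks give 0; two empty masks are identical and give 1.
#'
#' @param a,b Binary arrays (0/1) of identical dimensions.
#' @return A scalar in `[0, 1]`.
#' @examples
#' a <- matrix(0, 20, 20); a[1:10, 1:10] <- 1   # 100 pixels
#' b <- a; b[10, 10] <- 0; b[15, 15] <- 1       # overlap 99, union 101
#' iou(a, b)                                    # 99/101 = 0.98019...
#' @export
iou <- function(a, b) {
  if (!identical(dim_or_len(a), dim_or_len(b)))
    stop("masks must have identical dimensions")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary")
  inter <- sum(a * b)
  union <- sum(pmax(a, b))
  if (union == 0) return(1)
  inter / union
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its value is `>= threshold` (ties count as
#' foreground).
#'
#' @param p Numeric array in `[0, 1]`.
#' @param threshold Scalar in `[0, 1]`; 0.5 by default.
#' @return A 0/1 array of the same dimensions.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (length(threshold) != 1 || threshold < 0 || threshold > 1)
    stop("threshold must be a scalar in [0, 1]")
  if (any(p < 0 | p > 1)) stop("probability map must lie in [0, 1]")
  m <- (p >= threshold) * 1
  if (!is.null(dim(p))) dim(m) <- dim(p)
  m
}
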