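#' Pixel intersection-over-union of two binary masks
#'
#' `|A & B| / |A | B|` between a predicted and a ground-truth mask. Two
#' empty masks agree perfectly on the absence of foreground and score 1.
#'
#' @param A,B [label_map()]s or binary matrices of the same shape.
#' @return A number in [0, 1].
#' @export
iou <- function(A, B) {
  a <- raster_data(A) > 0
  b <- raster_data(B) > 0
  if (!identical(dim(a), dim(b))) abort_shape("masks differ in shape")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Signal-to-noise ratio of a noisy image given its clean signal
#'
#' `10 * log10(sum(clean^2) / sum((noisy - clean)^2))` in dB, or the plain
#' energy ratio on the linear scale (`linear = 10^(dB / 10)`).
#'
#' @param noisy,clean [micrograph()]s or matrices of the same shape; `clean`
#'   is the noise-free signal.
#' @param scale `"db"` (default) or `"linear"`.
#' @return SNR on the requested scale.
#' @export
snr <- function(noisy, clean, scale = c("db", "linear")) {
  scale <- match.arg(scale)
  f <- raster_data(noisy); fh <- raster_data(clean)
  if (!identical(dim(f), dim(fh))) abort_shape("images differ in shape")
  sig <- sum(fh^2)
  if (sig == 0) abort_domain("clean image has zero signal energy")
  noise <- sum((f - fh)^2)
  if (noise == 0) abort_domain("zero noise energy: SNR is infinite")
  ratio <- sig / noise
  if (scale == "db") 10 * log10(ratio) else ratio
}

#' Match picked coordinates against ground truth
#'
#' Greedy matching in descending pick-score order: each pick claims the
#' nearest still-unmatched truth center within `dist_threshold` (Euclidean,
#' pixels) and counts as a true positive; unmatched picks are false
#' positives and unmatched truth particles false negatives. Each truth is
#' matched at most once, so `TP + FP = n_picks` and `TP + FN = n_truth`.
#'
#' @param pred,truth [pick_set()]s (or tibbles with `x`, `y` and, for
#'   `pred`, `score`).
#' @param dist_threshold Match radius in pixels (> 0); a common choice is
#'   half the particle size.
#' @return An object of class `"pick_match"`: counts `TP`, `FP`, `FN`, the
#'   matched `pairs` tibble and the threshold used.
#' @export
match_picks <- function(pred, truth, dist_threshold) {
  if (dist_threshold <= 0) abort_validation("dist_threshold must be > 0")
  np <- nrow(pred); nt <- nrow(truth)
  ord <- if (np > 0 && "score" %in% names(pred)) {
    order(-pred$score, pred$y, pred$x)
  } else seq_len(np)
  taken <- logical(nt)
  rows <- list()
  for (i in ord) {
    if (nt == 0) break
    d2 <- (truth$x - pred$x[i])^2 + (truth$y - pred$y[i])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= dist_threshold^2) {
      taken[j] <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        pred_x = pred$x[i], pred_y = pred$y[i],
        truth_x = truth$x[j], truth_y = truth$y[j],
        dist = sqrt(d2[j]),
        score = if ("score" %in% names(pred)) pred$score[i] else NA_real_
      )
    }
  }
  pairs <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    pred_x = numeric(), pred_y = numeric(), truth_x = numeric(),
    truth_y = numeric(), dist = numeric(), score = numeric()
  )
  structure(list(
    TP = nrow(pairs), FP = np - nrow(pairs), FN = nt - nrow(pairs),
    pairs = pairs, dist_threshold = dist_threshold,
    n_pred = np, n_truth = nt
  ), class = "pick_match")
}

#' Precision and recall from a match result
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. A zero
#' denominator makes the corresponding metric undefined and raises an
#' error rather than silently reporting 0.
#'
#' @param m A `"pick_match"` from [match_picks()].
#' @return A one-row tibble with columns `precision` and `recall`.
#' @export
precision_recall <- function(m) {
  if (m$TP + m$FP == 0) abort_domain("precision undefined: no picks")
  if (m$TP + m$FN == 0) abort_domain("recall undefined: no truth particles")
  tibble::tibble(precision = m$TP / (m$TP + m$FP),
                 recall = m$TP / (m$TP + m$FN))
}

#' Per-particle IOU between two masks
#'
#' Crops a `box`-sized window around each truth center and computes the
#' IOU of the two masks inside it — a per-particle fidelity measure for
#' generated segmentation labels.
#'
#' @param A,B [label_map()]s or binary matrices of the same shape.
#' @param coords A [pick_set()] or tibble with truth centers `x`, `y`.
#' @param box Window side in pixels.
#' @return Numeric vector of IOUs, one per coordinate.
#' @export
iou_per_particle <- function(A, B, coords, box) {
  a <- raster_data(A); b <- raster_data(B)
  if (!identical(dim(a), dim(b))) abort_shape("masks differ in shape")
  H <- nrow(a); W <- ncol(a)
  purrr::map2_dbl(coords$x, coords$y, function(cx, cy) {
    top <- round(cy) - floor(box / 2); left <- round(cx) - floor(box / 2)
    rows <- max(0, top):min(H - 1, top + box - 1)
    cols <- max(0, left):min(W - 1, left + box - 1)
    iou(a[rows + 1, cols + 1], b[rows + 1, cols + 1])
  })
}

#' Evaluate a pick set against ground truth
#'
#' Coordinate matching plus, when masks are supplied, whole-map and
#' per-particle IOU.
#'
#' @param pred,truth [pick_set()]s.
#' @param dist_threshold Match radius in pixels.
#' @param pred_mask,truth_mask Optional [label_map()]s for IOU.
#' @param box Window side for per-particle IOU (defaults to the truth box
#'   size).
#' @return A list of class `"eval_report"`: `match` (the `pick_match`),
#'   `precision`, `recall`, and when masks are given `mean_iou` and
#'   `iou_per_particle`.
#' @export
evaluate_picks <- function(pred, truth, dist_threshold,
                           pred_mask = NULL, truth_mask = NULL,
                           box = NULL) {
  m <- match_picks(pred, truth, dist_threshold)
  pr <- precision_recall(m)
  rep <- list(match = m, precision = pr$precision, recall = pr$recall)
  if (!is.null(pred_mask) && !is.null(truth_mask)) {
    b <- box %||% if ("box_size" %in% names(truth)) truth$box_size[1] else
      2 * dist_threshold
    rep$mean_iou <- iou(pred_mask, truth_mask)
    rep$iou_per_particle <- iou_per_particle(pred_mask, truth_mask, truth, b)
  }
  structure(rep, class = "eval_report")
}

#' @export
print.pick_match <- function(x, ...) {
  cat(sprintf("<pick_match> TP %d, FP %d, FN %d (threshold %.3g px)\n",
              x$TP, x$FP, x$FN, x$dist_threshold))
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> precision %.4f, recall %.4f", x$precision,
              x$recall))
  if (!is.null(x$mean_iou)) cat(sprintf(", mean IOU %.4f", x$mean_iou))
  cat("\n")
  invisible(x)
}

#' Tidy the matched pairs of a pick match
#' @param x A `"pick_match"`.
#' @param ... Unused.
#' @return The matched-pairs tibble.
#' @importFrom generics tidy
#' @export
tidy.pick_match <- function(x, ...) x$pairs

#' One-row summary of a pick match
#' @param x A `"pick_match"`.
#' @param ... Unused.
#' @return Tibble with counts, precision and recall (NA when undefined).
#' @importFrom generics glance
#' @export
glance.pick_match <- function(x, ...) {
  tibble::tibble(
    TP = x$TP, FP = x$FP, FN = x$FN,
    precision = if (x$TP + x$FP > 0) x$TP / (x$TP + x$FP) else NA_real_,
    recall = if (x$TP + x$FN > 0) x$TP / (x$TP + x$FN) else NA_real_,
    dist_threshold = x$dist_threshold
  )
}
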