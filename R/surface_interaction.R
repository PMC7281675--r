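# Surface-interaction segmentation: one pooled Otsu threshold per movie,
# interaction-area curves, and interaction-loss transition maps.

#' Pooled Otsu threshold for a platelet time-lapse
#'
#' Pools all ROI intensities across the whole sequence and returns the
#' threshold that maximizes the between-class variance of the pooled
#' histogram. Pixels strictly below the threshold are "interacting with the
#' surface" (foreground): IRM contrast is darker-is-closer. One global
#' threshold serves the entire movie, never a per-frame one, so interaction
#' areas are comparable across frames.
#'
#' Histogram rule: integer-valued data with at most 256 distinct levels uses
#' unit bins at its native levels; wider integer ranges and float data use
#' 256 equal-width bins over the pooled min-max range (half-open edges).
#' Ties are broken toward the smallest threshold.
#'
#' @param seq an [irm_sequence()].
#' @param roi optional [platelet_roi()] crop.
#' @return Single numeric threshold (an intensity, a bin edge); foreground is
#'   `intensity < threshold`.
#' @export
pooled_otsu_threshold <- function(seq, roi = NULL) {
  crop <- crop_sequence(seq, roi)
  v <- as.numeric(crop$frames)
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("degenerate histogram: constant-intensity sequence (all = ", lo, ")")
  integral <- all(v == round(v))
  if (integral && (hi - lo + 1) <= 256) {
    edges <- seq(lo, hi + 1)                # unit bins at native levels
  } else {
    edges <- seq(lo, hi, length.out = 257)
    edges[257] <- hi + (hi - lo) * 1e-9     # include the max in the last bin
  }
  counts <- tabulate(findInterval(v, edges, rightmost.closed = FALSE,
                                  left.open = FALSE),
                     nbins = length(edges) - 1L)
  otsu_from_histogram(counts, edges)
}

# Between-class variance maximization on a binned histogram.
# counts: K bin counts; edges: K+1 bin edges. Returns the edge separating
# the optimal split (smallest on ties); bin representative = lower edge.
otsu_from_histogram <- function(counts, edges) {
  k <- length(counts)
  val <- edges[-length(edges)]
  n <- sum(counts)
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * val)
  tot <- s0[k]
  w1 <- n - w0
  # splits after bin i = 1..k-1; classes [1..i] vs (i..k]
  i <- seq_len(k - 1L)
  m0 <- ifelse(w0[i] > 0, s0[i] / w0[i], 0)
  m1 <- ifelse(w1[i] > 0, (tot - s0[i]) / w1[i], 0)
  bcv <- (w0[i] / n) * (w1[i] / n) * (m0 - m1)^2
  bcv[w0[i] == 0 | w1[i] == 0] <- -Inf
  best <- which.max(bcv)                    # which.max takes the first tie
  as.numeric(edges[best + 1L])
}

#' Label interacting pixels with a fixed threshold
#'
#' @param seq an [irm_sequence()].
#' @param roi optional [platelet_roi()] crop.
#' @param threshold intensity; pixels with `intensity < threshold` (strictly)
#'   are interacting. Pixels exactly at the threshold are background.
#' @return An object of class `interaction_mask`: list with `mask` (logical
#'   `H x W x T`), `threshold`, `frame_interval`.
#' @export
interaction_mask <- function(seq, roi = NULL, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  crop <- crop_sequence(seq, roi)
  structure(list(mask = crop$frames < threshold, threshold = threshold,
                 frame_interval = crop$frame_interval,
                 origin_time = crop$origin_time),
            class = "interaction_mask")
}

#' @export
print.interaction_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "interaction_mask: %d x %d x %d, threshold %g, %.1f%% interacting\n",
    d[1], d[2], d[3], x$threshold, 100 * mean(x$mask)))
  invisible(x)
}

#' Interaction-area curve: interacting pixels per frame
#'
#' @param mask an [interaction_mask()].
#' @return Integer vector of per-frame foreground pixel counts.
#' @export
interaction_area_trace <- function(mask) {
  stopifnot(inherits(mask, "interaction_mask"))
  as.integer(apply(mask$mask, 3, sum))
}

#' Accumulated interaction-loss transitions per pixel
#'
#' For every pixel, counts the transitions from interacting to
#' not-interacting (`TRUE -> FALSE` between consecutive frames) from the
#' start of the movie up to `up_to_frame`. Only losses are counted; the
#' complementary gain count is derivable and not stored. Unstable peripheral
#' contacts accumulate counts; stable interior contact stays at zero.
#'
#' @param mask an [interaction_mask()].
#' @param up_to_frame last frame considered (1-based, inclusive); transitions
#'   between frames `t` and `t+1` with `t + 1 <= up_to_frame` are counted.
#' @return Integer `H x W` matrix of counts (class `transition_map`), with
#'   attribute `up_to_frame`.
#' @export
accumulate_transitions <- function(mask, up_to_frame = NULL) {
  stopifnot(inherits(mask, "interaction_mask"))
  tt <- dim(mask$mask)[3]
  if (is.null(up_to_frame)) up_to_frame <- tt
  up_to_frame <- as.integer(up_to_frame)
  if (up_to_frame < 1L || up_to_frame > tt)
    stop("up_to_frame outside [1, ", tt, "]")
  d <- dim(mask$mask)
  if (up_to_frame == 1L) {
    counts <- matrix(0L, d[1], d[2])
  } else {
    loss <- mask$mask[, , 1:(up_to_frame - 1L), drop = FALSE] &
      !mask$mask[, , 2:up_to_frame, drop = FALSE]
    counts <- matrix(as.integer(rowSums(loss, dims = 2)), d[1], d[2])
  }
  structure(counts, up_to_frame = up_to_frame, class = c("transition_map",
                                                         class(counts)))
}

#' Export a transition map as a 16-bit grayscale TIFF
#'
#' @param tm a `transition_map` from [accumulate_transitions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_transition_map <- function(tm, path) {
  m <- unclass(tm) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
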