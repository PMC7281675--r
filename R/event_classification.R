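# Background-calibrated classification of attaching / detaching pixels.

#' Fit the background focal-activity model
#'
#' Pools signed frame-difference (delta) values from an empty region close
#' to the platelet across all frames, and summarizes them as mean and
#' standard deviation (population convention, divisor n). These statistics
#' calibrate the attach/detach thresholds of [classify_active_pixels()].
#'
#' @param x an [irm_sequence()] (with `bg_roi` giving the empty box) or a
#'   [focal_activity_map()] already computed over the background box.
#' @param bg_roi a [background_roi()]; required when `x` is a sequence.
#' @return An object of class `background_model`: list with `mean`, `sd`,
#'   `n_samples`, `roi`.
#' @export
fit_background_model <- function(x, bg_roi = NULL) {
  if (inherits(x, "irm_sequence")) {
    if (is.null(bg_roi)) stop("`bg_roi` is required with a sequence input")
    b <- bg_roi$box
    if (b[3] < b[1] || b[4] < b[2]) stop("empty background box")
    fam <- focal_activity_map(x, platelet_roi("background", b))
  } else if (inherits(x, "focal_activity_map")) {
    fam <- x
  } else stop("`x` must be an irm_sequence or a focal_activity_map")
  pool <- as.numeric(fam$deltas)
  n <- length(pool)
  if (n < 2L) stop("background delta pool needs at least 2 values, got ", n)
  m <- mean(pool)
  s <- sqrt(mean((pool - m)^2))      # population sd, divisor n
  if (s == 0)
    warning("background delta pool has zero variance; ",
            "any nonzero delta will be classified as active")
  structure(list(mean = m, sd = s, n_samples = n, roi = bg_roi),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: mean %.4g, sd %.4g (n = %d pooled deltas)\n",
              x$mean, x$sd, x$n_samples))
  invisible(x)
}

#' Classify significantly attaching / detaching pixels
#'
#' A pixel-frame is *attaching* when its delta exceeds
#' `mean + k * sd` of the background model (strictly), *detaching* when it
#' falls below `mean - k * sd` (strictly). The default `k = 1` follows the
#' one-standard-deviation rule; the two label sets are disjoint by
#' construction.
#'
#' @param fam a [focal_activity_map()] over the platelet box.
#' @param bg a [background_model()][fit_background_model].
#' @param k threshold multiplier in background standard deviations.
#' @return An object of class `event_labels`: list with logical arrays
#'   `attach` and `detach` (`H x W x (T-1)`), thresholds `lo`, `hi`, and `k`.
#' @export
classify_active_pixels <- function(fam, bg, k = 1) {
  stopifnot(inherits(fam, "focal_activity_map"),
            inherits(bg, "background_model"), k > 0)
  hi <- bg$mean + k * bg$sd
  lo <- bg$mean - k * bg$sd
  structure(list(attach = fam$deltas > hi, detach = fam$deltas < lo,
                 lo = lo, hi = hi, k = k,
                 frame_interval = fam$frame_interval,
                 origin_time = fam$origin_time),
            class = "event_labels")
}

#' @export
print.event_labels <- function(x, ...) {
  cat(sprintf(
    "event_labels: %d frames, thresholds (%.4g, %.4g), %.2f%% active\n",
    dim(x$attach)[3], x$lo, x$hi, 100 * (mean(x$attach) + mean(x$detach))))
  invisible(x)
}

#' Fraction of pixel-frames labeled active
#'
#' @param labels an [classify_active_pixels()] result.
#' @return Single number in `[0, 1]`: active pixel-frames / all pixel-frames.
#' @export
active_fraction <- function(labels) {
  stopifnot(inherits(labels, "event_labels"))
  mean(labels$attach) + mean(labels$detach)
}

#' Per-frame attach and detach fractions
#'
#' With the default denominator (`"active"`), the attach fraction of a frame
#' is `n_attach / (n_attach + n_detach)` and the two series are exact
#' complements; frames with no active pixel yield `NA`, never 0/0. The
#' alternative `"roi"` denominator normalizes each count by the full pixel
#' count of the box (the series are then not complementary).
#'
#' @param labels an [classify_active_pixels()] result.
#' @param denominator `"active"` (default) or `"roi"`.
#' @return data.frame with `frame`, `time_seconds`, `n_attach`, `n_detach`,
#'   `attach_fraction`, `detach_fraction`.
#' @export
attach_detach_fractions <- function(labels,
                                    denominator = c("active", "roi")) {
  stopifnot(inherits(labels, "event_labels"))
  denominator <- match.arg(denominator)
  na <- as.integer(apply(labels$attach, 3, sum))
  nd <- as.integer(apply(labels$detach, 3, sum))
  npix <- prod(dim(labels$attach)[1:2])
  if (denominator == "active") {
    tot <- na + nd
    af <- ifelse(tot > 0, na / tot, NA_real_)
    df <- ifelse(tot > 0, nd / tot, NA_real_)
  } else {
    af <- na / npix
    df <- nd / npix
  }
  data.frame(frame = seq_along(na),
             time_seconds = (seq_along(na) - 1) * labels$frame_interval +
               labels$origin_time,
             n_attach = na, n_detach = nd,
             attach_fraction = af, detach_fraction = df)
}

#' Overlay attach / detach events on the IRM image
#'
#' Renders difference frame `frame` (events between frames `frame` and
#' `frame + 1`) on the grayscale IRM frame, recoloring attach pixels in one
#' hue and detach pixels in another, pixel-exactly.
#'
#' @param seq the [irm_sequence()] the labels were computed from.
#' @param labels an [classify_active_pixels()] result.
#' @param frame difference-frame index (1-based, `<= T - 1`).
#' @param roi the [platelet_roi()] the labels were computed over (crop must
#'   match the label arrays).
#' @param path optional PNG output path.
#' @param attach_col,detach_col colors for the two event types.
#' @return `H x W x 3` RGB array in `[0, 1]`, invisibly.
#' @export
render_event_overlay <- function(seq, labels, frame, roi = NULL, path = NULL,
                                 attach_col = "yellow", detach_col = "blue") {
  stopifnot(inherits(labels, "event_labels"))
  crop <- crop_sequence(seq, roi)
  if (frame < 1L || frame > dim(labels$attach)[3])
    stop("frame outside [1, ", dim(labels$attach)[3], "]")
  if (!identical(dim(crop$frames)[1:2], dim(labels$attach)[1:2]))
    stop("label arrays do not match the ROI crop")
  g <- crop$frames[, , frame]
  rng <- range(crop$frames)
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  img <- array(g, dim = c(dim(g), 3L))
  ac <- grDevices::col2rgb(attach_col) / 255
  dc <- grDevices::col2rgb(detach_col) / 255
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[labels$attach[, , frame]] <- ac[ch]
    plane[labels$detach[, , frame]] <- dc[ch]
    img[, , ch] <- plane
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
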