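# Cohort-level kinetics: attachment curves, phase durations, endpoint
# fractions, and the Wilcoxon rank-sum comparison.

endpoint_levels <- c("no_attach", "filopodial", "fully_spread")

#' Assemble a cohort table
#'
#' One row per platelet: substrate label, attachment time (seconds; `NA`
#' with `attached = FALSE` means censored at the observation horizon),
#' phase durations, endpoint class.
#'
#' @param platelet_id,substrate character vectors.
#' @param attachment_time seconds, `NA` when censored.
#' @param attached logical; censored platelets are `FALSE`.
#' @param filopodial_duration,lamellipodial_duration seconds or `NA`.
#' @param endpoint_class one of `"no_attach"`, `"filopodial"`,
#'   `"fully_spread"` per platelet.
#' @param horizon observation horizon in seconds (recycled).
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(platelet_id, substrate, attachment_time,
                         attached = !is.na(attachment_time),
                         filopodial_duration = NA_real_,
                         lamellipodial_duration = NA_real_,
                         endpoint_class = NA_character_,
                         horizon = NA_real_) {
  if (any(attachment_time < 0, na.rm = TRUE) ||
      any(filopodial_duration < 0, na.rm = TRUE) ||
      any(lamellipodial_duration < 0, na.rm = TRUE))
    stop("times and durations must be >= 0")
  if (any(!attached & is.na(horizon)))
    stop("censored platelets must carry the observation horizon")
  bad <- !is.na(endpoint_class) & !endpoint_class %in% endpoint_levels
  if (any(bad))
    stop("unknown endpoint_class: ",
         paste(unique(endpoint_class[bad]), collapse = ", "))
  out <- data.frame(platelet_id = as.character(platelet_id),
                    substrate = as.character(substrate),
                    attachment_time = as.numeric(attachment_time),
                    attached = as.logical(attached),
                    filopodial_duration = as.numeric(filopodial_duration),
                    lamellipodial_duration = as.numeric(lamellipodial_duration),
                    endpoint_class = as.character(endpoint_class),
                    horizon = as.numeric(horizon),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", class(out))
  out
}

#' Attachment-percentage curve for one substrate
#'
#' The percentage of platelets in the group that have attached by each time
#' point: a scaled empirical CDF, monotone non-decreasing in `[0, 100]`.
#' Censored platelets never count as attached.
#'
#' @param cohort a [cohort_table()].
#' @param substrate group label to select.
#' @param time_grid increasing vector of seconds.
#' @return data.frame with `time_seconds`, `percent_attached`, and attribute
#'   `n` (group size).
#' @export
attachment_curve <- function(cohort, substrate, time_grid) {
  grp <- cohort[cohort$substrate == substrate, , drop = FALSE]
  if (nrow(grp) == 0L) stop("no platelets for substrate ", substrate)
  if (any(diff(time_grid) <= 0)) stop("time_grid must be increasing")
  pct <- vapply(time_grid, function(t)
    100 * sum(grp$attached & grp$attachment_time <= t, na.rm = TRUE) /
      nrow(grp), numeric(1))
  structure(data.frame(time_seconds = time_grid, percent_attached = pct),
            n = nrow(grp))
}

#' Phase durations from annotated stage time points
#'
#' Filopodial duration = (lamellipodia onset - filopodia onset) frames times
#' the frame interval; lamellipodial duration = (spread - lamellipodia
#' onset) likewise. Absent stages give `NA` durations, never zero.
#'
#' @param annotations list of [phase_annotation()] objects.
#' @param frame_interval seconds per frame.
#' @return data.frame with `platelet_id`, `filopodial_duration`,
#'   `lamellipodial_duration`, `endpoint_class` (seconds).
#' @export
phase_durations <- function(annotations, frame_interval) {
  stopifnot(frame_interval > 0)
  rows <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "phase_annotation"))
    filo <- if (!is.na(a$filopodia_onset_frame) &&
                !is.na(a$lamellipodia_onset_frame))
      (a$lamellipodia_onset_frame - a$filopodia_onset_frame) * frame_interval
    else NA_real_
    lam <- if (!is.na(a$lamellipodia_onset_frame) && !is.na(a$spread_frame))
      (a$spread_frame - a$lamellipodia_onset_frame) * frame_interval
    else NA_real_
    data.frame(platelet_id = a$platelet_id, filopodial_duration = filo,
               lamellipodial_duration = lam,
               endpoint_class = a$endpoint_class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Endpoint-class fractions for one substrate
#'
#' @param cohort a [cohort_table()].
#' @param substrate group label; `NULL` uses all rows.
#' @return Named numeric vector of fractions over
#'   `no_attach / filopodial / fully_spread` (sums to 1), with attribute `n`.
#' @export
endpoint_fractions <- function(cohort, substrate = NULL) {
  grp <- if (is.null(substrate)) cohort else
    cohort[cohort$substrate == substrate, , drop = FALSE]
  if (nrow(grp) == 0L) stop("empty group")
  tab <- table(factor(grp$endpoint_class, levels = endpoint_levels))
  structure(as.numeric(tab) / nrow(grp), names = endpoint_levels,
            n = nrow(grp))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' The statistic is the rank sum of the first sample (midranks under ties).
#' For pooled sizes `n1 + n2 <= 12` the null distribution is obtained by
#' full enumeration of all group assignments of the observed ranks (exact,
#' ties included); larger samples use the normal approximation with tie and
#' continuity corrections, refined by an Edgeworth kurtosis term (the
#' rank-sum null is platykurtic, and the fourth-moment term keeps the
#' approximate tail within a few thousandths of the exact one already at
#' pooled sizes near the enumeration boundary). The p-value is invariant
#' under any common strictly monotone transform of both samples.
#'
#' @param a,b numeric samples (each non-empty; ties allowed).
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` enumerates when `n1 + n2 <= 12`.
#' @return An object of class `rank_test`: list with `statistic` (rank sum
#'   of `a`), `p_value`, `n1`, `n2`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))                      # midranks
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  if (is.null(exact)) exact <- n <= 12L
  if (exact) {
    sums <- utils::combn(n, n1, FUN = function(ix) sum(r[ix]))
    p <- mean(abs(sums - e) >= abs(w - e) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- max((abs(w - e) - 0.5) / sqrt(v), 0)   # continuity correction
      # excess kurtosis of the tie-free rank-sum null (Edgeworth term)
      g2 <- -6 / 5 * (n1^2 + n2^2 + n1 * n2 + n1 + n2) /
        (n1 * n2 * (n + 1))
      q <- stats::pnorm(-z) + g2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)
      if (q <= 0) q <- stats::pnorm(-z)   # far tail: plain normal floor
      p <- min(1, 2 * q)
    }
    method <- "Edgeworth-refined normal approximation with tie and continuity correction"
  }
  structure(list(statistic = w, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Surrogate attachment frame from the interaction-area curve
#'
#' The gold-standard attachment call is the manually annotated
#' immobilization frame; when that is absent this surrogate is used: the first
#' frame from which the interaction area stays at or above `min_pixels` for
#' `consecutive` frames.
#'
#' @param area integer vector from [interaction_area_trace()].
#' @param min_pixels minimum interacting-pixel count (default 20).
#' @param consecutive required run length in frames (default 3).
#' @return Frame index (1-based), or `NA` if never attached.
#' @export
detect_attachment_frame <- function(area, min_pixels = 20L, consecutive = 3L) {
  ok <- area >= min_pixels
  if (length(ok) < consecutive) return(NA_integer_)
  run <- stats::filter(as.numeric(ok), rep(1, consecutive), sides = 1)
  hit <- which(run == consecutive)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1] - consecutive + 1L)
}
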