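# Synthetic IRM movie generator with full ground truth: hover blob,
# filopodial tapping, logistic lamellipodial growth, plateau.

#' Configuration for the synthetic IRM movie generator
#'
#' Defaults describe a collagen-like spreading platelet on an 8-bit-like
#' intensity scale (background mean 100, Gaussian noise sd 5, contact
#' pixels darkened by 60). The frame interval defaults to 1 s so that
#' 5-10 s filopodial tapping is comfortably resolvable; pass 5 to mimic
#' typical IRM acquisition (tapping then sits at the Nyquist limit).
#'
#' @param height,width image size in pixels.
#' @param frame_interval seconds per frame.
#' @param hover_duration seconds of pre-attachment hovering (bright
#'   out-of-focus blob, no surface contact).
#' @param filopodial_duration seconds of filopodial tapping.
#' @param lamellipodial_duration seconds of lamellipodial disk growth.
#' @param plateau_duration seconds of the fully spread plateau.
#' @param n_filopodia number of filopodia.
#' @param filopodium_length,filopodium_width segment geometry in pixels.
#' @param tapping_period_range seconds; each filopodium draws its tapping
#'   period uniformly from this range (default `c(5, 10)`). Must be
#'   Nyquist-representable: lower end `>= 2 * frame_interval`.
#' @param contact_darkening intensity drop of touching pixels; must exceed
#'   `2 * noise_sd` so contact is detectable by construction.
#' @param ramp_duration seconds over which newly contacted lamellipodial
#'   pixels mature to full darkening (filopodial contacts switch abruptly).
#' @param contact_jitter_sd extra intensity sd on touching pixels (residual
#'   membrane fluctuation; keeps the spread plateau's activity above the
#'   pre-attachment baseline).
#' @param background_mean,noise_sd additive Gaussian pixel noise model.
#' @param hover_brightening peak intensity rise of the out-of-focus blob
#'   (default 1.5 noise sd: visible, but never on the dark foreground side
#'   of the pooled Otsu split).
#' @param initial_disk_radius lamellipodial base disk radius (pixels),
#'   appearing at full contact at the lamellipodial onset.
#' @param max_radius pixel radius the lamellipodial disk grows toward
#'   (logistic growth `dr/dt = k r (1 - r / max_radius)`).
#' @param arrest_probability probability that the platelet never enters the
#'   lamellipodial phase and keeps cycling whole filopodia instead.
#' @param seed integer RNG seed; identical seed + config gives a
#'   bit-identical movie.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(height = 64L, width = 64L, frame_interval = 1,
                              hover_duration = 20,
                              filopodial_duration = 60,
                              lamellipodial_duration = 60,
                              plateau_duration = 40,
                              n_filopodia = 6L,
                              filopodium_length = 12,
                              filopodium_width = 2,
                              tapping_period_range = c(5, 10),
                              contact_darkening = 60,
                              ramp_duration = 10,
                              contact_jitter_sd = 6,
                              background_mean = 100,
                              noise_sd = 5,
                              hover_brightening = 1.5 * noise_sd,
                              initial_disk_radius = 4,
                              max_radius = 15,
                              arrest_probability = 0,
                              seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              frame_interval = frame_interval,
              hover_duration = hover_duration,
              filopodial_duration = filopodial_duration,
              lamellipodial_duration = lamellipodial_duration,
              plateau_duration = plateau_duration,
              n_filopodia = as.integer(n_filopodia),
              filopodium_length = filopodium_length,
              filopodium_width = filopodium_width,
              tapping_period_range = tapping_period_range,
              contact_darkening = contact_darkening,
              ramp_duration = ramp_duration,
              contact_jitter_sd = contact_jitter_sd,
              background_mean = background_mean,
              noise_sd = noise_sd,
              hover_brightening = hover_brightening,
              initial_disk_radius = initial_disk_radius,
              max_radius = max_radius,
              arrest_probability = arrest_probability,
              seed = as.integer(seed))
  durs <- c(cfg$hover_duration, cfg$filopodial_duration,
            cfg$lamellipodial_duration, cfg$plateau_duration)
  if (any(durs < 0)) stop("phase durations must be >= 0")
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (sum(durs) < 2 * cfg$frame_interval)
    stop("total duration must span at least 2 frames")
  if (cfg$n_filopodia > 0 &&
      cfg$tapping_period_range[1] < 2 * cfg$frame_interval)
    stop("tapping periods must be Nyquist-representable: ",
         "tapping_period_range[1] >= 2 * frame_interval")
  if (diff(cfg$tapping_period_range) < 0)
    stop("tapping_period_range must be increasing")
  if (cfg$contact_darkening <= 2 * cfg$noise_sd)
    stop("contact_darkening must exceed 2 * noise_sd to be detectable")
  if (cfg$max_radius <= cfg$initial_disk_radius)
    stop("max_radius must exceed initial_disk_radius")
  if (cfg$arrest_probability < 0 || cfg$arrest_probability > 1)
    stop("arrest_probability must be in [0, 1]")
  structure(cfg, class = "simulation_config")
}

#' Named simulator scenarios
#'
#' * `collagen_like`: the full phase script - hover, staggered filopodial
#'   tapping, logistic lamellipodial growth, spread plateau.
#' * `fibrinogen_like`: whole-filopodium attach/detach cycling; with
#'   probability 0.57 the platelet arrests in the filopodial state and the
#'   lamellipodial phase never occurs (the annotation then lacks a
#'   lamellipodial onset).
#' * `background_only`: additive noise only, no platelet.
#'
#' @param name scenario name.
#' @param ... overrides passed to [simulation_config()] (e.g. `seed`,
#'   `frame_interval`).
#' @return A [simulation_config()].
#' @export
scenario_preset <- function(name = c("collagen_like", "fibrinogen_like",
                                     "background_only"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    collagen_like = list(arrest_probability = 0),
    fibrinogen_like = list(arrest_probability = 0.57),
    background_only = list(n_filopodia = 0L, hover_duration = 180,
                           filopodial_duration = 0,
                           lamellipodial_duration = 0, plateau_duration = 0,
                           hover_brightening = 0))
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(simulation_config, defaults)
}

#' Simulate an IRM time-lapse movie with ground truth
#'
#' Builds a movie of a single spreading platelet: background Gaussian
#' noise; during hovering a bright out-of-focus blob; thin radial filopodia
#' whose surface contact is a square wave with the drawn tapping period;
#' then a lamellipodial disk growing from the filopodial base by logistic
#' radius growth, while new contact matures over `ramp_duration`; finally a
#' static plateau. All randomness is governed by `cfg$seed` - the same seed
#' and config give a bit-identical movie.
#'
#' @param cfg a [simulation_config()].
#' @return An object of class `irm_simulation`: list with
#'   `sequence` ([irm_sequence()]), `truth` (ground truth: `contact`
#'   `H x W x T` logical, `phase_onsets`, `tapping_periods`,
#'   `filopodium_masks`, `final_area`, `arrested`), `roi`
#'   ([platelet_roi()]), `background` ([background_roi()]), `annotation`
#'   ([phase_annotation()]), `config`.
#' @export
simulate_movie <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, simulate_movie_impl(cfg))
}

simulate_movie_impl <- function(cfg) {
  int <- cfg$frame_interval
  n_h <- round(cfg$hover_duration / int)
  n_f <- round(cfg$filopodial_duration / int)
  n_l <- round(cfg$lamellipodial_duration / int)
  n_p <- round(cfg$plateau_duration / int)
  tt <- n_h + n_f + n_l + n_p
  h <- cfg$height; w <- cfg$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rowm <- matrix(seq_len(h), h, w)
  colm <- matrix(seq_len(w), h, w, byrow = TRUE)
  dist <- sqrt((rowm - cy)^2 + (colm - cx)^2)

  has_filo <- cfg$n_filopodia > 0 && n_f > 0
  arrested <- has_filo && stats::runif(1) < cfg$arrest_probability

  filo_onset <- if (has_filo) n_h + 1L else NA_integer_
  lam_onset <- if (!arrested && n_l > 0) n_h + n_f + 1L else NA_integer_
  spread_frame <- if (!is.na(lam_onset) && n_h + n_f + n_l + 1L <= tt)
    n_h + n_f + n_l + 1L else NA_integer_

  # filopodia: staggered appearance over the first half of the phase,
  # square-wave tapping with per-filopodium period and phase
  nf <- cfg$n_filopodia
  masks <- list(); periods <- numeric(0)
  onsets <- integer(0); phases <- numeric(0)
  if (has_filo) {
    angles <- 2 * pi * (seq_len(nf) - 1) / nf +
      stats::runif(nf, -0.15, 0.15)
    periods <- stats::runif(nf, cfg$tapping_period_range[1],
                            cfg$tapping_period_range[2])
    onsets <- filo_onset +
      c(0L, as.integer(floor(stats::runif(max(nf - 1, 0), 0, max(n_f / 2, 1)))))
    onsets <- onsets[seq_len(nf)]
    phases <- stats::runif(nf, 0, periods / 2)
    inner <- 2
    masks <- lapply(seq_len(nf), function(i) {
      ux <- cos(angles[i]); uy <- sin(angles[i])
      along <- (rowm - cy) * ux + (colm - cx) * uy
      perp <- abs(-(rowm - cy) * uy + (colm - cx) * ux)
      along >= inner & along <= inner + cfg$filopodium_length &
        perp <= cfg$filopodium_width / 2
    })
  }
  tap_end <- if (arrested || is.na(lam_onset)) tt else lam_onset - 1L

  # lamellipodial disk: logistic growth ODE from the base disk radius
  r0 <- cfg$initial_disk_radius; rmax <- cfg$max_radius
  amp <- (rmax - r0) / r0
  kg <- if (n_l > 0) log(amp / (1 / 0.98 - 1)) / cfg$lamellipodial_duration
        else NA_real_
  t_on <- if (!is.na(lam_onset)) (lam_onset - 1L) * int else NA_real_
  # per-pixel first-contact time of the growing disk
  t_fc <- matrix(Inf, h, w)
  if (!is.na(lam_onset)) {
    inside <- dist < rmax
    t_fc[inside & dist <= r0] <- t_on
    grow <- inside & dist > r0
    t_fc[grow] <- t_on + log(amp * dist[grow] / (rmax - dist[grow])) / kg
    t_fc[grow] <- pmax(t_fc[grow], t_on)
  }

  blob <- cfg$hover_brightening * exp(-dist^2 / (2 * (rmax / 2)^2))
  frames <- array(0, dim = c(h, w, tt))
  contact <- array(FALSE, dim = c(h, w, tt))
  for (f in seq_len(tt)) {
    t_now <- (f - 1) * int
    dark <- matrix(0, h, w)
    con <- matrix(FALSE, h, w)
    if (!is.na(lam_onset) && f >= lam_onset) {
      hit <- t_fc <= t_now
      con[hit] <- TRUE
      ramp <- if (cfg$ramp_duration > 0)
        pmin(1, (t_now - t_fc[hit] + int) / cfg$ramp_duration) else 1
      ramp[dist[hit] <= r0] <- 1          # base disk matures instantly
      dark[hit] <- cfg$contact_darkening * ramp
    }
    if (has_filo && f >= filo_onset) {
      for (i in seq_len(nf)) {
        if (f < onsets[i]) next
        attached <- if (f > tap_end) TRUE else {
          s <- (f - onsets[i]) * int
          ((s + phases[i]) %% periods[i]) < periods[i] / 2
        }
        if (attached) {
          con[masks[[i]]] <- TRUE
          dark[masks[[i]]] <- pmax(dark[masks[[i]]], cfg$contact_darkening)
        }
      }
    }
    body_hovering <- is.na(lam_onset) || f < lam_onset
    img <- cfg$background_mean +
      stats::rnorm(h * w, 0, cfg$noise_sd) +
      (if (body_hovering) blob else 0) - dark
    idx <- which(con)
    if (length(idx) && cfg$contact_jitter_sd > 0)
      img[idx] <- img[idx] + stats::rnorm(length(idx), 0,
                                          cfg$contact_jitter_sd)
    frames[, , f] <- pmin(255, pmax(0, img))
    contact[, , f] <- con
  }

  footprint <- apply(contact, c(1, 2), any)
  margin <- 3L
  if (any(footprint)) {
    rr <- range(which(apply(footprint, 1, any)))
    cc <- range(which(apply(footprint, 2, any)))
    box <- c(max(1L, rr[1] - margin), max(1L, cc[1] - margin),
             min(h, rr[2] + margin), min(w, cc[2] + margin))
  } else {
    half <- min(cfg$max_radius + margin, floor(min(h, w) / 2) - 1L)
    box <- c(round(cy - half), round(cx - half),
             round(cy + half), round(cx + half))
  }
  roi <- platelet_roi("sim", box, c(1L, tt))
  bg <- pick_background_box(box, h, w, size = 8L)
  endpoint <- if (!has_filo && is.na(lam_onset)) "no_attach"
              else if (is.na(lam_onset)) "filopodial"
              else "fully_spread"
  ann <- phase_annotation("sim", onset_frame = 1L,
                          filopodia_onset_frame = filo_onset,
                          lamellipodia_onset_frame = lam_onset,
                          spread_frame = spread_frame,
                          endpoint_class = endpoint)
  truth <- structure(
    list(contact = contact,
         phase_onsets = c(filopodia = filo_onset, lamellipodia = lam_onset,
                          spread = spread_frame),
         tapping_periods = periods,
         filopodium_masks = masks,
         filopodium_onsets = onsets,
         final_area = sum(contact[, , tt]),
         arrested = arrested,
         center = c(cy, cx)),
    class = "irm_ground_truth")
  structure(list(sequence = irm_sequence(frames, int, source_id = "synthetic"),
                 truth = truth, roi = roi, background = bg,
                 annotation = ann, config = cfg),
            class = "irm_simulation")
}

# first image corner (size x size) disjoint from the platelet box
pick_background_box <- function(box, h, w, size = 8L) {
  corners <- list(c(1L, 1L), c(1L, w - size + 1L),
                  c(h - size + 1L, 1L), c(h - size + 1L, w - size + 1L))
  for (cn in corners) {
    cand <- c(cn[1], cn[2], cn[1] + size - 1L, cn[2] + size - 1L)
    if (boxes_disjoint(cand, box)) return(background_roi(cand))
  }
  stop("no empty corner left for a background box; platelet box too large")
}

#' @export
print.irm_simulation <- function(x, ...) {
  d <- dim(x$sequence$frames)
  cat(sprintf("irm_simulation: %d x %d x %d frames, endpoint %s%s\n",
              d[1], d[2], d[3], x$annotation$endpoint_class,
              if (isTRUE(x$truth$arrested)) " (arrested)" else ""))
  invisible(x)
}

#' Write a simulated movie, its annotations and ground truth to disk
#'
#' Emits `movie.tif` (16-bit multi-page TIFF), `annotations.csv` (the
#' [load_annotations()] dialect), `contact.tif` (ground-truth contact masks
#' as a paged TIFF) and `ground_truth.json` (phase onsets, tapping periods,
#' final area).
#'
#' @param sim an [simulate_movie()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "irm_simulation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seq16 <- sim$sequence
  seq16$frames <- round(seq16$frames)
  write_sequence(seq16, file.path(out_dir, "movie.tif"), 16L)
  write_annotations(list(list(roi = sim$roi, phases = sim$annotation,
                              background = sim$background)),
                    file.path(out_dir, "annotations.csv"))
  pages <- lapply(seq_len(dim(sim$truth$contact)[3]),
                  function(t) sim$truth$contact[, , t] * 1)
  tiff::writeTIFF(pages, file.path(out_dir, "contact.tif"),
                  bits.per.sample = 8L, compression = "none")
  gt <- list(phase_onsets = as.list(sim$truth$phase_onsets),
             tapping_periods = sim$truth$tapping_periods,
             final_area = sim$truth$final_area,
             arrested = sim$truth$arrested)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Simulate a two-substrate attachment-time cohort
#'
#' Desk-scale stand-in for a donor cohort: attachment times are exponential
#' with a substrate-specific mean (collagen-like surfaces bind faster),
#' censored at the observation horizon; endpoint classes are drawn with the
#' substrate's arrest probability.
#'
#' @param n_collagen,n_fibrinogen group sizes.
#' @param mean_collagen,mean_fibrinogen mean attachment times (seconds).
#' @param arrest_collagen,arrest_fibrinogen probability that an attached
#'   platelet stays filopodial instead of fully spreading.
#' @param horizon observation horizon (seconds).
#' @param seed RNG seed.
#' @return A [cohort_table()] with substrates `"collagen_iv"` and
#'   `"fibrinogen"`.
#' @export
simulate_attachment_cohort <- function(n_collagen = 274L,
                                       n_fibrinogen = 121L,
                                       mean_collagen = 30,
                                       mean_fibrinogen = 60,
                                       arrest_collagen = 0.24,
                                       arrest_fibrinogen = 0.57,
                                       horizon = 600,
                                       seed = 1L) {
  withr::with_seed(seed, {
    t_c <- stats::rexp(n_collagen, 1 / mean_collagen)
    t_f <- stats::rexp(n_fibrinogen, 1 / mean_fibrinogen)
    times <- c(t_c, t_f)
    subs <- rep(c("collagen_iv", "fibrinogen"), c(n_collagen, n_fibrinogen))
    attached <- times <= horizon
    arrest_p <- ifelse(subs == "collagen_iv", arrest_collagen,
                       arrest_fibrinogen)
    arrested <- stats::runif(length(times)) < arrest_p
    endpoint <- ifelse(!attached, "no_attach",
                       ifelse(arrested, "filopodial", "fully_spread"))
    cohort_table(platelet_id = sprintf("plt%03d", seq_along(times)),
                 substrate = subs,
                 attachment_time = ifelse(attached, times, NA_real_),
                 attached = attached,
                 endpoint_class = endpoint,
                 horizon = horizon)
  })
}
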