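test_that("simulation is bit-deterministic given seed and config", {
  a <- simulate_movie(scenario_preset("collagen_like", seed = 12))
  b <- simulate_movie(scenario_preset("collagen_like", seed = 12))
  expect_identical(a$sequence$frames, b$sequence$frames)
  expect_identical(a$truth$contact, b$truth$contact)
  c2 <- simulate_movie(scenario_preset("collagen_like", seed = 13))
  expect_false(identical(a$sequence$frames, c2$sequence$frames))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(hover_duration = -1), ">= 0")
  expect_error(simulation_config(tapping_period_range = c(5, 10),
                                 frame_interval = 4), "Nyquist")
  expect_error(simulation_config(contact_darkening = 8, noise_sd = 5),
               "2 \\* noise_sd")
  expect_error(simulation_config(max_radius = 3, initial_disk_radius = 4),
               "exceed")
  expect_error(scenario_preset("no_such"))
})

test_that("background-only movies carry no contact and no foreground", {
  sim <- simulate_movie(scenario_preset("background_only", seed = 2))
  expect_false(any(sim$truth$contact))
  expect_equal(sim$annotation$endpoint_class, "no_attach")
  an <- analyze_platelet(sim$sequence, sim$roi, sim$background)
  expect_false(an$contact_detected)
  expect_equal(an$area, rep(0L, length(an$area)))
})

test_that("a hovering platelet alone yields zero interaction area", {
  # static bright blob, no noise, no filopodia: the pipeline must not call
  # the background "interacting" just because Otsu can split blob from it
  sim <- simulate_movie(scenario_preset("background_only", seed = 3,
                                        noise_sd = 0.5,
                                        hover_brightening = 10))
  an <- analyze_platelet(sim$sequence, sim$roi, sim$background)
  expect_false(an$contact_detected)
  expect_true(all(an$area == 0))
})

test_that("phase script structure holds in the ground truth", {
  sim <- simulate_movie(scenario_preset("collagen_like", seed = 21))
  tr <- sim$truth
  n_h <- tr$phase_onsets["filopodia"] - 1
  # contact empty during hover
  expect_false(any(tr$contact[, , seq_len(n_h)]))
  # contact area non-decreasing through the lamellipodial phase
  area <- apply(tr$contact, 3, sum)
  lam <- tr$phase_onsets["lamellipodia"]:tr$phase_onsets["spread"]
  expect_true(all(diff(area[lam]) >= 0))
  # final footprint equals disk + filopodia pixel geometry
  expect_equal(tr$final_area, sum(tr$contact[, , dim(tr$contact)[3]]))
  filo_px <- Reduce(`|`, tr$filopodium_masks)
  expect_true(all(tr$contact[, , dim(tr$contact)[3]][filo_px]))
  # annotations mirror the truth
  expect_equal(sim$annotation$lamellipodia_onset_frame,
               unname(tr$phase_onsets["lamellipodia"]))
  expect_equal(sim$annotation$endpoint_class, "fully_spread")
})

test_that("single-filopodium tapping alternates at the drawn period", {
  cfg <- scenario_preset("collagen_like", n_filopodia = 1L, seed = 31,
                         tapping_period_range = c(10, 10))
  sim <- simulate_movie(cfg)
  m <- sim$truth$filopodium_masks[[1]]
  fw <- sim$annotation$filopodia_onset_frame:
    (sim$annotation$lamellipodia_onset_frame - 1)
  state <- vapply(fw, function(f) any(sim$truth$contact[, , f][m]),
                  logical(1))
  # ground-truth contact alternates with period 10 frames
  expect_equal(state[seq_len(length(state) - 10)],
               state[11:length(state)])
  expect_true(any(state) && !all(state))
  # recovered by autocorrelation of the interaction-area trace
  th <- pooled_otsu_threshold(sim$sequence, sim$roi)
  trc <- vapply(fw, function(f) sum(sim$sequence$frames[, , f][m] < th),
                numeric(1))
  expect_lte(abs(estimate_tapping_period(trc) - 10), 1)
})

test_that("fibrinogen-like arrest suppresses the lamellipodial phase", {
  cls <- vapply(1:30, function(s) {
    sim <- simulate_movie(scenario_preset("fibrinogen_like", seed = s))
    if (sim$truth$arrested)
      expect_true(is.na(sim$annotation$lamellipodia_onset_frame))
    sim$annotation$endpoint_class
  }, character(1))
  frac <- mean(cls == "filopodial")
  # binomial 95% band around the configured arrest fraction (0.57, n = 30)
  expect_gt(frac, 0.57 - 1.96 * sqrt(0.57 * 0.43 / 30))
  expect_lt(frac, 0.57 + 1.96 * sqrt(0.57 * 0.43 / 30))
})

test_that("simulation output files round trip through the io module", {
  sim <- simulate_movie(scenario_preset("collagen_like", seed = 41,
                                        hover_duration = 5,
                                        filopodial_duration = 10,
                                        lamellipodial_duration = 10,
                                        plateau_duration = 5))
  dir <- tempfile()
  write_simulation(sim, dir)
  back <- load_sequence(file.path(dir, "movie.tif"), frame_interval = 1)
  expect_equal(dim(back$frames), dim(sim$sequence$frames))
  expect_equal(back$frames, round(sim$sequence$frames), tolerance = 1e-12)
  rec <- load_annotations(file.path(dir, "annotations.csv"), back)
  expect_equal(rec[[1]]$roi$box, sim$roi$box)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$final_area, sim$truth$final_area)
})

test_that("synthetic cohorts carry censoring and substrate structure", {
  co <- simulate_attachment_cohort(n_collagen = 50, n_fibrinogen = 40,
                                   horizon = 100, seed = 9)
  expect_equal(nrow(co), 90)
  expect_true(all(is.na(co$attachment_time[!co$attached])))
  expect_true(all(co$endpoint_class[!co$attached] == "no_attach"))
  expect_true(all(co$attachment_time[co$attached] <= 100))
})
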