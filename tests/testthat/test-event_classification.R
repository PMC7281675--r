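test_that("background model pools deltas with population mean and sd", {
  # constant background: zero-variance pool warns
  s <- irm_sequence(array(5, c(2, 2, 3)), 5)
  expect_warning(bg <- fit_background_model(s, background_roi(c(1, 1, 2, 2))),
                 "zero variance")
  expect_equal(bg$mean, 0); expect_equal(bg$sd, 0)
  expect_equal(bg$n_samples, 2 * 2 * 2)

  # pool {-1, +1}: mean 0, population sd exactly 1
  f <- array(0, c(1, 2, 2)); f[1, 1, 2] <- 1; f[1, 2, 2] <- -1
  bg2 <- fit_background_model(irm_sequence(f, 5),
                              background_roi(c(1, 1, 1, 2)))
  expect_equal(bg2$mean, 0); expect_equal(bg2$sd, 1)

  # random pool matches the two-pass oracle
  s3 <- rand_stack(4, 5, 6, seed = 71)
  fam <- focal_activity_map(s3, platelet_roi("bg", c(1, 1, 3, 3)))
  bg3 <- fit_background_model(fam)
  ref <- oracle_mean_sd(as.numeric(fam$deltas))
  expect_equal(bg3$mean, unname(ref["mean"]))
  expect_equal(bg3$sd, unname(ref["sd"]))
})

test_that("active-pixel classification applies strict mean +/- k sd cuts", {
  s <- rand_stack(5, 5, 4, seed = 81)
  fam <- focal_activity_map(s)
  bg <- list(mean = 0, sd = 1000, n_samples = 10, roi = NULL)
  class(bg) <- "background_model"
  lab <- classify_active_pixels(fam, bg, k = 1)
  expect_false(any(lab$attach)); expect_false(any(lab$detach))

  # uniform delta far above the cut labels every pixel attach
  f <- array(100, c(3, 3, 2)); f[, , 2] <- 0
  fam2 <- focal_activity_map(irm_sequence(f, 5))
  bgn <- bg; bgn$sd <- 10
  lab2 <- classify_active_pixels(fam2, bgn, k = 1)
  expect_true(all(lab2$attach)); expect_false(any(lab2$detach))

  # attach and detach sets are disjoint and fractions complementary
  s3 <- rand_stack(6, 6, 10, seed = 82)
  fam3 <- focal_activity_map(s3)
  bg3 <- fit_background_model(fam3)
  lab3 <- classify_active_pixels(fam3, bg3, k = 1)
  expect_false(any(lab3$attach & lab3$detach))
  fr <- attach_detach_fractions(lab3)
  ok <- !is.na(fr$attach_fraction)
  expect_equal(fr$attach_fraction[ok] + fr$detach_fraction[ok],
               rep(1, sum(ok)))
  # counting oracle per frame
  hi <- bg3$mean + bg3$sd; lo <- bg3$mean - bg3$sd
  for (t in c(1, 5, 9)) {
    expect_equal(fr$n_attach[t], sum(fam3$deltas[, , t] > hi))
    expect_equal(fr$n_detach[t], sum(fam3$deltas[, , t] < lo))
  }
})

test_that("frames with no active pixels yield NA fractions, never 0/0", {
  f <- array(50, c(2, 2, 3))
  f[1, 1, 2:3] <- 47; f[2, 2, 2:3] <- 53  # one attach + one detach, frame 1;
                                          # frame 2 static -> no active pixels
  fam <- focal_activity_map(irm_sequence(f, 5))
  bg <- structure(list(mean = 0, sd = 1, n_samples = 9, roi = NULL),
                  class = "background_model")
  fr <- attach_detach_fractions(classify_active_pixels(fam, bg, k = 2))
  expect_equal(fr$attach_fraction[1], 0.5)
  expect_true(is.na(fr$attach_fraction[2]))
  expect_true(is.na(fr$detach_fraction[2]))

  # 3 attach + 1 detach -> 0.75 / 0.25
  f2 <- array(50, c(2, 2, 2))
  f2[, , 2] <- c(40, 40, 40, 60)
  fr2 <- attach_detach_fractions(classify_active_pixels(
    focal_activity_map(irm_sequence(f2, 5)), bg, k = 2))
  expect_equal(fr2$attach_fraction[1], 0.75)
  expect_equal(fr2$detach_fraction[1], 0.25)

  # roi denominator normalizes by box size instead
  fr3 <- attach_detach_fractions(classify_active_pixels(
    focal_activity_map(irm_sequence(f2, 5)), bg, k = 2),
    denominator = "roi")
  expect_equal(fr3$attach_fraction[1], 3 / 4)
  expect_equal(fr3$detach_fraction[1], 1 / 4)
})

test_that("active fraction of pure Gaussian noise matches 2 * pnorm(-1)", {
  # thresholds are +/- 1 sd of the same delta distribution by construction
  sim <- simulate_movie(scenario_preset("background_only", hover_duration = 120,
                                        seed = 5))
  fam <- focal_activity_map(sim$sequence)
  bg <- fit_background_model(fam)
  lab <- classify_active_pixels(fam, bg, k = 1)
  expect_equal(active_fraction(lab), 2 * pnorm(-1), tolerance = 0.02)
})

test_that("event overlays recolor exactly the labeled pixels", {
  s <- rand_stack(5, 5, 3, seed = 91)
  fam <- focal_activity_map(s)
  bg <- structure(list(mean = 0, sd = 1e6, n_samples = 9, roi = NULL),
                  class = "background_model")
  empty <- classify_active_pixels(fam, bg, k = 1)
  img <- render_event_overlay(s, empty, 1)
  expect_equal(img[, , 1], img[, , 2])   # pure grayscale
  expect_equal(img[, , 2], img[, , 3])

  one <- empty
  one$attach[2, 3, 1] <- TRUE
  img2 <- render_event_overlay(s, one, 1, attach_col = "red")
  expect_equal(img2[2, 3, ], c(1, 0, 0))
  changed <- which(img2 != img, arr.ind = TRUE)
  expect_true(all(changed[, 1] == 2 & changed[, 2] == 3))
  # writes a PNG when asked
  p <- tempfile(fileext = ".png")
  render_event_overlay(s, one, 1, path = p)
  expect_true(file.exists(p) && file.size(p) > 0)
})
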