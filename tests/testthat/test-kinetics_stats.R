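test_that("attachment curves are scaled empirical CDFs", {
  co <- cohort_table(platelet_id = c("a", "b"), substrate = "collagen_iv",
                     attachment_time = c(10, 30))
  got <- attachment_curve(co, "collagen_iv", c(5, 10, 30))
  expect_equal(got$percent_attached, c(0, 50, 100))
  expect_equal(attr(got, "n"), 2)

  # censored platelets never count as attached
  cens <- cohort_table(platelet_id = c("a", "b"), substrate = "fbg",
                       attachment_time = c(NA, NA), attached = FALSE,
                       horizon = 600)
  expect_equal(attachment_curve(cens, "fbg", c(10, 1000))$percent_attached,
               c(0, 0))
  expect_error(attachment_curve(co, "nope", 1), "no platelets")
  expect_error(attachment_curve(co, "collagen_iv", c(3, 2)), "increasing")

  # monotone, bounded, right-continuous in the large
  co2 <- simulate_attachment_cohort(seed = 3)
  g <- attachment_curve(co2, "collagen_iv", seq(0, 600, by = 5))
  expect_true(all(diff(g$percent_attached) >= 0))
  expect_true(all(g$percent_attached >= 0 & g$percent_attached <= 100))
})

test_that("empirical attachment curve recovers the generating CDF (DKW)", {
  n <- 500
  rate <- 1 / 40
  times <- withr::with_seed(17, stats::rexp(n, rate))
  co <- cohort_table(platelet_id = sprintf("p%d", 1:n), substrate = "s",
                     attachment_time = times)
  grid <- seq(5, 200, by = 5)
  got <- attachment_curve(co, "s", grid)$percent_attached / 100
  eps <- sqrt(log(2 / 0.05) / (2 * n))   # 95% DKW band
  expect_true(all(abs(got - stats::pexp(grid, rate)) <= eps))
})

test_that("phase durations come from stage frame differences", {
  a <- phase_annotation("p1", 1, 10, 40, 70, "fully_spread")
  b <- phase_annotation("p2", 1, 5, NA, NA, "filopodial")
  d <- phase_durations(list(a, b), frame_interval = 5)
  expect_equal(d$filopodial_duration, c((40 - 10) * 5, NA))
  expect_equal(d$lamellipodial_duration, c((70 - 40) * 5, NA))
  # absent stages are NA, never zero
  expect_true(is.na(d$filopodial_duration[2]))

  # batch of random annotations matches a per-record computation
  withr::with_seed(23, {
    anns <- lapply(1:20, function(i) {
      on <- sample(1:5, 1); fi <- on + sample(0:10, 1)
      la <- fi + sample(0:20, 1); sp <- la + sample(0:30, 1)
      phase_annotation(paste0("r", i), on, fi, la, sp, "fully_spread")
    })
    got <- phase_durations(anns, 2)
    ref_f <- vapply(anns, function(x)
      (x$lamellipodia_onset_frame - x$filopodia_onset_frame) * 2, numeric(1))
    ref_l <- vapply(anns, function(x)
      (x$spread_frame - x$lamellipodia_onset_frame) * 2, numeric(1))
    expect_equal(got$filopodial_duration, ref_f)
    expect_equal(got$lamellipodial_duration, ref_l)
  })
})

test_that("endpoint fractions sum to one and count correctly", {
  co <- cohort_table(platelet_id = letters[1:4], substrate = "s",
                     attachment_time = c(1, 2, 3, 4),
                     endpoint_class = c("filopodial", "filopodial",
                                        "filopodial", "fully_spread"))
  fr <- endpoint_fractions(co, "s")
  expect_equal(as.numeric(fr), c(0, 0.75, 0.25))
  expect_equal(sum(fr), 1)
  expect_equal(attr(fr, "n"), 4)
  single <- endpoint_fractions(co[4, , drop = FALSE])
  expect_equal(as.numeric(single), c(0, 0, 1))
  expect_error(endpoint_fractions(co, "none"), "empty group")
})

test_that("wilcoxon rank-sum: exact enumeration matches hand combinatorics", {
  # identical samples: no deviation, exact p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$p_value, 1)
  # most extreme of C(4,2) = 6 orderings, doubled
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$statistic, 1 + 2)
  # symmetric under group swap
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2))$p_value, 1 / 3)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("wilcoxon exact branch agrees with the reference implementation", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      a <- stats::rnorm(n1); b <- stats::rnorm(n2)   # tie-free a.s.
      mine <- wilcoxon_rank_sum(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$statistic - n1 * (n1 + 1) / 2,
                   unname(ref$statistic))
    }
  })
})

test_that("wilcoxon approximate branch tracks the reference with ties", {
  # the Edgeworth kurtosis term is the only difference from the textbook
  # tie- and continuity-corrected normal approximation; at these sizes it
  # moves p by well under half a percent
  withr::with_seed(37, {
    for (i in 1:10) {
      a <- sample(1:8, 30, replace = TRUE)
      b <- sample(1:8, 25, replace = TRUE) + sample(0:2, 25, replace = TRUE)
      mine <- wilcoxon_rank_sum(a, b)
      ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
      expect_lt(abs(mine$p_value - ref$p.value), 5e-3)
    }
  })
})

test_that("wilcoxon exact and approximate branches agree at the boundary", {
  # tie-free pooled n = 12, every achievable statistic for splits 3..9
  # (rank-equivalence: integer subsets of 1..12 cover all cases)
  worst <- 0
  for (n1 in 3:6) {
    combos <- utils::combn(12, n1)
    for (j in seq_len(ncol(combos))) {
      a <- combos[, j]; b <- setdiff(1:12, a)
      pe <- wilcoxon_rank_sum(a, b, exact = TRUE)$p_value
      pa <- wilcoxon_rank_sum(a, b, exact = FALSE)$p_value
      worst <- max(worst, abs(pe - pa))
    }
  }
  expect_lte(worst, 0.01)
})

test_that("wilcoxon is invariant under common monotone transforms", {
  withr::with_seed(43, {
    a <- stats::rexp(15); b <- stats::rexp(20, 0.5)
    p0 <- wilcoxon_rank_sum(a, b)$p_value
    expect_equal(wilcoxon_rank_sum(log(a), log(b))$p_value, p0)
    expect_equal(wilcoxon_rank_sum(a^3, b^3)$p_value, p0)
  })
  # large separated Gaussians: overwhelming evidence
  withr::with_seed(47, {
    a <- stats::rnorm(200); b <- stats::rnorm(200, 1)
    expect_lt(wilcoxon_rank_sum(a, b)$p_value, 1e-6)
  })
})

test_that("surrogate attachment frame needs a sustained area run", {
  expect_equal(detect_attachment_frame(c(0, 5, 25, 25, 25, 30)), 3L)
  expect_true(is.na(detect_attachment_frame(c(0, 25, 0, 25, 0, 25))))
  expect_true(is.na(detect_attachment_frame(c(0, 0))))
  expect_equal(detect_attachment_frame(rep(100, 10), min_pixels = 20), 1L)
})
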