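test_that("noiseless staircases are segmented exactly", {
  rate <- 1000
  lv <- c(0, 20, 40, 60, 80, 100) # 5 steps
  x <- rep(lv, times = c(300, 200, 400, 150, 250, 300))
  tr <- list(time = seq_along(x) / rate, extension = x)
  ev <- detect_steps(tr, expected_step = 20)
  expect_equal(nrow(ev), 5L)
  expect_equal(count_steps(ev), 5L)
  true_t <- cumsum(c(300, 200, 400, 150, 250))[1:5] / rate + 1 / rate
  expect_true(all(abs(ev$time - true_t) <= 1 / rate))
  expect_equal(ev$size, rep(20, 5), tolerance = 1e-9)

  flat <- list(time = seq_len(2000) / rate, extension = rep(3, 2000))
  expect_equal(nrow(detect_steps(flat, 20)), 0L)

  short <- list(time = (1:6) / rate, extension = rnorm(6))
  expect_error(detect_steps(short, 20), "shorter")
})

test_that("coincident unfolding events are recovered via multiplicity", {
  rate <- 1000
  x <- c(rep(0, 500), rep(40, 700), rep(60, 800)) # double step then single
  tr <- list(time = seq_along(x) / rate, extension = x + 0)
  ev <- detect_steps(tr, expected_step = 20)
  expect_equal(count_steps(ev), 3L)
  expect_equal(ev$multiplicity, c(2L, 1L))
})

test_that("detector precision and recall reach 0.99 at nominal noise", {
  pr <- force_quench_protocol(t_unfold = 8, t_q = 0, t_test = 0)
  cfg <- sim_config(n_recordings = 120, pickup_min = 6, noise_sd = 1,
                    seed = 11)
  sim <- simulate_experiment(ubiquitin_scheme(), pr, cfg)
  tp <- fp <- fn <- 0L
  for (i in seq_along(sim$traces)) {
    tr <- trace_pulse(sim$traces[[i]], "unfold")
    ev <- detect_steps(tr, expected_step = 20)
    det <- rep(ev$time, ev$multiplicity)
    truth <- true_unfold_times(tr)
    m <- match_events(det, truth)
    tp <- tp + m
    fp <- fp + length(det) - m
    fn <- fn + length(truth) - m
  }
  expect_gte(tp / (tp + fn), 0.99)
  expect_gte(tp / (tp + fp), 0.99)
})

test_that("P(u) analysis recovers the dwell rate and flags degenerate input", {
  # Monte-Carlo oracle: exponential dwells fed in directly as event lists
  set.seed(55)
  k <- 1.7
  evs <- lapply(1:1500, function(i) {
    tt <- sort(rexp(7, k))
    data.frame(time = tt, multiplicity = 1L)
  })
  uk <- unfolding_kinetics(evs, min_events = 6)
  expect_true(uk$fit$ok)
  expect_equal(uk$fit$rate, k, tolerance = 0.05)
  # curve is a normalized nondecreasing probability
  expect_true(all(diff(uk$curve$p_u) >= -1e-12))
  expect_equal(min(uk$curve$p_u), 0, tolerance = 1e-9)
  expect_equal(max(uk$curve$p_u), 1, tolerance = 1e-9)

  # single-event traces require relaxing the event filter
  expect_error(unfolding_kinetics(evs[1:3], min_events = 8), "events")
  one <- lapply(1:4000, function(i) data.frame(time = rexp(1, k),
                                               multiplicity = 1L))
  uk1 <- unfolding_kinetics(one, min_events = 1)
  expect_equal(uk1$fit$rate, k, tolerance = 0.05)

  # all events at t = 0: must report failure, not a number
  degen <- lapply(1:20, function(i) data.frame(time = rep(0, 6),
                                               multiplicity = 1L))
  expect_false(unfolding_kinetics(degen, min_events = 6)$fit$ok)
})

test_that("pooled refolding yield applies the quality filters", {
  full <- data.frame(steps_initial = c(6, 7), steps_test = c(6, 7),
                     final_ext_initial = c(120, 140),
                     final_ext_test = c(120, 140))
  expect_equal(refolding_yield(full, yield_qc(step_size = 20), B = 0)$yield, 1)
  none <- transform(full, steps_test = 0, final_ext_test = final_ext_initial)
  expect_equal(refolding_yield(none, yield_qc(step_size = 20), B = 0)$yield, 0)

  # hand-built oracle: (5/5 kept) + (4/6 fails extension QC) + (0/5 kept)
  d <- data.frame(steps_initial = c(5, 6, 5), steps_test = c(5, 4, 0),
                  final_ext_initial = c(100, 120, 100),
                  final_ext_test = c(100, 60, 100))
  ry <- refolding_yield(d, yield_qc(step_size = 20), B = 0)
  expect_equal(ry$yield, 0.5)
  expect_equal(ry$n_recordings, 2L)
  expect_equal(ry$n_domains, 10L)

  # recordings below five initial steps are dropped; all-fail errors
  d2 <- data.frame(steps_initial = c(3, 4), steps_test = c(3, 4),
                   final_ext_initial = c(60, 80), final_ext_test = c(60, 80))
  expect_error(refolding_yield(d2, yield_qc(step_size = 20), B = 0),
               "quality control")
  expect_error(refolding_yield(d2[0, ], yield_qc(), B = 0), "empty")
})

test_that("bootstrap SEM is seeded, unbiased against the binomial and scales as 1/sqrt(n)", {
  ident <- data.frame(steps_initial = rep(7, 10), steps_test = rep(4, 10))
  stat <- function(d) sum(d$steps_test) / sum(d$steps_initial)
  expect_equal(bootstrap_sem(ident, stat, B = 100, seed = 4), 0)
  expect_error(bootstrap_sem(ident, stat, B = 1), "B")
  expect_error(bootstrap_sem(ident[1, , drop = FALSE], stat, B = 10), "recordings")

  set.seed(66)
  p <- 0.6
  d <- data.frame(steps_initial = rep(5, 60),
                  steps_test = rbinom(60, 5, p))
  s1 <- bootstrap_sem(d, stat, B = 500, seed = 9)
  expect_identical(s1, bootstrap_sem(d, stat, B = 500, seed = 9))
  phat <- stat(d)
  binom_se <- sqrt(phat * (1 - phat) / 300)
  expect_lt(abs(s1 - binom_se) / binom_se, 0.25)

  big <- data.frame(steps_initial = rep(5, 240),
                    steps_test = rbinom(240, 5, p))
  s_small <- bootstrap_sem(big[1:40, ], stat, B = 400, seed = 2)
  s_large <- bootstrap_sem(big[1:160, ], stat, B = 400, seed = 2)
  expect_gt(s_small / s_large, 1.4) # ~2 expected for a 4x size ratio
  expect_lt(s_small / s_large, 2.9)
})

test_that("exponential yield-curve fits invert exact data and honour weights", {
  tq <- c(0.5, 1, 2, 5, 10, 15)
  ys <- 0.75 * (1 - exp(-0.52 * tq))
  fit <- fit_yield_curve(tq, ys, form = "saturating")
  expect_equal(fit$rate, 0.52, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.75, tolerance = 1e-6)

  te <- c(1, 2, 3, 5, 10, 15, 30)
  yd <- 0.10 + (0.65 - 0.10) * exp(-0.27 * te)
  fit <- fit_yield_curve(te, yd, form = "decaying")
  expect_equal(fit$rate, 0.27, tolerance = 1e-6)
  expect_equal(fit$offset, 0.10, tolerance = 1e-5)

  # equal SEMs reproduce the unweighted fit
  set.seed(8)
  yn <- pmin(pmax(yd + rnorm(7, 0, 0.03), 0), 1)
  f_u <- fit_yield_curve(te, yn, form = "decaying")
  f_w <- fit_yield_curve(te, yn, sems = rep(0.04, 7), form = "decaying")
  expect_equal(f_w$rate, f_u$rate, tolerance = 1e-6)

  # flat data: typed failure instead of a spurious rate
  flat <- fit_yield_curve(tq, rep(0.4, 6), form = "saturating")
  expect_false(flat$ok)
  expect_error(fit_yield_curve(1:2, c(0.1, 0.2)), "points")
})

test_that("detection-based yields equal count-based yields on noiseless traces", {
  # fold-competent scheme and a long quench keep collapsed remnants out of
  # the test pulse, whose half-step re-extensions are not staircase events
  sch <- dnaj_scheme(fold_competence = 1)
  pr <- force_quench_protocol(t_unfold = 6, t_q = 8, t_test = 6)
  cfg <- sim_config(n_recordings = 30, noise_sd = 0, seed = 23)
  sim <- simulate_experiment(sch, pr, cfg)
  det <- do.call(rbind, lapply(seq_along(sim$traces), function(i) {
    tr <- sim$traces[[i]]
    ev_i <- detect_steps(trace_pulse(tr, "unfold"), 20, min_dwell = 0.001)
    ev_t <- detect_steps(trace_pulse(tr, "test"), 20, min_dwell = 0.001)
    n_tail <- 20
    data.frame(steps_initial = count_steps(ev_i),
               steps_test = count_steps(ev_t),
               final_ext_initial = mean(tail(trace_pulse(tr, "unfold")$extension,
                                             n_tail)),
               final_ext_test = mean(tail(trace_pulse(tr, "test")$extension,
                                          n_tail)))
  }))
  qc <- yield_qc(step_size = 20)
  y_det <- refolding_yield(det, qc, B = 0)$yield
  y_cnt <- refolding_yield(sim$dataset, qc, B = 0)$yield
  expect_equal(y_det, y_cnt, tolerance = 1e-12)
})
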