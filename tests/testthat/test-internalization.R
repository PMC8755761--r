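test_that("quench statistic matches direct substitution and identities", {
  # full quench -> everything was on the surface
  expect_equal(as.numeric(percent_surface_quench(5, 105, 5)), 100)
  # quenching changed nothing -> everything internal
  expect_equal(as.numeric(percent_surface_quench(105, 105, 5)), 0)
  expect_equal(as.numeric(percent_surface_quench(55, 105, 5)), 50)
  expect_error(percent_surface_quench(10, 5, 5), "denominator")
  expect_error(percent_surface_quench(10, 5, 5, sample_label = "t=5min"),
               "t=5min")
  expect_error(percent_surface_quench(NA, 10, 1), "finite")
})

test_that("time-zero statistic matches direct substitution and identities", {
  expect_equal(as.numeric(percent_surface_timezero(110, 110, 10)), 100)
  expect_equal(as.numeric(percent_surface_timezero(10, 110, 10)), 0)
  expect_equal(as.numeric(percent_surface_timezero(60, 110, 10)), 50)
  expect_error(percent_surface_timezero(10, 5, 5), "denominator")
})

test_that("out-of-range values are flagged raw, clipped only on request", {
  p <- percent_surface_quench(120, 105, 5)     # noisy: F_Q > F_noQ
  expect_lt(as.numeric(p), 0)
  expect_true(attr(p, "out_of_range"))
  pc <- percent_surface_quench(120, 105, 5, clip = TRUE)
  expect_equal(as.numeric(pc), 0)
  expect_false(attr(pc, "out_of_range"))
})

test_that("both statistics are affine invariant and the quench statistic is monotone", {
  set.seed(31)
  for (i in 1:20) {
    F_bg <- runif(1, 0, 50)
    F_noQ <- F_bg + runif(1, 10, 500)
    F_Q <- runif(1, F_bg, F_noQ)
    a <- runif(1, 0.1, 10); b <- runif(1, -20, 20)
    p0 <- as.numeric(percent_surface_quench(F_Q, F_noQ, F_bg))
    p1 <- as.numeric(percent_surface_quench(a * F_Q + b, a * F_noQ + b,
                                            a * F_bg + b))
    expect_equal(p0, p1)
    p2 <- as.numeric(percent_surface_timezero(F_Q, F_noQ, F_bg))
    p3 <- as.numeric(percent_surface_timezero(a * F_Q + b, a * F_noQ + b,
                                              a * F_bg + b))
    expect_equal(p2, p3)
  }
  # increasing F_Q means less was quenched away, hence less on the surface
  fq <- seq(10, 100, 10)
  ps <- vapply(fq, function(q)
    as.numeric(percent_surface_quench(q, 105, 5)), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("a perfect-quench noise-free table inverts to the exact truth", {
  km <- kinetics_model(decay_delta = 0)
  sim <- simulate_flow_timecourse(km, quench_model(efficiency_q = 1),
                                  n_cells = 40,
                                  timepoints = c(0, 5, 15, 30),
                                  size_sdlog = 0, read_sd = 0, seed = 2)
  curve <- summarize_flow_table(sim$table)
  expect_s3_class(curve, "internalization_curve")
  expect_equal(curve$percent_internalized,
               100 * internalized_fraction(km, curve$timepoint_min),
               tolerance = 1e-9)
  expect_equal(curve$percent_surface + curve$percent_internalized,
               rep(100, nrow(curve)))
})

test_that("summaries error on unmatched timepoints, naming them", {
  sim <- simulate_flow_timecourse(n_cells = 10, timepoints = c(5, 15),
                                  seed = 1)
  tb <- sim$table
  tb <- tb[!(tb$timepoint_min %in% 15 & tb$quenched %in% 1), ]
  expect_error(summarize_flow_table(tb), "15")
})

test_that("quench and time-zero estimators agree when both apply", {
  # perfect quench, no decay: the quenched signal is the internal pool and
  # the surface pool equals unquenched - quenched, referenced to t = 0
  km <- kinetics_model(decay_delta = 0)
  sim <- simulate_flow_timecourse(km, quench_model(efficiency_q = 1),
                                  n_cells = 5000,
                                  timepoints = c(0, 5, 15, 30, 45),
                                  seed = 8)
  tb <- sim$table
  bg <- mean(tb$intensity[tb$group == "unstained"])
  eq1 <- summarize_flow_table(sim$table)
  # build the time-zero readout: F_x = surface staining = noQ - Q + bg
  tps <- sort(unique(tb$timepoint_min[tb$group == "stained"]))
  Fx <- vapply(tps, function(tp) {
    mn <- mean(tb$intensity[tb$timepoint_min %in% tp & tb$quenched %in% 0])
    mq <- mean(tb$intensity[tb$timepoint_min %in% tp & tb$quenched %in% 1])
    mn - mq + bg
  }, numeric(1))
  eq2 <- vapply(seq_along(tps), function(i)
    as.numeric(percent_surface_timezero(Fx[i], Fx[1], bg)), numeric(1))
  expect_lt(max(abs(eq1$percent_surface - eq2)), 1)
})

test_that("timezero mode summarizes a surface-stain table", {
  # surface staining at 0/15/30 min decays from 1000 to 700 to 400 over a
  # background of 100: 100%, 100*(700-100)/(1000-100), ...
  mk <- function(tp, level, id0)
    data.frame(cell_id = id0 + 1:20, timepoint_min = tp, quenched = 0,
               replicate = 1, intensity = level, group = "stained")
  tb <- rbind(mk(0, 1000, 0), mk(15, 700, 20), mk(30, 400, 40),
              data.frame(cell_id = 61:80, timepoint_min = NA, quenched = NA,
                         replicate = 1, intensity = 100,
                         group = "unstained"))
  curve <- summarize_flow_table(tb, mode = "timezero")
  expect_equal(curve$method, rep("timezero", 3))
  expect_equal(curve$percent_surface,
               c(100, 100 * 600 / 900, 100 * 300 / 900))
  # no time-0 group -> contract error
  expect_error(summarize_flow_table(tb[tb$timepoint_min %in% c(15, 30) |
                                         tb$group == "unstained", ],
                                    mode = "timezero"),
               "time-0")
})

test_that("kinetics fitting recovers the generating parameters", {
  km <- kinetics_model()
  tp <- c(0, 2, 5, 10, 15, 30, 45)
  curve <- data.frame(timepoint_min = tp,
                      percent_internalized =
                        100 * internalized_fraction(km, tp))
  fit <- fit_internalization_kinetics(curve)
  expect_true(fit$identifiable)
  expect_equal(fit$lag_min, 2, tolerance = 1e-3)
  expect_equal(fit$rate_k, 0.0327, tolerance = 1e-3)

  flat <- data.frame(timepoint_min = tp, percent_internalized = rep(0, 7))
  expect_false(fit_internalization_kinetics(flat)$identifiable)
  expect_error(fit_internalization_kinetics(curve[1:2, ]), "3 timepoints")
})

test_that("kinetics rate is recovered from a stochastic timecourse", {
  km <- kinetics_model(decay_delta = 0)
  sim <- simulate_flow_timecourse(km, quench_model(efficiency_q = 1),
                                  n_cells = 5000,
                                  timepoints = c(0, 5, 15, 30, 45),
                                  seed = 12)
  curve <- summarize_flow_table(sim$table)
  fit <- fit_internalization_kinetics(curve)
  expect_true(fit$identifiable)
  expect_equal(fit$rate_k, 0.0327, tolerance = 0.15)
})
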