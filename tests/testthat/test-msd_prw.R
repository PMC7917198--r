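test_that("anchored MSD matches analytic single-track cases", {
  v <- 3
  ball <- cohort(list(make_track(cbind(v * (0:10), 0))))
  m <- compute_msd(ball)
  expect_equal(m$msd, v^2 * m$lag^2)
  expect_equal(m$lag[1], 0)
  expect_equal(m$msd[1], 0)
  still <- cohort(list(make_track(matrix(2, 11, 2))))
  expect_equal(compute_msd(still)$msd, rep(0, 11))
})

test_that("anchored MSD equals the brute-force double-loop oracle", {
  set.seed(31)
  # three hand-built 4-frame tracks first
  co <- cohort(list(
    make_track(rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1)), id = "a"),
    make_track(rbind(c(0, 0), c(0, 2), c(0, 4), c(0, 6)), id = "b"),
    make_track(rbind(c(5, 5), c(5, 5), c(6, 5), c(8, 5)), id = "c")))
  m <- compute_msd(co)
  o <- oracle_msd_anchored(co, 3)
  expect_equal(m$msd[-1], o$msd)
  expect_equal(m$sem[-1], o$sem)
  expect_equal(m$n_cells[-1], o$n_cells)
  # and random cohorts, including ragged track lengths
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    co <- cohort(lapply(seq_len(n), function(i)
      random_track(n = sample(3:20, 1), id = paste0("r", i))))
    kmax <- max(vapply(co$tracks, function(t) max(t$frames), integer(1)))
    m <- compute_msd(co)
    o <- oracle_msd_anchored(co, kmax)
    expect_equal(m$msd[-1], o$msd)
    expect_equal(m$sem[-1], o$sem)
    expect_equal(m$n_cells[-1], o$n_cells)
  }
})

test_that("cells lacking a frame at some lag are excluded from that lag", {
  co <- cohort(list(
    make_track(cbind(0:4, 0), id = "full"),
    make_track(rbind(c(0, 0), c(1, 0), c(4, 0)), frames = c(0, 1, 4),
               id = "gappy")))
  m <- compute_msd(co)
  expect_equal(m$n_cells, c(2, 2, 1, 1, 2))  # lags 0,1,2,3,4
  expect_equal(m$msd[m$lag == 4], mean(c(16, 16)))
})

test_that("Fuerth closed-form round trip recovers v and tau exactly", {
  curve <- data.frame(lag = 1:80, msd = prw_msd(1:80, v = 10, tau = 5))
  f <- fit_prw(curve)
  expect_equal(f$v, 10, tolerance = 1e-6)
  expect_equal(f$tau, 5, tolerance = 1e-6)
  expect_equal(f$D, 250, tolerance = 1e-6)
  expect_false(f$tau_at_bound)
  # restricting to an 80-min window is the neutrophil-style default use
  f80 <- fit_prw(data.frame(lag = 1:120, msd = prw_msd(1:120, 10, 5)),
                 fit_window = 80)
  expect_equal(f80$n_lags, 80)
  expect_equal(f80$v, 10, tolerance = 1e-6)
})

test_that("Fuerth formula has ballistic and diffusive limits", {
  v <- 7; tau <- 50
  t_small <- tau / 100
  expect_equal(prw_msd(t_small, v, tau), v^2 * t_small^2, tolerance = 0.01)
  # large-t slope approaches 2 v^2 tau within 1% at t = 100 tau
  slope <- (prw_msd(100 * tau, v, tau) - prw_msd(99 * tau, v, tau)) / tau
  expect_equal(slope, 2 * v^2 * tau, tolerance = 0.01)
  # ballistic-limit fit: tau >> window means MSD ~ v^2 t^2 over the window
  curve <- data.frame(lag = 1:10, msd = prw_msd(1:10, v = 4, tau = 1e4))
  expect_equal(curve$msd, 16 * (1:10)^2, tolerance = 1e-3)
})

test_that("diffusivity follows D = v^2 tau / 2 and the large-t MSD slope", {
  expect_equal(diffusivity(10, 2), 100)
  expect_equal(diffusivity(0, 5), 0)
  expect_error(diffusivity(3, 0))
  # (1/(2n)) dMSD/dt with n = 2 at large t equals v^2 tau / 2
  v <- 6; tau <- 10
  slope <- (prw_msd(2000, v, tau) - prw_msd(1999, v, tau)) / 1
  expect_equal(slope / 4, diffusivity(v, tau), tolerance = 1e-9)
})

test_that("fit errors are informative on underpopulated windows", {
  curve <- data.frame(lag = 1:4, msd = prw_msd(1:4, 5, 5))
  expect_error(fit_prw(curve), ">= 5 positive lags")
})

test_that("simulated unbiased PRW cohorts recover the generative v and tau", {
  hits <- 0L
  for (s in 1:10) {
    co <- simulate_cohort(simulation_config(n_cells = 50, duration = 120,
                                            dt = 1, v_true = 6,
                                            tau_true = 10, seed = s))
    f <- fit_prw(compute_msd(co, anchored = FALSE), fit_window = 30)
    if (abs(f$v / 6 - 1) <= 0.10 && abs(f$tau / 10 - 1) <= 0.25)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("fitted D agrees with the empirical large-lag MSD slope over 4", {
  co <- simulate_cohort(simulation_config(n_cells = 200, duration = 120,
                                          v_true = 6, tau_true = 10,
                                          seed = 5))
  m <- compute_msd(co, anchored = FALSE)
  f <- fit_prw(m, fit_window = 30)
  tail_lags <- m$lag >= 60 & m$lag <= 100
  slope <- stats::coef(stats::lm(msd ~ lag, data = m[tail_lags, ]))[["lag"]]
  expect_equal(f$D, slope / 4, tolerance = 0.2)
})
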