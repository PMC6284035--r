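pulse_free_nh3 <- function() fixture("pulse_free_nh3", {
  p <- adm1_params()
  experiment_schedule("NH3", p, pulses = FALSE)
})

noise_free_obs <- function() fixture("noise_free_obs", {
  p <- adm1_params()
  sch <- pulse_free_nh3()
  generate_observations(p, sch, noise_model(cv = 0), seed = 11)
})

cal_base <- function() fixture("cal_base", {
  p <- adm1_params()
  sch <- pulse_free_nh3()
  list(params = p, schedule = sch,
       init = steady_state_init(p, sch, override_fitted = FALSE),
       rtol = 1e-8, atol = 1e-12, dt_out = 0.1)
})

test_that("objective is near zero at the generating truth and never negative", {
  obs <- noise_free_obs()
  base <- cal_base()
  truth <- c(X_pro1_0 = 0.004, K_S_pro1 = 0.34, K_I_nh3_pro1 = 0.4887,
             K_I_nh3_pro2 = 0.0036)
  sse <- sse_objective(truth, obs, "pro", base)
  expect_gte(sse, 0)
  expect_lt(sse, 1e-6)
  sse_ac <- sse_objective(c(X_ac1_0 = 0.05), obs, "ac", base)
  expect_lt(sse_ac, 1e-6)
})

test_that("objective is invariant to observation row order", {
  obs <- noise_free_obs()
  base <- cal_base()
  theta <- c(K_I_nh3_pro2 = 0.006)
  df <- obs$concentrations[, c("time", "acid", "value")]
  set.seed(3)
  shuffled <- df[sample.int(nrow(df)), ]
  expect_equal(sse_objective(theta, df, "pro", base),
               sse_objective(theta, shuffled, "pro", base))
})

test_that("perturbing the sensitive inhibition constant raises the objective", {
  obs <- noise_free_obs()
  base <- cal_base()
  at <- function(v) sse_objective(c(K_I_nh3_pro2 = v), obs, "pro", base)
  s_lo <- at(0.0036 * 0.5)
  s_tr <- at(0.0036)
  s_hi <- at(0.0036 * 1.5)
  expect_gt(s_lo, s_tr + 1e-4)
  expect_gt(s_hi, s_tr + 1e-4)
})

test_that("a failing simulation returns the documented penalty, not an error", {
  obs <- noise_free_obs()
  base <- cal_base()
  # a parameter set violating validation makes the simulation unrunnable
  bad <- c(K_S_pro1 = -1)
  v <- sse_objective(bad, obs, "pro", base)
  ser <- obs$concentrations
  zero_sse <- sum(ser$value[ser$acid == "pro"]^2)
  expect_equal(v, 1e6 * zero_sse)
})

test_that("sequential fitting is deterministic and freezes stage 1", {
  obs <- noise_free_obs()
  start <- c(X_pro1_0 = 0.008, K_S_pro1 = 0.2, K_I_nh3_pro1 = 0.2,
             K_I_nh3_pro2 = 0.007, X_ac1_0 = 0.03, K_S_ac1 = 0.2,
             K_I_nh3_ac1 = 0.2, K_I_nh3_ac2 = 0.003)
  spec <- calibration_spec(start = start, maxit = 2, multistart = 2,
                           seed = 9, rtol = 1e-5, atol = 1e-9, dt_out = 2)
  f1 <- fit_sequential(obs, spec, schedule = pulse_free_nh3())
  f2 <- fit_sequential(obs, spec, schedule = pulse_free_nh3())
  expect_identical(f1$stages$pro$estimate, f2$stages$pro$estimate)
  expect_identical(f1$stages$ac$estimate, f2$stages$ac$estimate)
  # stage-2 freezes stage-1 results: disjoint parameters, stage-1 estimates
  # present verbatim in the final parameter set
  expect_length(intersect(names(f1$stages$pro$estimate),
                          names(f1$stages$ac$estimate)), 0)
  for (nm in names(f1$stages$pro$estimate)) {
    expect_identical(f1$params[[nm]], unname(f1$stages$pro$estimate[[nm]]))
  }
  td <- tidy(f1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(f1)
  expect_equal(gl$seed, 9)
})
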