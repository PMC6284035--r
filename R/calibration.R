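#' Calibration specification for the sequential fit
#'
#' The eight free parameters of the study are estimated in two stages:
#' stage `"pro"` fits `X_pro1_0`, `K_S_pro1`, `K_I_nh3_pro1`, `K_I_nh3_pro2`
#' on the propionate series, stage `"ac"` then fits `X_ac1_0`, `K_S_ac1`,
#' `K_I_nh3_ac1`, `K_I_nh3_ac2` on the acetate series with the stage-1
#' results frozen. Parameters are optimized on a log10 scale (which enforces
#' positivity); default bounds span a factor 100 either side of the start.
#'
#' @param start named list/vector of start values for any of the eight
#'   parameters; defaults to the packaged parameter defaults.
#' @param lower,upper optional named bound overrides (natural scale).
#' @param maxit L-BFGS-B iteration cap per stage.
#' @param multistart number of starts per stage (1 = the given start only;
#'   additional starts are drawn log-uniformly within the bounds).
#' @param seed integer seed controlling the extra starts.
#' @param rtol,atol,dt_out integrator settings used inside the objective.
#' @return list of class `adm1_calspec`.
#' @export
calibration_spec <- function(start = NULL, lower = NULL, upper = NULL,
                             maxit = 60, multistart = 1, seed = 1,
                             rtol = 1e-7, atol = 1e-12, dt_out = 0.5) {
  base <- adm1_params()
  free <- list(
    pro = c("X_pro1_0", "K_S_pro1", "K_I_nh3_pro1", "K_I_nh3_pro2"),
    ac = c("X_ac1_0", "K_S_ac1", "K_I_nh3_ac1", "K_I_nh3_ac2")
  )
  all_free <- unlist(free, use.names = FALSE)
  st <- setNames(as.numeric(base[all_free]), all_free)
  if (!is.null(start)) {
    bad <- setdiff(names(start), all_free)
    if (length(bad)) abort(paste0("unknown free parameter(s): ", paste(bad, collapse = ", ")))
    st[names(start)] <- unlist(start)
  }
  lo <- st / 100; hi <- st * 100
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (any(lo <= 0)) abort("bounds must be strictly positive")
  if (any(st < lo | st > hi)) abort("start values must lie within the bounds")
  structure(list(free = free, start = st, lower = lo, upper = hi,
                 maxit = maxit, multistart = multistart, seed = seed,
                 rtol = rtol, atol = atol, dt_out = dt_out),
            class = "adm1_calspec")
}

obs_series <- function(obs, acid) {
  df <- if (inherits(obs, "adm1_obs")) obs$concentrations else obs
  stopifnot(all(c("time", "acid", "value") %in% names(df)))
  df <- df[df$acid == acid, c("time", "value")]
  df[order(df$time), ]
}

#' Sum-of-squares objective for one calibration stage
#'
#' Simulates the model with the candidate parameters, interpolates the
#' simulated acid concentration of the stage (`"pro"`: propionate, `"ac"`:
#' acetate) onto the observation times, and returns the unweighted sum of
#' squared deviations. A failed simulation returns the documented penalty
#' `1e6 * sum(obs^2)` (a million times the SSE of the all-zero model)
#' instead of raising, so bounded optimizers can continue.
#'
#' @param theta named vector of candidate parameter values (natural scale);
#'   any of the eight free parameters.
#' @param obs an [generate_observations()] result or a tibble with columns
#'   `time`, `acid` (`"ac"`, `"pro"`, `"bu"`), `value` (gCOD/L).
#' @param stage `"pro"` or `"ac"`.
#' @param base list with `params`, `schedule`, `init` (pre-override steady
#'   state) and integrator settings; see [fit_sequential()] for how it is
#'   assembled.
#' @return scalar SSE (>= 0).
#' @export
sse_objective <- function(theta, obs, stage = c("pro", "ac"), base) {
  stage <- match.arg(stage)
  ser <- obs_series(obs, stage)
  params <- base$params
  params[names(theta)] <- as.list(unname(theta))
  y0 <- base$init
  y0["X_ac1"] <- params$X_ac1_0
  y0["X_pro1"] <- params$X_pro1_0
  sim <- tryCatch(
    simulate_reactor(base$schedule, params, init = y0,
                     dt_out = base$dt_out %||% 0.5,
                     rtol = base$rtol %||% 1e-7, atol = base$atol %||% 1e-12),
    error = function(e) NULL
  )
  if (is.null(sim)) return(1e6 * sum(ser$value^2))
  col <- if (stage == "pro") "S_pro" else "S_ac"
  pred <- approx(sim$timeseries$time, sim$timeseries[[col]], ser$time)$y
  if (any(!is.finite(pred))) return(1e6 * sum(ser$value^2))
  sum((pred - ser$value)^2)
}

fit_stage <- function(stage, obs, spec, base) {
  free <- spec$free[[stage]]
  lo <- log10(spec$lower[free]); hi <- log10(spec$upper[free])
  ser_n <- nrow(obs_series(obs, stage))
  evals <- new.env(); evals$log <- list()
  obj <- function(lt) {
    th <- setNames(10^lt, free)
    v <- sse_objective(th, obs, stage, base)
    evals$log[[length(evals$log) + 1]] <- c(v)
    v
  }
  starts <- list(log10(spec$start[free]))
  if (spec$multistart > 1) {
    for (k in seq_len(spec$multistart - 1)) {
      starts[[k + 1]] <- lo + runif(length(free)) * (hi - lo)
    }
  }
  fits <- lapply(starts, function(s0) {
    tryCatch(
      optim(s0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = spec$maxit, factr = 1e9)),
      error = function(e) list(par = s0, value = Inf, convergence = 99)
    )
  })
  best <- fits[[which.min(vapply(fits, function(f) f$value, 0))]]
  list(stage = stage, estimate = setNames(10^best$par, free),
       sse = best$value, convergence = best$convergence,
       n_obs = ser_n, n_eval = length(evals$log),
       objective_trace = unlist(evals$log))
}

#' Sequential bounded least-squares calibration
#'
#' Stage 1 fits the propionate-side parameters on the propionate
#' concentration series; stage 2 fits the acetate-side parameters on the
#' acetate series with the stage-1 estimates frozen. Bounded local
#' minimization (L-BFGS-B on log10-parameters) with optional log-uniform
#' multistart; deterministic under a fixed seed. The steady-state initial
#' condition is computed once from the base parameters and reused, with the
#' candidate `X_ac1_0` / `X_pro1_0` overriding the two fitted slots.
#'
#' @param obs observations, see [sse_objective()].
#' @param spec an [calibration_spec()] object.
#' @param schedule the experiment schedule the observations were collected
#'   under (default the pulsed `NH3` variant).
#' @param params base parameter set for everything not being fitted.
#' @return object of class `adm1_fit`.
#' @export
fit_sequential <- function(obs, spec = calibration_spec(),
                           schedule = NULL, params = adm1_params()) {
  if (is.null(schedule)) {
    schedule <- if (inherits(obs, "adm1_obs")) obs$truth$schedule
                else experiment_schedule("NH3", params)
  }
  set.seed(spec$seed)
  init <- steady_state_init(params, schedule, override_fitted = FALSE)
  base <- list(params = params, schedule = schedule, init = init,
               rtol = spec$rtol, atol = spec$atol, dt_out = spec$dt_out)

  s1 <- fit_stage("pro", obs, spec, base)
  params2 <- params
  params2[names(s1$estimate)] <- as.list(unname(s1$estimate))
  base$params <- params2
  s2 <- fit_stage("ac", obs, spec, base)

  fitted <- params2
  fitted[names(s2$estimate)] <- as.list(unname(s2$estimate))
  if (!all(vapply(s1$estimate, function(v) v > 0, TRUE))) {
    abort("calibration failed: non-positive estimate")
  }
  structure(list(stages = list(pro = s1, ac = s2), params = fitted,
                 spec = spec, seed = spec$seed), class = "adm1_fit")
}

#' @export
print.adm1_fit <- function(x, ...) {
  cat("<adm1_fit> sequential two-stage calibration\n")
  for (s in x$stages) {
    cat(sprintf("  stage %-3s sse %.4g (%d obs, %d evaluations, convergence %d)\n",
                s$stage, s$sse, s$n_obs, s$n_eval, s$convergence))
  }
  print(tidy(x), n = 8)
  invisible(x)
}

#' @export
tidy.adm1_fit <- function(x, ...) {
  purrr::map_dfr(x$stages, function(s) {
    free <- names(s$estimate)
    tibble::tibble(
      parameter = free, estimate = unname(s$estimate), stage = s$stage,
      start = unname(x$spec$start[free]),
      lower = unname(x$spec$lower[free]), upper = unname(x$spec$upper[free])
    )
  })
}

#' @export
glance.adm1_fit <- function(x, ...) {
  tibble::tibble(
    sse_pro = x$stages$pro$sse, sse_ac = x$stages$ac$sse,
    convergence_pro = x$stages$pro$convergence,
    convergence_ac = x$stages$ac$convergence,
    n_eval = x$stages$pro$n_eval + x$stages$ac$n_eval,
    multistart = x$spec$multistart, seed = x$seed
  )
}

#' One-at-a-time parameter sensitivity scan
#'
#' Multiplies each scanned parameter by each factor, re-simulates, and
#' reports the headline target quantities ([sim_targets()]) and their
#' relative change against the factor-1 reference, plus the stage SSE
#' against observations when supplied.
#'
#' @param params base parameter set.
#' @param schedule experiment schedule.
#' @param parameters character vector of parameter names to scan.
#' @param factors positive multipliers (1 is added automatically as the
#'   reference).
#' @param obs optional observations for an SSE column (acetate-stage SSE).
#' @param init optional initial state (computed once if missing).
#' @param ... passed to [simulate_reactor()].
#' @return tibble: `parameter`, `factor`, target columns, `rel_change_*`
#'   columns, and `sse`/`delta_sse` when `obs` is given.
#' @export
sensitivity_scan <- function(params, schedule, parameters, factors,
                             obs = NULL, init = NULL, ...) {
  if (any(factors <= 0)) abort("factors must be positive")
  if (is.null(init)) init <- steady_state_init(params, schedule,
                                               override_fitted = FALSE)
  run_one <- function(par, fac) {
    p <- params
    if (!par %in% names(p)) abort(paste0("unknown parameter: ", par))
    p[[par]] <- p[[par]] * fac
    y0 <- init; y0["X_ac1"] <- p$X_ac1_0; y0["X_pro1"] <- p$X_pro1_0
    sim <- simulate_reactor(schedule, p, init = y0, ...)
    tg <- sim_targets(sim)
    sse <- if (!is.null(obs)) {
      ser <- obs_series(obs, "ac")
      pred <- approx(sim$timeseries$time, sim$timeseries$S_ac, ser$time)$y
      sum((pred - ser$value)^2)
    } else NA_real_
    cbind(tibble::tibble(parameter = par, factor = fac), tg,
          tibble::tibble(sse = sse))
  }
  ref <- run_one(parameters[1], 1)
  grid <- expand.grid(parameter = parameters,
                      factor = unique(c(1, factors)),
                      stringsAsFactors = FALSE)
  out <- purrr::pmap_dfr(grid, function(parameter, factor) {
    if (factor == 1) {
      r <- ref; r$parameter <- parameter; r
    } else {
      run_one(parameter, factor)
    }
  })
  tcols <- names(sim_targets_cols())
  for (cc in tcols) {
    out[[paste0("rel_change_", cc)]] <- out[[cc]] / ref[[cc]] - 1
  }
  out$delta_sse <- if (!is.null(obs)) out$sse - ref$sse else NA_real_
  tibble::as_tibble(out)
}

sim_targets_cols <- function() {
  c(peak_ac = NA, peak_pro = NA, ac_day55 = NA, abund_ac1_day55 = NA,
    pro_day62 = NA, abund_pro1_day62 = NA)
}
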