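#' Measurement noise model for synthetic observations
#'
#' Concentrations receive multiplicative lognormal noise parameterized so the
#' *median* equals the noise-free value (`meanlog = log(truth)`,
#' `sdlog = sqrt(log(1 + cv^2))`), then left-censoring at a detection floor.
#' Community compositions are resampled from a Dirichlet distribution whose
#' concentration parameters are the true composition times an effective
#' count, emulating the sampling spread of profiling-based relative
#' abundances.
#'
#' @param cv coefficient of variation of the concentration noise.
#' @param effective_counts Dirichlet concentration (larger = less noisy);
#'   `Inf` disables composition noise.
#' @param floor detection floor for concentrations (same unit as the series).
#' @return list of class `adm1_noise`.
#' @export
noise_model <- function(cv = 0.07, effective_counts = 200, floor = 0.01) {
  if (cv < 0) abort("cv must be >= 0")
  if (effective_counts <= 0) abort("effective_counts must be > 0")
  structure(list(cv = cv, effective_counts = effective_counts, floor = floor),
            class = "adm1_noise")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) rep(1 / length(alpha), length(alpha)) else g / sum(g)
}

#' Generate a synthetic observation set from a simulated truth
#'
#' Simulates the model (or reuses a supplied simulation), samples the VFA
#' concentrations and community compositions at the sampling times, and
#' corrupts them with the noise model. The generating truth (parameters,
#' schedule, noise-free values) is attached so recovery studies can compare
#' estimates against it.
#'
#' @param params generating parameter set.
#' @param schedule generating schedule.
#' @param noise an [noise_model()].
#' @param seed integer seed; identical seeds give identical observation sets.
#' @param times sampling times (d), default every 2 d over the horizon.
#' @param sim optional precomputed `adm1_sim` to sample from.
#' @return object of class `adm1_obs`: list with `concentrations` (tibble
#'   `time`, `acid`, `value`, `truth`, `censored`), `community` (tibble
#'   `time`, `panel`, `taxon`, `abundance`, `truth`), `noise`, `seed`,
#'   `censored_fraction` and `truth` (params + schedule).
#' @export
generate_observations <- function(params = adm1_params(),
                                  schedule = experiment_schedule("NH3", params),
                                  noise = noise_model(), seed = 1,
                                  times = NULL, sim = NULL) {
  if (is.null(sim)) sim <- simulate_reactor(schedule, params)
  ts <- sim$timeseries
  if (is.null(times)) times <- seq(0, max(ts$time), by = 2)
  times <- times[times >= min(ts$time) & times <= max(ts$time)]
  set.seed(seed)

  truth_at <- function(col) approx(ts$time, ts[[col]], times)$y
  conc <- tibble::tibble(
    time = rep(times, 3),
    acid = rep(c("ac", "pro", "bu"), each = length(times)),
    truth = c(truth_at("S_ac"), truth_at("S_pro"), truth_at("S_bu"))
  )
  sdlog <- sqrt(log(1 + noise$cv^2))
  conc$value <- if (noise$cv > 0) {
    conc$truth * rlnorm(nrow(conc), meanlog = 0, sdlog = sdlog)
  } else {
    conc$truth
  }
  conc$censored <- conc$value < noise$floor
  conc$value[conc$censored] <- noise$floor

  comm <- community_observation(sim, noise, seed = seed + 1, times = times)

  structure(list(concentrations = conc, community = comm, noise = noise,
                 seed = seed,
                 censored_fraction = mean(conc$censored),
                 truth = list(params = params, schedule = schedule)),
            class = "adm1_obs")
}

#' @export
print.adm1_obs <- function(x, ...) {
  cat("<adm1_obs>", length(unique(x$concentrations$time)), "sampling times,",
      sprintf("cv %.3g, %.1f%% censored\n", x$noise$cv,
              100 * x$censored_fraction))
  invisible(x)
}

#' Noisy community relative-abundance readout of a simulation
#'
#' Converts the simulated biomasses into two composition panels - methanogens
#' (`X_ac1`, `X_ac2`, `X_h2`) and bacteria (`X_su`, `X_aa`, `X_fa`, `X_c4`,
#' `X_pro1`, `X_pro2`) - and resamples each timepoint from a Dirichlet
#' distribution with concentration `truth * effective_counts`. Compositions
#' sum to 1 at every timepoint. A timepoint with all-zero biomass in a panel
#' yields the uniform composition with a warning.
#'
#' @param sim an `adm1_sim`.
#' @param noise an [noise_model()].
#' @param seed integer seed.
#' @param times sampling times (d).
#' @return tibble `time`, `panel`, `taxon`, `abundance`, `truth`.
#' @export
community_observation <- function(sim, noise = noise_model(), seed = 1,
                                  times = NULL) {
  ts <- sim$timeseries
  if (is.null(times)) times <- seq(0, max(ts$time), by = 2)
  set.seed(seed)
  panels <- list(
    methanogens = c("X_ac1", "X_ac2", "X_h2"),
    bacteria = c("X_su", "X_aa", "X_fa", "X_c4", "X_pro1", "X_pro2")
  )
  warned <- FALSE
  out <- purrr::map_dfr(names(panels), function(pn) {
    taxa <- panels[[pn]]
    truth_m <- vapply(taxa, function(cl) approx(ts$time, ts[[cl]], times)$y,
                      numeric(length(times)))
    truth_m <- matrix(truth_m, nrow = length(times),
                      dimnames = list(NULL, taxa))
    purrr::map_dfr(seq_along(times), function(i) {
      x <- pmax(truth_m[i, ], 0)
      if (sum(x) <= 0) {
        if (!warned) {
          warn(sprintf("all-zero %s biomass at t = %g; uniform composition used",
                       pn, times[i]))
          warned <<- TRUE
        }
        p_true <- rep(1 / length(x), length(x))
      } else {
        p_true <- x / sum(x)
      }
      ab <- if (is.finite(noise$effective_counts)) {
        rdirichlet1(p_true * noise$effective_counts)
      } else {
        p_true
      }
      tibble::tibble(time = times[i], panel = pn, taxon = names(x),
                     abundance = unname(ab), truth = unname(p_true))
    })
  })
  out
}
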