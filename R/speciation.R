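#' Non-competitive free-ammonia inhibition factor
#'
#' `I = 1 / (1 + S_nh3 / K_I)`: equals 1 without inhibitor, 0.5 when the free
#' ammonia concentration equals the inhibition constant, and decreases
#' monotonically towards 0. An infinite `K_I` disables the term (factor 1),
#' which is how the single-population structure drops the propionate ammonia
#' term.
#'
#' @param S_nh3 free ammonia concentration (M), >= 0.
#' @param K_I inhibition constant (M), > 0 (may be `Inf`).
#' @return inhibition factor in (0, 1].
#' @examples
#' ammonia_inhibition(0.0104, 0.0052) # one third
#' @export
ammonia_inhibition <- function(S_nh3, K_I) {
  if (any(!is.numeric(K_I)) || any(K_I <= 0)) {
    abort("K_I must be positive")
  }
  if (any(S_nh3 < 0)) abort("S_nh3 must be >= 0")
  ifelse(is.infinite(K_I), 1, 1 / (1 + S_nh3 / K_I))
}

#' Free ammonia from total ammonia nitrogen at a given pH
#'
#' Henderson-Hasselbalch split of total ammonia `S_IN` into NH3 and NH4+
#' using the van 't Hoff-corrected ammonium dissociation constant at the
#' model temperature.
#'
#' @param S_IN total ammonia nitrogen (M).
#' @param pH reactor pH.
#' @param params an [adm1_params()] list (supplies temperature).
#' @return free ammonia concentration (M).
#' @export
free_ammonia <- function(S_IN, pH, params = adm1_params()) {
  ab <- acid_base_constants(params)
  S_h <- 10^(-pH)
  S_IN * ab$K_a_IN / (ab$K_a_IN + S_h)
}

charge_balance_residual <- function(S_h, state, ab) {
  s <- state
  s[s < 0] <- 0
  s["S_cat"] + s["S_IN"] * S_h / (ab$K_a_IN + S_h) + S_h -
    s["S_an"] - ab$K_w / S_h -
    s["S_IC"] * ab$K_a_co2 / (ab$K_a_co2 + S_h) -
    s["S_ac"] / cod_per_mol["ac"] * ab$K_a_ac / (ab$K_a_ac + S_h) -
    s["S_pro"] / cod_per_mol["pro"] * ab$K_a_pro / (ab$K_a_pro + S_h) -
    s["S_bu"] / cod_per_mol["bu"] * ab$K_a_bu / (ab$K_a_bu + S_h) -
    s["S_va"] / cod_per_mol["va"] * ab$K_a_va / (ab$K_a_va + S_h)
}

#' Acid-base speciation of a reactor state
#'
#' Solves the ion charge balance for the proton concentration by scalar
#' root-finding (the balance is strictly increasing in `S_h`), then reports
#' pH, free ammonia, bicarbonate/CO2 split and the ionized VFA fractions.
#' Equilibrium constants are temperature-corrected via
#' [acid_base_constants()].
#'
#' @param state named numeric state vector (see `adm1_state_names`).
#' @param params an [adm1_params()] list.
#' @return list with `pH`, `S_h`, `S_nh3`, `S_nh4`, `S_hco3`, `S_co2`,
#'   `S_va_ion`, `S_bu_ion`, `S_pro_ion`, `S_ac_ion` (molar for ions) and the
#'   charge-balance `residual` (M).
#' @export
speciate <- function(state, params) {
  ab <- acid_base_constants(params)
  f <- function(h) charge_balance_residual(h, state, ab)
  # solve on the pH scale: a uniform x-tolerance there keeps the residual
  # near machine precision whether the root sits at pH 3 or pH 11
  g <- function(pH) f(10^-pH)
  if (!is.finite(g(12)) || !is.finite(g(2)) || g(12) > 0 || g(2) < 0) {
    abort("speciation failure: no sign change of the charge balance in pH (2, 12)")
  }
  root <- uniroot(g, c(2, 12), tol = 1e-13)
  S_h <- 10^-root$root
  s <- state
  s[s < 0] <- 0
  list(
    pH = -log10(S_h),
    S_h = S_h,
    S_nh3 = s[["S_IN"]] * ab$K_a_IN / (ab$K_a_IN + S_h),
    S_nh4 = s[["S_IN"]] * S_h / (ab$K_a_IN + S_h),
    S_hco3 = s[["S_IC"]] * ab$K_a_co2 / (ab$K_a_co2 + S_h),
    S_co2 = s[["S_IC"]] * S_h / (ab$K_a_co2 + S_h),
    S_va_ion = s[["S_va"]] / cod_per_mol[["va"]] * ab$K_a_va / (ab$K_a_va + S_h),
    S_bu_ion = s[["S_bu"]] / cod_per_mol[["bu"]] * ab$K_a_bu / (ab$K_a_bu + S_h),
    S_pro_ion = s[["S_pro"]] / cod_per_mol[["pro"]] * ab$K_a_pro / (ab$K_a_pro + S_h),
    S_ac_ion = s[["S_ac"]] / cod_per_mol[["ac"]] * ab$K_a_ac / (ab$K_a_ac + S_h),
    residual = f(S_h)
  )
}
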