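# Hill-type lower-pH inhibition used by the benchmark model: centred between
# the upper and lower pH limits with steepness 3 / (pH_UL - pH_LL).
ph_inhibition <- function(S_h, pH_UL, pH_LL) {
  K <- 10^(-(pH_UL + pH_LL) / 2)
  n <- 3 / (pH_UL - pH_LL)
  K^n / (S_h^n + K^n)
}

#' Biochemical process rates of the extended reaction system
#'
#' Monod uptake per population with the benchmark inhibition products:
#' fermentative uptakes carry `I_pH * I_IN`, LCFA/valerate/butyrate uptakes
#' additionally carry hydrogen inhibition, propionate uptake (both
#' populations) carries `I_pH * I_IN * I_h2 * I_nh3,i` (the ammonia term is
#' the model extension), acetoclastic uptake (both populations) carries
#' `I_pH * I_IN * I_nh3,i`, and hydrogenotrophic uptake `I_pH * I_IN`.
#' Negative concentrations are clipped to zero inside the rate evaluation
#' only.
#'
#' @param state named numeric state vector.
#' @param spec speciation of that state, from [speciate()].
#' @param params an [adm1_params()] list.
#' @return named numeric vector of process rates (one per column of the
#'   stoichiometry matrix, gCOD/L/d) with the inhibition factors attached as
#'   attribute `"inhibition"`.
#' @export
process_rates <- function(state, spec, params) {
  p <- params
  s <- state
  if (any(!is.finite(s))) abort("non-finite state in rate evaluation")
  s[s < 0] <- 0
  monod <- function(S, K) if (S <= 0) 0 else S / (K + S)

  I_pH_aa <- ph_inhibition(spec$S_h, p$pH_UL_aa, p$pH_LL_aa)
  I_pH_ac <- ph_inhibition(spec$S_h, p$pH_UL_ac, p$pH_LL_ac)
  I_pH_h2 <- ph_inhibition(spec$S_h, p$pH_UL_h2, p$pH_LL_h2)
  I_IN <- monod(s[["S_IN"]], p$K_S_IN)
  I_h2_fa <- 1 / (1 + s[["S_h2"]] / p$K_Ih2_fa)
  I_h2_c4 <- 1 / (1 + s[["S_h2"]] / p$K_Ih2_c4)
  I_h2_pro <- 1 / (1 + s[["S_h2"]] / p$K_Ih2_pro)
  I_nh3_ac1 <- ammonia_inhibition(spec$S_nh3, p$K_I_nh3_ac1)
  I_nh3_ac2 <- ammonia_inhibition(spec$S_nh3, p$K_I_nh3_ac2)
  I_nh3_pro1 <- ammonia_inhibition(spec$S_nh3, p$K_I_nh3_pro1)
  I_nh3_pro2 <- ammonia_inhibition(spec$S_nh3, p$K_I_nh3_pro2)

  # competitive split of the shared valerate/butyrate degrader
  frac_va <- if (s[["S_va"]] + s[["S_bu"]] <= 0) 0 else
    s[["S_va"]] / (s[["S_va"]] + s[["S_bu"]])
  frac_bu <- if (s[["S_va"]] + s[["S_bu"]] <= 0) 0 else
    s[["S_bu"]] / (s[["S_va"]] + s[["S_bu"]])

  rho <- c(
    dis = p$k_dis * s[["X_c"]],
    hyd_ch = p$k_hyd_ch * s[["X_ch"]],
    hyd_pr = p$k_hyd_pr * s[["X_pr"]],
    hyd_li = p$k_hyd_li * s[["X_li"]],
    up_su = p$k_m_su * monod(s[["S_su"]], p$K_S_su) * s[["X_su"]] *
      I_pH_aa * I_IN,
    up_aa = p$k_m_aa * monod(s[["S_aa"]], p$K_S_aa) * s[["X_aa"]] *
      I_pH_aa * I_IN,
    up_fa = p$k_m_fa * monod(s[["S_fa"]], p$K_S_fa) * s[["X_fa"]] *
      I_pH_aa * I_IN * I_h2_fa,
    up_va = p$k_m_c4 * monod(s[["S_va"]], p$K_S_c4) * s[["X_c4"]] * frac_va *
      I_pH_aa * I_IN * I_h2_c4,
    up_bu = p$k_m_c4 * monod(s[["S_bu"]], p$K_S_c4) * s[["X_c4"]] * frac_bu *
      I_pH_aa * I_IN * I_h2_c4,
    up_pro1 = p$k_m_pro1 * monod(s[["S_pro"]], p$K_S_pro1) * s[["X_pro1"]] *
      I_pH_aa * I_IN * I_h2_pro * I_nh3_pro1,
    up_pro2 = p$k_m_pro2 * monod(s[["S_pro"]], p$K_S_pro2) * s[["X_pro2"]] *
      I_pH_aa * I_IN * I_h2_pro * I_nh3_pro2,
    up_ac1 = p$k_m_ac1 * monod(s[["S_ac"]], p$K_S_ac1) * s[["X_ac1"]] *
      I_pH_ac * I_IN * I_nh3_ac1,
    up_ac2 = p$k_m_ac2 * monod(s[["S_ac"]], p$K_S_ac2) * s[["X_ac2"]] *
      I_pH_ac * I_IN * I_nh3_ac2,
    up_h2 = p$k_m_h2 * monod(s[["S_h2"]], p$K_S_h2) * s[["X_h2"]] *
      I_pH_h2 * I_IN,
    dec_X_su = p$k_dec * s[["X_su"]],
    dec_X_aa = p$k_dec * s[["X_aa"]],
    dec_X_fa = p$k_dec * s[["X_fa"]],
    dec_X_c4 = p$k_dec * s[["X_c4"]],
    dec_X_pro1 = p$k_dec * s[["X_pro1"]],
    dec_X_pro2 = p$k_dec * s[["X_pro2"]],
    dec_X_ac1 = p$k_dec * s[["X_ac1"]],
    dec_X_ac2 = p$k_dec * s[["X_ac2"]],
    dec_X_h2 = p$k_dec * s[["X_h2"]]
  )
  attr(rho, "inhibition") <- c(
    I_pH_aa = I_pH_aa, I_pH_ac = I_pH_ac, I_pH_h2 = I_pH_h2, I_IN = I_IN,
    I_h2_fa = I_h2_fa, I_h2_c4 = I_h2_c4, I_h2_pro = I_h2_pro,
    I_nh3_ac1 = I_nh3_ac1, I_nh3_ac2 = I_nh3_ac2,
    I_nh3_pro1 = I_nh3_pro1, I_nh3_pro2 = I_nh3_pro2
  )
  rho
}

#' Headspace gas flow from overpressure
#'
#' Linear overpressure law `q = k_p * (P_headspace - P_atm)` with the
#' headspace pressure assembled from the H2, CH4 and CO2 partial pressures
#' plus water vapour; flow is clipped at zero.
#'
#' @param state named numeric state vector (gas-phase components used).
#' @param params an [adm1_params()] list.
#' @return list with `q_gas` (L/d), `P_gas` (bar), partial pressures
#'   `p_h2`, `p_ch4`, `p_co2`, `p_h2o` (bar) and `q_ch4` (L CH4/d).
#' @export
gas_flow <- function(state, params) {
  ab <- acid_base_constants(params)
  s <- state
  s[s < 0] <- 0
  RT <- ab$Rgas * params$T_op
  p_h2 <- s[["S_gas_h2"]] * RT / 16
  p_ch4 <- s[["S_gas_ch4"]] * RT / 64
  p_co2 <- s[["S_gas_co2"]] * RT
  P_gas <- p_h2 + p_ch4 + p_co2 + ab$p_h2o
  q_gas <- max(0, params$k_p * (P_gas - params$P_atm))
  list(q_gas = q_gas, P_gas = P_gas, p_h2 = p_h2, p_ch4 = p_ch4,
       p_co2 = p_co2, p_h2o = ab$p_h2o,
       q_ch4 = if (P_gas > 0) q_gas * p_ch4 / P_gas else 0)
}
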