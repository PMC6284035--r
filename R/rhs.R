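#' Right-hand side of the extended reactor model (reference implementation)
#'
#' Full derivative of the CSTR state: dilution `(in - out)/HRT` for every
#' liquid component, biological conversion from the Petersen matrix and rate
#' vector, liquid-gas transfer for H2, CH4 and CO2, and the headspace balance
#' with overpressure-driven outflow. This pure-R version is the readable
#' module surface and the cross-check oracle for the compiled right-hand side
#' used by the integrator.
#'
#' @param t time (d); the influent must already be evaluated at `t`.
#' @param state named numeric state vector.
#' @param influent named numeric influent concentration vector (same layout).
#' @param params an [adm1_params()] list.
#' @param stoich optional precomputed [adm1_stoichiometry()] result.
#' @param dilution dilution rate (1/d); defaults to `1/HRT`, set to 0 while
#'   feeding is suspended after a pulse disturbance.
#' @return list: `dstate` (named derivative vector), `aux` (pH, free ammonia,
#'   gas flow, partial pressures, transfer rates).
#' @export
adm1_rhs <- function(t, state, influent, params,
                     stoich = adm1_stoichiometry(params),
                     dilution = 1 / params$HRT) {
  if (any(!is.finite(state))) abort("non-finite state passed to adm1_rhs")
  p <- params
  ab <- acid_base_constants(p)
  spec <- speciate(state, p)
  rho <- process_rates(state, spec, p)
  bio <- drop(stoich$nu %*% rho)

  s <- state
  s[s < 0] <- 0
  gs <- gas_flow(state, p)

  # liquid-gas transfer (gCOD/L/d for h2, ch4; M/d for co2)
  rT_h2 <- p$k_L_a * (s[["S_h2"]] - 16 * ab$K_H_h2 * gs$p_h2)
  rT_ch4 <- p$k_L_a * (s[["S_ch4"]] - 64 * ab$K_H_ch4 * gs$p_ch4)
  rT_co2 <- p$k_L_a * (spec$S_co2 - ab$K_H_co2 * gs$p_co2)

  d <- dilution * (influent - state) + bio
  d[["S_h2"]] <- d[["S_h2"]] - rT_h2
  d[["S_ch4"]] <- d[["S_ch4"]] - rT_ch4
  d[["S_IC"]] <- d[["S_IC"]] - rT_co2

  # gas phase: no dilution; transfer in, overpressure outflow
  gas_names <- c("S_gas_h2", "S_gas_ch4", "S_gas_co2")
  d[gas_names] <- -state[gas_names] * gs$q_gas / p$V_gas +
    c(rT_h2, rT_ch4, rT_co2) * p$V_liq / p$V_gas

  list(
    dstate = d,
    aux = c(pH = spec$pH, S_nh3 = spec$S_nh3, S_hco3 = spec$S_hco3,
            q_gas = gs$q_gas, q_ch4 = gs$q_ch4, P_gas = gs$P_gas,
            rT_h2 = rT_h2, rT_ch4 = rT_ch4, rT_co2 = rT_co2)
  )
}
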