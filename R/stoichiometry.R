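#' Petersen stoichiometry matrix with carbon and nitrogen closure
#'
#' Builds the yield-coefficient matrix nu (components x processes) of the
#' extended reaction system: disintegration, hydrolysis, the seven
#' fermentative/acetogenic uptakes (with propionate uptake carried by two
#' competing populations), two acetoclastic uptakes, hydrogenotrophic
#' methanogenesis, and nine biomass decay processes. The inorganic-carbon and
#' inorganic-nitrogen rows are computed as closure terms, so that every
#' process column conserves elemental C and N exactly:
#' `nu[S_IC, j] = -sum_i C_i nu[i, j]` and likewise for N.
#'
#' @param params an [adm1_params()] list.
#' @return list with `nu` (31 x 23 matrix, rows named by state, columns by
#'   process), and the per-component composition vectors `cod`, `carbon`
#'   (mol C / gCOD, 1 for S_IC) and `nitrogen` (mol N / gCOD, 1 for S_IN).
#' @export
adm1_stoichiometry <- function(params) {
  p <- params
  ns <- adm1_state_names
  np <- adm1_process_names
  nu <- matrix(0, length(ns), length(np), dimnames = list(ns, np))

  set <- function(j, ...) {
    v <- c(...)
    nu[names(v), j] <<- v
  }

  set("dis", X_c = -1, S_I = p$f_sI_xc, X_ch = p$f_ch_xc, X_pr = p$f_pr_xc,
      X_li = p$f_li_xc, X_I = p$f_xI_xc)
  set("hyd_ch", X_ch = -1, S_su = 1)
  set("hyd_pr", X_pr = -1, S_aa = 1)
  set("hyd_li", X_li = -1, S_fa = p$f_fa_li, S_su = 1 - p$f_fa_li)

  set("up_su", S_su = -1, X_su = p$Y_su,
      S_bu = (1 - p$Y_su) * p$f_bu_su, S_pro = (1 - p$Y_su) * p$f_pro_su,
      S_ac = (1 - p$Y_su) * p$f_ac_su, S_h2 = (1 - p$Y_su) * p$f_h2_su)
  set("up_aa", S_aa = -1, X_aa = p$Y_aa,
      S_va = (1 - p$Y_aa) * p$f_va_aa, S_bu = (1 - p$Y_aa) * p$f_bu_aa,
      S_pro = (1 - p$Y_aa) * p$f_pro_aa, S_ac = (1 - p$Y_aa) * p$f_ac_aa,
      S_h2 = (1 - p$Y_aa) * p$f_h2_aa)
  set("up_fa", S_fa = -1, X_fa = p$Y_fa,
      S_ac = (1 - p$Y_fa) * 0.7, S_h2 = (1 - p$Y_fa) * 0.3)
  set("up_va", S_va = -1, X_c4 = p$Y_c4,
      S_pro = (1 - p$Y_c4) * 0.54, S_ac = (1 - p$Y_c4) * 0.31,
      S_h2 = (1 - p$Y_c4) * 0.15)
  set("up_bu", S_bu = -1, X_c4 = p$Y_c4,
      S_ac = (1 - p$Y_c4) * 0.8, S_h2 = (1 - p$Y_c4) * 0.2)
  set("up_pro1", S_pro = -1, X_pro1 = p$Y_pro1,
      S_ac = (1 - p$Y_pro1) * 0.57, S_h2 = (1 - p$Y_pro1) * 0.43)
  set("up_pro2", S_pro = -1, X_pro2 = p$Y_pro2,
      S_ac = (1 - p$Y_pro2) * 0.57, S_h2 = (1 - p$Y_pro2) * 0.43)
  set("up_ac1", S_ac = -1, X_ac1 = p$Y_ac1, S_ch4 = 1 - p$Y_ac1)
  set("up_ac2", S_ac = -1, X_ac2 = p$Y_ac2, S_ch4 = 1 - p$Y_ac2)
  set("up_h2", S_h2 = -1, X_h2 = p$Y_h2, S_ch4 = 1 - p$Y_h2)

  decays <- c(dec_X_su = "X_su", dec_X_aa = "X_aa", dec_X_fa = "X_fa",
              dec_X_c4 = "X_c4", dec_X_pro1 = "X_pro1", dec_X_pro2 = "X_pro2",
              dec_X_ac1 = "X_ac1", dec_X_ac2 = "X_ac2", dec_X_h2 = "X_h2")
  for (j in names(decays)) {
    nu[decays[[j]], j] <- -1
    nu["X_c", j] <- 1
  }

  carbon <- setNames(numeric(length(ns)), ns)
  carbon[c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac", "S_ch4",
           "S_I", "X_c", "X_ch", "X_pr", "X_li", "X_I")] <-
    c(p$C_su, p$C_aa, p$C_fa, p$C_va, p$C_bu, p$C_pro, p$C_ac, p$C_ch4,
      p$C_sI, p$C_xc, p$C_ch, p$C_pr, p$C_li, p$C_xI)
  carbon[c("X_su", "X_aa", "X_fa", "X_c4", "X_pro1", "X_pro2",
           "X_ac1", "X_ac2", "X_h2")] <- p$C_bac
  carbon["S_IC"] <- 1

  nitrogen <- setNames(numeric(length(ns)), ns)
  nitrogen[c("S_aa", "X_pr")] <- p$N_aa
  nitrogen[c("S_I", "X_I")] <- p$N_I
  nitrogen["X_c"] <- p$N_xc
  nitrogen[c("X_su", "X_aa", "X_fa", "X_c4", "X_pro1", "X_pro2",
             "X_ac1", "X_ac2", "X_h2")] <- p$N_bac
  nitrogen["S_IN"] <- 1

  cod <- setNames(numeric(length(ns)), ns)
  cod[c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac", "S_h2",
        "S_ch4", "S_I", "X_c", "X_ch", "X_pr", "X_li", "X_su", "X_aa",
        "X_fa", "X_c4", "X_pro1", "X_pro2", "X_ac1", "X_ac2", "X_h2",
        "X_I")] <- 1

  # elemental closure: the S_IC / S_IN rows absorb whatever C / N the organic
  # conversions release or take up, making every column conserve C and N
  nu["S_IC", ] <- -colSums(nu[ns != "S_IC", , drop = FALSE] *
                             carbon[ns != "S_IC"])
  nu["S_IN", ] <- -colSums(nu[ns != "S_IN", , drop = FALSE] *
                             nitrogen[ns != "S_IN"])

  list(nu = nu, cod = cod, carbon = carbon, nitrogen = nitrogen)
}

#' Index set of acetate-producing processes
#'
#' The uptake processes whose stoichiometry produces acetate: sugars, amino
#' acids, LCFA, valerate, butyrate, and propionate (both competing
#' populations). Used by the acetate balance and by the efficiency
#' production-credit bookkeeping.
#' @return character vector of process names.
#' @export
acetate_producing_processes <- function() {
  c("up_su", "up_aa", "up_fa", "up_va", "up_bu", "up_pro1", "up_pro2")
}
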