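# Independent step-by-step evaluation of the one-day degradation balance,
# written as a plain loop over sampling dates, deliberately separate from the
# vectorized pipeline in the package.
oracle_efficiency <- function(df, inf, hrt, basis, dt = 1) {
  f <- conversion_factors(basis)
  interp <- function(tt, col) approx(df$time, df[[col]], tt)$y
  out <- NULL
  for (t in df$time) {
    if (t - dt < df$time[1]) next
    E <- list()
    for (acid in c("pro", "bu")) {
      col <- paste0("S_", acid)
      S_in <- inf[[col]]
      St <- interp(t, col); Sl <- interp(t - dt, col)
      dSout <- (St + Sl) / 2 / hrt * dt
      dS <- St - Sl
      E[[acid]] <- (S_in / hrt * dt - dSout - dS) / (S_in / hrt * dt)
    }
    credit <- inf[["S_pro"]] / hrt * dt * E$pro * f[["f_ac_pro"]] +
      inf[["S_bu"]] / hrt * dt * E$bu * f[["f_ac_bu"]]
    St <- interp(t, "S_ac"); Sl <- interp(t - dt, "S_ac")
    dSout <- (St + Sl) / 2 / hrt * dt
    dS <- St - Sl
    E$ac <- (inf[["S_ac"]] / hrt * dt - dSout + credit - dS) /
      (inf[["S_ac"]] / hrt * dt + credit)
    out <- rbind(out, data.frame(time = t, E_ac = E$ac, E_pro = E$pro,
                                 E_bu = E$bu, dS_ac_p = credit))
  }
  out
}
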