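# Expensive shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

default_params <- function(...) adm1_params(...)

nh3_sim <- function() fixture("nh3_sim", {
  p <- adm1_params()
  simulate_reactor(experiment_schedule("NH3", p), p)
})

ctrl_sim <- function() fixture("ctrl_sim", {
  p <- adm1_params()
  simulate_reactor(experiment_schedule("ctrl", p), p)
})

base_init <- function() fixture("base_init", {
  p <- adm1_params()
  steady_state_init(p, experiment_schedule("ctrl", p))
})

# influent VFA concentrations (gCOD/L) of the experiment
vfa_influent <- c(S_ac = 16.74, S_pro = 3.72, S_bu = 16.74)
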