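# Typical parameter points (rates in events/ms; times in ms) used across
# the suite: rates of 40-80 Hz, an indecision half-width of ~20 ms and a
# reset window of ~15 ms with ~18 ms spread.
pars_simple <- c(vp = 0.06, vr = 0.04, tau = 0)
pars_ind <- c(vp = 0.05, vr = 0.05, delta = 20, xi = 0.5, tau = 0)
pars_reset <- c(vp = 0.06, vr = 0.04, t0 = 15, s0 = 18, tau = 0)

# small design for fast fitting tests
small_design <- function(reps = 60) {
  toj_design(soas = seq(-100, 100, by = 20), repetitions = reps,
             label = "small")
}

# random valid parameter draw inside the fitting bounds
random_params <- function(model) {
  p <- c(vp = runif(1, 0.01, 0.2), vr = runif(1, 0.01, 0.2))
  extra <- switch(model,
    simple = c(tau = runif(1, -50, 50)),
    indecision = c(delta = runif(1, 0, 60), xi = runif(1),
                   tau = runif(1, -50, 50)),
    reset = c(t0 = runif(1, 0, 60), s0 = runif(1, 1, 40),
              tau = runif(1, -50, 50)))
  c(p, extra)
}
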