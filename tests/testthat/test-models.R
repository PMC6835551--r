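test_that("percept probabilities are a proper partition", {
  pp <- percept_probs(c(vp = 0.05, vr = 0.05, delta = 20),
                      soa = seq(-100, 100, by = 10))
  expect_true(all(pp$probe_first >= 0 & pp$simultaneous >= -1e-12 &
                    pp$reference_first >= 0))
  expect_equal(pp$probe_first + pp$simultaneous + pp$reference_first,
               rep(1, nrow(pp)), tolerance = 1e-12)
})

test_that("percept probabilities match frozen values at SOA 0", {
  # 0.5 * exp(-1) at +/- delta for equal rates 0.05/ms, delta 20 ms
  pp <- percept_probs(c(vp = 0.05, vr = 0.05, delta = 20), soa = 0)
  expect_equal(pp$probe_first, 0.183939721, tolerance = 1e-8)
  expect_equal(pp$simultaneous, 0.632120559, tolerance = 1e-8)
  expect_equal(pp$reference_first, 0.183939721, tolerance = 1e-8)

  # zero-width range: no simultaneity percepts
  pp0 <- percept_probs(c(vp = 0.05, vr = 0.05, delta = 0), soa = 0)
  expect_equal(pp0$simultaneous, 0, tolerance = 1e-12)
  # infinite range: everything is simultaneous
  ppI <- percept_probs(c(vp = 0.05, vr = 0.05, delta = 1e6), soa = 0)
  expect_equal(ppI$simultaneous, 1, tolerance = 1e-9)
})

test_that("indecision-model response probability matches frozen value", {
  expect_equal(
    toj_prob("indecision", c(vp = 0.05, vr = 0.05, delta = 20, xi = 0.3),
             soa = 0),
    0.626424112, tolerance = 1e-8)
  # neutral bias with equal rates pins the plateau at 0.5
  expect_equal(toj_prob("indecision", pars_ind, soa = 0), 0.5,
               tolerance = 1e-12)
})

test_that("xi is inert when the indecision range has zero width", {
  s <- seq(-100, 100, by = 10)
  for (xi in c(0, 0.3, 0.9)) {
    expect_equal(
      toj_prob("indecision",
               c(vp = 0.06, vr = 0.04, delta = 0, xi = xi), s),
      toj_prob("simple", c(vp = 0.06, vr = 0.04), s), tolerance = 1e-12)
  }
})

test_that("indecision plateau height follows the percept decomposition", {
  for (i in 1:5) {
    set.seed(i)
    p <- random_params("indecision")
    at_plateau <- toj_prob("indecision", p, soa = -p[["tau"]])
    pf <- race_prob(p[["vp"]], p[["vr"]], p[["delta"]])
    pb <- race_prob(p[["vp"]], p[["vr"]], -p[["delta"]])
    expect_equal(at_plateau, pf + (1 - p[["xi"]]) * (pb - pf),
                 tolerance = 1e-12)
  }
  # with equal rates the plateau moves linearly in xi, rates held fixed
  h <- vapply(c(0.2, 0.5, 0.8), function(xi)
    toj_prob("indecision",
             c(vp = 0.05, vr = 0.05, delta = 25, xi = xi), 0), numeric(1))
  expect_equal(diff(h)[1], diff(h)[2], tolerance = 1e-12)
  expect_lt(h[3], h[1])
})

test_that("reset weight matches the normal-CDF closed form", {
  # branch boundary: both sides give pnorm(t0/s0) at soa + tau = 0
  p <- pars_reset
  expect_equal(reset_prob(p, 0), pnorm(15 / 18), tolerance = 1e-12)
  expect_equal(reset_prob(p, -1e-9), reset_prob(p, 1e-9),
               tolerance = 1e-7)
  # frozen value pnorm(-5/6) at soa -30
  expect_equal(reset_prob(p, -30), 0.202328381, tolerance = 1e-8)
  # widely separated onsets never reset
  expect_equal(reset_prob(p, c(-2000, 2000)), c(0, 0), tolerance = 1e-12)
})

test_that("reset-model response probability matches frozen value", {
  expect_equal(toj_prob("reset", pars_reset, -30), 0.866326955,
               tolerance = 1e-8)
  # at soa + tau = 0 the value is the Luce ratio regardless of t0, s0
  for (t0 in c(1, 15, 80)) for (s0 in c(0.5, 18)) {
    expect_equal(
      toj_prob("reset", c(vp = 0.06, vr = 0.04, t0 = t0, s0 = s0), 0),
      0.6, tolerance = 1e-12)
  }
  # plateau is displaced from 0.5 only through unequal rates
  expect_equal(toj_prob("reset",
                        c(vp = 0.05, vr = 0.05, t0 = 15, s0 = 18), 0),
               0.5, tolerance = 1e-12)
})

test_that("reset model with t0 = 0, s0 = 0 reduces to the simple race", {
  s <- seq(-200, 200, by = 0.5)
  expect_equal(
    toj_prob("reset", c(vp = 0.06, vr = 0.04, t0 = 0, s0 = 0), s),
    toj_prob("simple", c(vp = 0.06, vr = 0.04), s), tolerance = 1e-9)
})

test_that("all model curves stay in [0,1] and are non-increasing", {
  s <- seq(-250, 250, by = 1)
  for (model in toj_models()) {
    for (i in 1:8) {
      set.seed(100 + i)
      p <- random_params(model)
      prob <- toj_prob(model, p, s)
      expect_true(all(prob >= 0 & prob <= 1))
      expect_true(all(diff(prob) <= 1e-12))
    }
  }
})

test_that("tau shifts every model curve along the SOA axis", {
  s <- seq(-80, 80, by = 10)
  shift <- 25
  for (model in toj_models()) {
    p0 <- switch(model, simple = pars_simple, indecision = pars_ind,
                 reset = pars_reset)
    p1 <- replace(p0, "tau", shift)
    expect_equal(toj_prob(model, p1, s - shift), toj_prob(model, p0, s),
                 tolerance = 1e-12)
  }
})

test_that("invalid model parameters are rejected", {
  expect_error(toj_prob("indecision",
                        c(vp = 0.05, vr = 0.05, delta = -1, xi = 0.5), 0),
               "delta")
  expect_error(toj_prob("indecision",
                        c(vp = 0.05, vr = 0.05, delta = 5, xi = 1.2), 0),
               "xi")
  expect_error(toj_prob("reset",
                        c(vp = 0.05, vr = 0.05, t0 = 10, s0 = -2), 0),
               "s0")
  expect_error(toj_prob("simple", c(vp = 0.05), 0), "missing")
  expect_error(toj_prob("banana", pars_simple, 0))
})
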