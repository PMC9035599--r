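test_that("single-probe probabilities match direct arithmetic", {
  probs <- fig6_probs()

  # non-engaging partner with zero base rate is undetectable
  z <- detection_probs(0, 0.1, 0, 0.35)
  expect_equal(p_L(encounter_params(0), z), 0)

  expect_equal(p_L(encounter_params(1), probs), 0.1 / 3)
  expect_equal(p_L(encounter_params(0.5), probs), (0.5 * 0.04 + 0.5 * 0.1) / 3)
  expect_equal(p_M(encounter_params(1), probs), 0.35 / 3)
  expect_equal(p_M(encounter_params(0.5), probs),
               (0.5 * 0.04 + 0.5 * 0.35) / 3)

  # against a never-engaging partner the two strategies coincide (reduced form)
  expect_equal(p_M(encounter_params(0), probs), p_L(encounter_params(0), probs))

  # vectorized alpha
  expect_equal(p_L(encounter_params(c(0, 1)), probs), c(0.04 / 3, 0.1 / 3))
})

test_that("compounded probabilities: endpoints, tau = 1 identity, closed form", {
  probs <- fig6_probs()
  expect_equal(P_L(encounter_params(1, tau = 1), probs),
               p_L(encounter_params(1, tau = 1), probs))
  expect_equal(P_L(encounter_params(0), detection_probs(0, 0, 0, 0)), 0)
  expect_equal(P_L(encounter_params(1, tau = 5, prior = 1),
                   detection_probs(1, 1, 1, 1)), 1)

  expect_equal(P_L(encounter_params(1, tau = 3), probs), 1 - (29 / 30)^3)

  # P_M is definitionally p_M
  a <- encounter_params(c(0, 0.3, 1), tau = 4)
  expect_identical(P_M(a, probs), p_M(a, probs))
  expect_equal(P_M(encounter_params(0), probs), 0.04 / 3)
})

test_that("closed form agrees with the explicit geometric series", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      p <- runif(1)
      tau <- sample(1:20, 1)
      expect_lt(abs(series_P_L(p, tau) - (1 - (1 - p)^tau)), 1e-12)
    }
  })
})

test_that("P_L dominates p_L strictly unless tau = 1 or p degenerate", {
  probs <- fig6_probs()
  a <- encounter_params(0.7, tau = 3)
  expect_gt(P_L(a, probs), p_L(a, probs))
  a1 <- encounter_params(0.7, tau = 1)
  expect_equal(P_L(a1, probs), p_L(a1, probs))
})

test_that("benefit of engaging: signs at the canonical parameter set", {
  probs <- fig6_probs()
  expect_lt(benefit_g(encounter_params(0, tau = 3), probs), 0)
  expect_gt(benefit_g(encounter_params(1, tau = 3), probs), 0)
  expect_equal(benefit_g(encounter_params(1, tau = 3), probs),
               0.35 / 3 - (1 - (29 / 30)^3))

  # symmetric strategies with no compounding: zero benefit for all alpha
  sym <- detection_probs(0.05, 0.2, 0.05, 0.2)
  expect_equal(benefit_g(encounter_params(seq(0, 1, 0.1), tau = 1), sym),
               rep(0, 11))
})

test_that("engaging alone is costly: g(0) < 0 whenever tau >= 2, u > 0", {
  withr::with_seed(202, {
    for (i in 1:200) {
      u <- runif(1, 0.001, 0.999)
      tau <- sample(2:10, 1)
      prior <- runif(1, 0.05, 1)
      rho_lm <- runif(1, 0, 1)
      w <- runif(1, 0, 1 / max(rho_lm, 1e-9))
      probs <- reduced_probs(u, rho_lm, w)
      expect_lt(benefit_g(encounter_params(0, tau = tau, prior = prior),
                          probs), 0)
    }
  })
})

test_that("benefit is monotone in alpha and in w where the model says so", {
  alphas <- seq(0, 1, length.out = 51)
  withr::with_seed(303, {
    for (i in 1:50) {
      u <- runif(1, 0, 0.1)
      rho_lm <- runif(1, max(u, 0.01), 0.15)
      tau <- sample(1:5, 1)
      # monotone regime: the M-side slope must beat the compounded L-side
      # slope, i.e. rho_mm - rho_ml >= tau * (rho_lm - rho_ll)
      w_min <- (u + tau * (rho_lm - u)) / rho_lm
      w <- runif(1, max(1, w_min), 1 / rho_lm)
      g <- benefit_g(encounter_params(alphas, tau = tau),
                     reduced_probs(u, rho_lm, w))
      expect_true(all(diff(g) > -1e-12))
    }
  })
  # increasing in w at fixed alpha
  g_w <- vapply(seq(1, 6, 0.25), function(w) {
    benefit_g(encounter_params(0.8, tau = 3), reduced_probs(0.04, 0.1, w))
  }, numeric(1))
  expect_true(all(diff(g_w) > 0))
})

test_that("reduced parameterization maps and validates", {
  probs <- reduced_probs(0.04, 0.1, 3.5)
  expect_equal(unclass(probs)[c("rho_ll", "rho_lm", "rho_ml", "rho_mm")],
               list(rho_ll = 0.04, rho_lm = 0.1, rho_ml = 0.04,
                    rho_mm = 0.35))
  expect_equal(reduced_probs(0.1, 0.2, 1)$rho_mm, 0.2)
  expect_error(reduced_probs(0.04, 0.1, 11), "exceeds 1")
  expect_error(detection_probs(-0.1, 0.5, 0.5, 0.5), "probability")
  expect_error(encounter_params(0.5, tau = 2.5), "integer")
  expect_error(encounter_params(1.2), "alpha")
  expect_error(encounter_params(0.5, prior = 0), "prior")
})

test_that("delta threshold: bisection agrees with the closed form", {
  d <- delta_threshold(rho_lm = 0.1, tau = 3, u = 0.04)
  expect_lt(abs(d - delta_closed_form(0.1, 3)), 1e-6)
  expect_lt(d, 3)
  expect_gt(d, 2.5)

  # no compounding: M pays exactly when rho_MM > rho_LM
  expect_equal(delta_threshold(0.3, tau = 1, u = 0.1), 1, tolerance = 1e-6)

  # delta -> tau as rho_lm -> 0
  expect_equal(delta_threshold(1e-6, tau = 4, u = 0.04), 4,
               tolerance = 1e-4)

  expect_error(delta_threshold(0, tau = 3, u = 0.04), "undefined")
})

test_that("delta matches the closed form across random parameter draws", {
  withr::with_seed(404, {
    for (i in 1:100) {
      rho_lm <- runif(1, 0.01, 0.5)
      tau <- sample(1:8, 1)
      u <- runif(1, 0, min(rho_lm, 0.2))
      dc <- delta_closed_form(rho_lm, tau)
      # the closed form presumes the benefit is increasing in alpha at the
      # threshold; skip draws where compounding breaks that regime
      if (dc * rho_lm - u < tau * (rho_lm - u)) next
      d <- delta_threshold(rho_lm, tau, u)
      expect_lt(abs(d - dc), 1e-6)
    }
  })
})

test_that("threshold separates the regimes: no gain below, gain above", {
  eps <- 1e-3
  d <- delta_threshold(0.1, 3, 0.04)
  alphas <- seq(0, 1, length.out = 401)
  g_below <- benefit_g(encounter_params(alphas, tau = 3),
                       reduced_probs(0.04, 0.1, d - eps))
  g_above <- benefit_g(encounter_params(alphas, tau = 3),
                       reduced_probs(0.04, 0.1, d + eps))
  expect_true(all(g_below <= 0))
  expect_true(any(g_above > 0))
})

test_that("engagement cutoff exists above delta, not below, and falls with w", {
  expect_true(is.na(alpha_cutoff(reduced_probs(0.04, 0.1, 2.0), tau = 3)))

  cut <- alpha_cutoff(fig6_probs(), tau = 3)
  expect_gt(cut, 0)
  expect_lt(cut, 1)
  g_at_cut <- benefit_g(encounter_params(cut, tau = 3), fig6_probs())
  expect_lt(abs(g_at_cut), 1e-8)

  ws <- seq(3.0, 6, 0.5)
  cuts <- vapply(ws, function(w) {
    alpha_cutoff(reduced_probs(0.04, 0.1, w), tau = 3)
  }, numeric(1))
  expect_true(all(diff(cuts) < 0))
})

test_that("joint detection probability: mixture endpoints and monotonicity", {
  probs <- fig6_probs()
  a_b <- c(0, 0.4, 1)
  expect_equal(joint_P(0, a_b, probs, tau = 3),
               P_L(encounter_params(a_b, tau = 3), probs))
  expect_equal(joint_P(1, a_b, probs, tau = 3),
               P_M(encounter_params(a_b, tau = 3), probs))

  expect_equal(joint_P(1, 1, probs, tau = 3), 0.35 / 3)
  expect_equal(joint_P(1, 0, probs, tau = 3), 0.04 / 3)

  # corner ordering that generates the game's payoff structure
  corners <- c(pp <- joint_P(1, 1, probs, 3), lp <- joint_P(0, 1, probs, 3),
               ll <- joint_P(0, 0, probs, 3), pl <- joint_P(1, 0, probs, 3))
  expect_true(pp > lp && lp > ll && ll > pl)

  # increasing in the partner's engagement
  grid <- seq(0, 1, 0.05)
  for (aa in c(0, 0.5, 1)) {
    expect_true(all(diff(joint_P(aa, grid, probs, 3)) > 0))
  }
})
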