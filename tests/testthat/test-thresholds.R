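test_that("cubic coefficients match their defining polynomials and their phi = 0 limits", {
  # simple closure at phi = 0: leading coefficient vanishes and the quadratic
  # factors as n(alpha - (n-2))(tau*alpha + gamma)
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(3:9, 1); tau <- runif(1, 0.2, 2); gamma <- runif(1, 0.5, 2)
    p <- model_params(1e4, n, tau, gamma, 0)
    co <- cubic_coefficients(p, "simple")
    expect_equal(co$c3, 0)
    expect_equal(co$c2, -n * tau)           # -n*tau*alpha^2
    expect_equal(co$c1, n * (tau * (n - 2) - gamma))
    expect_equal(co$c0, gamma * n * (n - 2))
    # ... which is -n(alpha - (n-2))(tau*alpha + gamma):
    expect_equal(c(co$c2, co$c1, co$c0),
                 -n * c(tau, gamma - tau * (n - 2), -gamma * (n - 2)))
  }
  # compact improved intermediates
  p <- model_params(1e4, 5, 1, 1, 0.2)
  co <- cubic_coefficients(p, "compact_improved")
  expect_equal(co$aux$A, 1.4)
  expect_equal(co$aux$B, 1)
  expect_error(cubic_coefficients(model_params(1e4, 5, 0, 1, 0.2),
                                  "compact_improved"), "tau > 0")
  # coefficients continuous in phi at 0
  co_eps <- cubic_coefficients(model_params(1e4, 5, 1, 1, 1e-10), "simple")
  co_0 <- cubic_coefficients(model_params(1e4, 5, 1, 1, 0), "simple")
  for (k in c("c3", "c2", "c1", "c0"))
    expect_equal(co_eps[[k]], co_0[[k]], tolerance = 1e-8)
})

test_that("feasible-root selection: closed forms, sign-change oracle, and cubic/ODE agreement", {
  # phi = 0: alpha = n - 2 exactly, the root -gamma/tau rejected
  for (n in c(3, 5, 8)) for (tau in c(0.5, 1.5)) {
    p <- model_params(1e4, n, tau, 1, 0)
    ss <- solve_steady_state(cubic_coefficients(p, "simple"), p)
    expect_equal(ss[["alpha"]], n - 2, tolerance = 1e-12)
    expect_true(all(attr(ss, "roots") %in% c(n - 2, -1 / tau) |
                      abs(attr(ss, "roots") - (n - 2)) < 1e-9 |
                      abs(attr(ss, "roots") + 1 / tau) < 1e-9))
  }
  # compact improved at phi = 0: delta = 2*tau*(n-2)/(gamma + tau*(n-2))
  p <- model_params(1e4, 5, 1, 1, 0)
  ssc <- solve_steady_state(cubic_coefficients(p, "compact_improved"), p)
  expect_equal(ssc[["delta"]], 1.5, tolerance = 1e-12)
  expect_equal(ssc[["alpha"]], 3, tolerance = 1e-12)

  # independent oracle: dense sign-change scan of the cubic on (0, n)
  p5 <- model_params(1e4, 5, 1, 1, 0.5)
  co <- cubic_coefficients(p5, "simple")
  poly <- function(x) co$c3 * x^3 + co$c2 * x^2 + co$c1 * x + co$c0
  xs <- seq(1e-6, 5, length.out = 200001)
  ys <- poly(xs)
  flips <- which(ys[-1] * ys[-length(ys)] < 0)
  expect_length(flips, 1L)
  alpha_scan <- uniroot(poly, c(xs[flips], xs[flips + 1]), tol = 1e-14)$root
  ss5 <- solve_steady_state(co, p5)
  expect_equal(ss5[["alpha"]], alpha_scan, tolerance = 1e-10)

  # cubic root agrees with the fast-variable quasi-equilibrium across a grid
  for (n in c(3, 5, 8)) for (phi in c(0, 0.15, 0.3)) for (tau in c(0.5, 1.5)) {
    if (phi >= (n - 2) / (n - 1)) next
    p <- model_params(1e4, n, tau, 1, phi)
    for (cl in c("simple", "compact_improved")) {
      ss <- solve_steady_state(cubic_coefficients(p, cl), p)
      qe <- quasi_equilibrium(p, cl, "ode_relaxation")
      expect_equal(ss[["alpha"]], qe[["alpha"]], tolerance = 1e-6)
      expect_equal(ss[["delta"]], qe[["delta"]], tolerance = 1e-6)
    }
  }
})

test_that("asymptotic expansions match their closed-form coefficients", {
  p <- model_params(1e4, 5, 1, 1, 0.2)
  ex <- expansion(p, "simple")
  expect_equal(ex$order0, 3)
  expect_equal(ex$order1, -(8 / 25) * (29 / 4))  # -2.32 at n=5, tau=gamma=1
  expect_equal(ex$value_at_phi, 3 - 0.2 * 2.32)

  exc <- expansion(p, "compact_improved")
  expect_equal(exc$order0, 1.5)
  expect_equal(exc$alpha, 3 - 0.2 * 24 / 13)
  # delta1 from its closed-form rational expression
  d0 <- 1.5
  expect_equal(exc$order1,
               2 * 4 * d0 * (5 - 4 + d0) / (1 * (5 + 3 * d0) + 3 * (5 + 3 * d0 - 4)))

  # zeroth order is the unclustered limit for both closures
  p0 <- model_params(1e4, 7, 0.8, 1.2, 0)
  expect_equal(expansion(p0, "simple")$alpha, 5)
  expect_equal(expansion(p0, "compact_improved")$alpha, 5)
  expect_error(expansion(model_params(1e4, 2, 1, 1, 0), "simple"), "n > 2")

  # first-order expansion is tangent to the cubic root at phi = 0
  for (cl in c("simple", "compact_improved")) {
    alpha_of_phi <- function(phi) {
      p <- model_params(1e4, 5, 1, 1, phi)
      solve_steady_state(cubic_coefficients(p, cl), p)[["alpha"]]
    }
    h <- 1e-6
    slope_num <- (alpha_of_phi(h) - alpha_of_phi(0)) / h
    slope_exp <- (expansion(model_params(1e4, 5, 1, 1, 1), cl)$alpha -
                    expansion(model_params(1e4, 5, 1, 1, 0), cl)$alpha)
    expect_equal(slope_num, slope_exp, tolerance = 1e-4)
  }
})

test_that("threshold R = tau * alpha / gamma with the documented closed forms and ordering", {
  # phi = 0: R = tau (n-2) / gamma for both closures and both methods
  for (tau in c(0.4, 1)) {
    p <- model_params(1e4, 5, tau, 1, 0)
    for (cl in c("simple", "compact_improved"))
      for (m in c("cubic_numeric", "asymptotic"))
        expect_equal(threshold(p, cl, m)$R, 3 * tau, tolerance = 1e-10)
  }
  # asymptotic example: n=5, tau=gamma=1, phi=0.2
  expect_equal(threshold(model_params(1e4, 5, 1, 1, 0.2), "simple", "asymptotic")$R,
               2.536)
  # the rearranged parameterisation with a = 2(n-1)/n gives the same number
  a <- 2 * 4 / 5; R <- 3; phi <- 0.2
  expect_equal(R - phi * a * (a * R + 1) / (R + 1), 2.536)

  # clustering can only lower the threshold
  for (cl in c("simple", "compact_improved")) {
    Rs <- vapply(c(0, 0.1, 0.2, 0.3, 0.45), function(phi)
      threshold(model_params(1e4, 5, 1, 1, phi), cl, "cubic_numeric")$R, numeric(1))
    expect_equal(Rs[1], 3, tolerance = 1e-12)
    expect_true(all(diff(Rs) < 0))
    Ra <- vapply(c(0, 0.1, 0.2, 0.3, 0.45), function(phi)
      threshold(model_params(1e4, 5, 1, 1, phi), cl, "asymptotic")$R, numeric(1))
    expect_true(all(Ra <= 3 + 1e-12))
  }
  expect_equal(threshold(model_params(1e4, 5, 0, 1, 0.3), "simple")$R, 0)
})

test_that("C*_SI: closed form at phi = 0 and feasibility errors", {
  p0 <- model_params(1e4, 5, 1, 1, 0)
  expect_equal(keeling_CSI_star(p0), 0.6, tolerance = 1e-12)
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(3:9, 1)
    p <- model_params(1e4, n, runif(1, 0.3, 2), 1, 0)
    expect_equal(keeling_CSI_star(p), (n - 2) / n, tolerance = 1e-10)
  }
  expect_error(keeling_CSI_star(model_params(1e4, 4, 1, 1, 0.7)), "feasible")
})

test_that("NGM threshold: eigenvalue equals the rational closed form and phi = 0 limits agree", {
  expect_equal(ngm_R0(model_params(1e4, 5, 1, 1, 0))$R, 2)
  set.seed(29)
  for (rep in 1:8) {
    n <- sample(3:9, 1)
    p <- model_params(1e4, n, runif(1, 0.3, 2), runif(1, 0.5, 2),
                      runif(1, 0, 0.9 * (n - 2) / (n - 1)))
    r <- ngm_R0(p)
    expect_equal(r$R, r$eigenvalue, tolerance = 1e-10)
    p0 <- model_params(1e4, p$n, p$tau, p$gamma, 0)
    expect_equal(ngm_R0(p0)$R, li_R0(p0)$R, tolerance = 1e-12)
    expect_equal(ngm_R0(p0)$R, miller_R0_regular(p0)$R, tolerance = 1e-12)
    expect_equal(r$r0, li_R0(p)$r0, tolerance = 1e-12)
  }
  # r1 is the exact phi-derivative of the eigenvalue at phi = 0 (with the
  # fast variables at their unclustered quasi-equilibrium)
  p <- model_params(1e4, 5, 0.9, 1.3, 0)
  qe0 <- quasi_equilibrium(p, "simple")
  eig_at <- function(phi) {
    pp <- model_params(1e4, p$n, p$tau, p$gamma, phi)
    ngm_R0(pp, quasi_eq = qe0)$R
  }
  h <- 1e-7
  expect_equal(ngm_R0(p)$r1, (eig_at(h) - eig_at(0)) / h, tolerance = 1e-5)
})

test_that("motif-closure and percolation thresholds coincide to first order in phi", {
  p <- model_params(1e4, 5, 1, 1, 0)
  expect_equal(li_R0(p)$R, 2)
  expect_equal(miller_R0_regular(model_params(1e4, 5, 1, 1, 0.5))$R,
               2 - 4 * 0.5 * 0.25)
  set.seed(37)
  for (rep in 1:100) {
    n <- runif(1, 3, 12); tau <- runif(1, 0.1, 3); gamma <- runif(1, 0.3, 3)
    phi <- runif(1)
    p <- model_params(1e4, n, tau, gamma, phi)
    li <- li_R0(p)
    expect_equal(li$r0 + phi * li$r1, miller_R0_regular(p)$R, tolerance = 1e-10)
  }
  # strictly decreasing in phi
  Rli <- vapply(seq(0, 1, by = 0.1), function(phi)
    li_R0(model_params(1e4, 5, 1, 1, phi))$R, numeric(1))
  expect_true(all(diff(Rli) < 0))
})

test_that("household model: M, mu_D/phi round trip, R* monotone decreasing in phi", {
  hh <- household_params(lambda_G = 1, lambda_L = 2, gamma = 1, mu_D = 2)
  # M(lambda_G = gamma) = 1/2 enters through the (1 - M) prefactor
  r <- household_R_star(hh)
  expect_equal(r$R, 0.5 * ((1 + r$mu_T) * 2 - 1))
  expect_equal(household_mu_D(1), 0)
  set.seed(41)
  for (phi in runif(20, 0.01, 1))
    expect_equal(household_phi(household_mu_D(phi)), phi, tolerance = 1e-12)
  Rs <- vapply(seq(0.05, 0.95, by = 0.05), function(phi)
    household_R_star(hh, phi = phi)$R, numeric(1))
  expect_true(all(diff(Rs) < 0))
  # the T1/T2 decomposition reproduces R*
  for (phi in c(0.1, 0.4, 0.8)) {
    r <- household_R_star(hh, phi = phi)
    expect_equal(r$T1 + r$T2 * sqrt(1 + 8 / phi), r$R, tolerance = 1e-12)
  }
  expect_error(household_mu_D(0), "phi in \\(0, 1\\]")
})
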