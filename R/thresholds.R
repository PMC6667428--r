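#' Steady-state cubic coefficients for the fast subsystems
#'
#' Eliminating one fast variable from the steady-state conditions of
#' [rhs_fast()] reduces the quasi-equilibrium to the root of a cubic. For
#' the simple closure the cubic is in \eqn{\alpha}:
#' \deqn{2\tau\xi\phi(1-\xi\phi)\,\alpha^3
#'   + (\tau\xi n\phi - 2\tau\xi^2 n\phi(1-\phi) - \tau n)\,\alpha^2
#'   + (-n(\tau+\gamma) + \tau\xi n^2(1-\phi) + \gamma\xi n\phi)\,\alpha
#'   + \gamma\xi n^2(1-\phi) - \gamma n = 0.}
#' For the compact improved closure it is in \eqn{\delta}, with
#' \eqn{A = (n-2) - 2\phi(n-1)} and \eqn{B = \gamma/\tau}:
#' \deqn{(-A-B)\,\delta^3 + (-n(n-2) - A^2 - 2nB)\,\delta^2
#'   + (-n(n-2)A + 2nA - n^2 B)\,\delta + 2n^2(n-2) = 0.}
#'
#' @param params A [model_params()] object (for the compact improved closure
#'   `tau` must be positive since \eqn{B = \gamma/\tau}).
#' @param closure `"simple"` or `"compact_improved"`.
#' @return An object of class `cubic_coefficients`: list with fields `c3`,
#'   `c2`, `c1`, `c0` (highest degree first), `closure`, `variable`
#'   (`"alpha"` or `"delta"`) and `aux` (the intermediates `A`, `B` for the
#'   compact improved closure).
#' @export
cubic_coefficients <- function(params, closure = c("simple", "compact_improved")) {
  closure <- match.arg(closure)
  n <- params$n; tau <- params$tau; gamma <- params$gamma
  phi <- params$phi; xi <- params$xi
  if (closure == "simple") {
    co <- list(
      c3 = 2 * tau * xi * phi * (1 - xi * phi),
      c2 = tau * xi * n * phi - 2 * tau * xi^2 * n * phi * (1 - phi) - tau * n,
      c1 = -n * (tau + gamma) + tau * xi * n^2 * (1 - phi) + gamma * xi * n * phi,
      c0 = gamma * xi * n^2 * (1 - phi) - gamma * n)
    aux <- NULL
    variable <- "alpha"
  } else {
    if (tau <= 0)
      stop("compact improved cubic requires tau > 0 (B = gamma/tau)", call. = FALSE)
    A <- (n - 2) - 2 * phi * (n - 1)
    B <- gamma / tau
    co <- list(
      c3 = -A - B,
      c2 = -n * (n - 2) - A^2 - 2 * n * B,
      c1 = -n * (n - 2) * A + 2 * n * A - n^2 * B,
      c0 = 2 * n^2 * (n - 2))
    aux <- list(A = A, B = B)
    variable <- "delta"
  }
  structure(c(co, list(closure = closure, variable = variable, aux = aux)),
            class = "cubic_coefficients")
}

#' @export
print.cubic_coefficients <- function(x, ...) {
  cat(sprintf("Steady-state cubic in %s (%s closure):\n", x$variable, x$closure))
  cat(sprintf("  %.6g x^3 + %.6g x^2 + %.6g x + %.6g = 0\n",
              x$c3, x$c2, x$c1, x$c0))
  invisible(x)
}

#' Solve the steady-state cubic and select the feasible root
#'
#' Computes all roots of the cubic from [cubic_coefficients()] and selects
#' the biologically feasible one: the real root in \eqn{(0, n]} (for the
#' compact improved closure the \eqn{\delta}-root is mapped to \eqn{\alpha}
#' via \eqn{\alpha = (n-2) - 2(n-1)\phi\,\delta/(n+\delta)}). A numerically
#' degenerate leading coefficient (relative magnitude below `1e-12`, which
#' happens identically at \eqn{\phi = 0} for the simple closure) downgrades
#' the polynomial before root finding. If several roots lie in \eqn{(0, n]},
#' the one closest to the first-order asymptotic expansion (hence continuous
#' with the \eqn{\phi \to 0} limit \eqn{n - 2}) is selected and a warning is
#' attached.
#'
#' @param coeffs A `cubic_coefficients` object.
#' @param params The [model_params()] used to build `coeffs`.
#' @return A `fast_state` vector `c(alpha, delta)` with attribute `roots`
#'   (all real roots of the cubic in its own variable).
#' @export
solve_steady_state <- function(coeffs, params) {
  stopifnot(inherits(coeffs, "cubic_coefficients"))
  n <- params$n; tau <- params$tau; gamma <- params$gamma
  phi <- params$phi; xi <- params$xi
  co <- c(coeffs$c0, coeffs$c1, coeffs$c2, coeffs$c3)  # ascending order
  scale <- max(abs(co))
  while (length(co) > 1L && abs(co[length(co)]) < 1e-12 * scale)
    co <- co[-length(co)]
  if (length(co) <= 1L)
    stop("steady-state polynomial is degenerate", call. = FALSE)
  r <- polyroot(co)
  real <- Re(r[abs(Im(r)) < 1e-8 * max(1, Mod(r))])
  feasible <- real[real > 1e-12 & real <= n * (1 + 1e-12)]
  if (length(feasible) == 0L)
    stop("no feasible steady-state root in (0, n]", call. = FALSE)
  target <- expansion(params, coeffs$closure)
  guess <- if (coeffs$variable == "alpha")
    target$fast_state[["alpha"]] else target$fast_state[["delta"]]
  if (length(feasible) > 1L) {
    warning("multiple steady-state roots in (0, n]; selecting the one continuous with the phi -> 0 limit")
    feasible <- feasible[which.min(abs(feasible - guess))]
  }
  x <- feasible
  if (coeffs$variable == "alpha") {
    alpha <- x
    # delta from the ddelta/dt = 0 condition
    delta <- 2 * tau * alpha / (gamma + tau * alpha - 2 * tau * xi * phi * alpha^2 / n)
  } else {
    delta <- x
    alpha <- (n - 2) - 2 * (n - 1) * phi * delta / (n + delta)
  }
  structure(c(alpha = alpha, delta = delta), class = "fast_state", roots = real)
}

#' First-order asymptotic expansion of the quasi-equilibrium in phi
#'
#' Treats clustering as a perturbation of the unclustered system and expands
#' the feasible root of the steady-state cubic in powers of \eqn{\phi},
#' truncated at first order. For the simple closure,
#' \eqn{\alpha \approx \alpha_0 + \phi\,\alpha_1} with \eqn{\alpha_0 = n-2} and
#' \deqn{\alpha_1 = -\frac{2(n-1)}{n^2}\,
#'       \frac{2\tau(n-1)(n-2) + \gamma n}{\tau(n-2) + \gamma}.}
#' For the compact improved closure the natural expansion variable is
#' \eqn{\delta \approx \delta_0 + \phi\,\delta_1} with
#' \deqn{\delta_0 = \frac{2\tau(n-2)}{\gamma + \tau(n-2)},\qquad
#'       \delta_1 = \frac{2\tau(n-1)\delta_0(n-4+\delta_0)}
#'       {\gamma(n+3\delta_0) + \tau(n-2)(n+3\delta_0-4)},}
#' and the induced first-order value of \eqn{\alpha} is
#' \deqn{\alpha \approx (n-2) - \phi\,
#'       \frac{4\tau(n-1)(n-2)}{\tau(n+2)(n-2) + \gamma n}.}
#'
#' The truncation is strictly first order; no second-order coefficients are
#' computed, and the series is never evaluated beyond \eqn{\phi = 1}.
#'
#' @inheritParams cubic_coefficients
#' @return An object of class `pw_expansion`: list with `variable`, `order0`,
#'   `order1`, `value_at_phi` (the truncated series at the parameters' own
#'   \eqn{\phi}), `alpha` (the first-order \eqn{\alpha} value for either
#'   closure) and `fast_state` (the induced `c(alpha, delta)` pair).
#' @export
expansion <- function(params, closure = c("simple", "compact_improved")) {
  closure <- match.arg(closure)
  n <- params$n; tau <- params$tau; gamma <- params$gamma; phi <- params$phi
  if (n <= 2) stop("expansion requires n > 2 (alpha0 = n - 2 must be positive)",
                   call. = FALSE)
  delta0 <- 2 * tau * (n - 2) / (gamma + tau * (n - 2))
  if (closure == "simple") {
    alpha0 <- n - 2
    alpha1 <- -2 * (n - 1) / n^2 *
      (2 * tau * (n - 1) * (n - 2) + gamma * n) / (tau * (n - 2) + gamma)
    alpha <- alpha0 + phi * alpha1
    # delta on the ddelta/dt = 0 cline at the expanded alpha
    delta <- 2 * tau * alpha /
      (gamma + tau * alpha - 2 * tau * params$xi * phi * alpha^2 / n)
    structure(list(closure = closure, variable = "alpha",
                   order0 = alpha0, order1 = alpha1,
                   value_at_phi = alpha, alpha = alpha,
                   fast_state = c(alpha = alpha, delta = delta)),
              class = "pw_expansion")
  } else {
    delta1 <- 2 * tau * (n - 1) * delta0 * (n - 4 + delta0) /
      (gamma * (n + 3 * delta0) + tau * (n - 2) * (n + 3 * delta0 - 4))
    delta <- delta0 + phi * delta1
    alpha <- (n - 2) - phi * 4 * tau * (n - 1) * (n - 2) /
      (tau * (n + 2) * (n - 2) + gamma * n)
    structure(list(closure = closure, variable = "delta",
                   order0 = delta0, order1 = delta1,
                   value_at_phi = delta, alpha = alpha,
                   fast_state = c(alpha = alpha, delta = delta)),
              class = "pw_expansion")
  }
}

#' @export
print.pw_expansion <- function(x, ...) {
  cat(sprintf("First-order expansion in phi (%s closure), variable %s:\n",
              x$closure, x$variable))
  cat(sprintf("  %s = %.6g %+.6g phi  ->  %.6g at this phi (alpha = %.6g)\n",
              x$variable, x$order0, x$order1, x$value_at_phi, x$alpha))
  invisible(x)
}

threshold_result <- function(R, method, quasi_eq = NULL, valid = TRUE,
                             notes = "", extra = NULL) {
  structure(c(list(R = R, method = method, quasi_eq = quasi_eq,
                   valid = valid, notes = notes), extra),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Epidemic threshold R = %.6g  [method: %s%s]\n", x$R, x$method,
              if (!x$valid) ", OUTSIDE validity region" else ""))
  if (nzchar(x$notes)) cat(" ", x$notes, "\n")
  invisible(x)
}

#' Epidemic threshold from the pairwise fast variables
#'
#' The growth-rate-based epidemic threshold is
#' \eqn{R = \tau\alpha^*/\gamma}, with \eqn{\alpha^* = [SI]/[I]} at the
#' quasi-equilibrium of the fast variables: the epidemic grows when
#' \eqn{R > 1} and dies out when \eqn{R < 1} (at the critical point it is
#' equivalent to the basic reproduction number). `method = "cubic_numeric"`
#' uses the feasible root of the steady-state cubic
#' ([solve_steady_state()]); `"asymptotic"` uses the first-order expansion
#' in \eqn{\phi} ([expansion()]). For the simple closure the asymptotic form
#' can be written
#' \eqn{R^c = R_{uc} - \phi\,a\,(\tau/\gamma)\,(aR_{uc}+1)/(R_{uc}+1)} with
#' \eqn{a = 2(n-1)/n} and \eqn{R_{uc} = \tau(n-2)/\gamma}; this
#' parameterisation is returned in the `notes`.
#'
#' @inheritParams cubic_coefficients
#' @param method `"cubic_numeric"` or `"asymptotic"`.
#' @return A `threshold_result` with fields `R`, `method`, `quasi_eq`,
#'   `valid` (the feasibility flag from [stability_conditions()]) and
#'   `notes`.
#' @examples
#' p <- model_params(10000, 5, 1, 1, 0.2)
#' threshold(p, "simple", "asymptotic")$R  # 3 - 0.2 * 2.32 = 2.536
#' @export
threshold <- function(params, closure = c("simple", "compact_improved"),
                      method = c("cubic_numeric", "asymptotic")) {
  closure <- match.arg(closure)
  method <- match.arg(method)
  sc <- stability_conditions(params)
  valid <- if (closure == "simple") sc$feasibility_ok else TRUE
  if (params$tau == 0)
    return(threshold_result(0, method, quasi_eq = NULL, valid = valid,
                            notes = "tau = 0: no transmission"))
  if (method == "cubic_numeric") {
    qe <- solve_steady_state(cubic_coefficients(params, closure), params)
    R <- params$tau * qe[["alpha"]] / params$gamma
    threshold_result(R, "cubic_numeric", quasi_eq = qe, valid = valid)
  } else {
    ex <- expansion(params, closure)
    R <- params$tau * ex$alpha / params$gamma
    notes <- if (closure == "simple") {
      a <- 2 * (params$n - 1) / params$n
      Ruc <- params$tau * (params$n - 2) / params$gamma
      sprintf("R^c = R - phi * a * (tau/gamma) * (a*R + 1)/(R + 1), a = %.6g, R = %.6g",
              a, Ruc)
    } else ""
    threshold_result(R, "asymptotic", quasi_eq = ex$fast_state, valid = valid,
                     notes = notes)
  }
}

#' Quasi-equilibrium correlation C*_SI (Keeling's equation)
#'
#' Solves the quasi-equilibrium equation for the susceptible--infected pair
#' correlation \eqn{C_{SI}},
#' \deqn{1 + C - n\xi(1-C)(1-\phi) +
#'       \frac{2\beta\xi\phi C^2}{\gamma + \beta C - 2\xi\beta C^2\phi} = 0,
#'       \qquad \beta = \tau n,}
#' for the root \eqn{C^*_{SI} \in (0, 1)}. At \eqn{\phi = 0} the closed form
#' is \eqn{C^*_{SI} = (n-2)/n}. Under the substitution
#' \eqn{C_{SI} = \alpha/n} this equation is equivalent to the steady-state
#' cubic of the simple closure, so \eqn{n\,C^*_{SI}} equals the feasible
#' \eqn{\alpha}-root.
#'
#' The root is bracketed on \eqn{(10^{-9}, 1-10^{-9})} after clearing the
#' (positive) denominator; a warning is issued if the denominator changes
#' sign inside the bracket.
#'
#' @param params A [model_params()] object with
#'   \eqn{\phi < (n-2)/(n-1)} and \eqn{\tau > 0}.
#' @return The correlation \eqn{C^*_{SI}}, a number in \eqn{(0, 1)}.
#' @export
keeling_CSI_star <- function(params) {
  n <- params$n; tau <- params$tau; gamma <- params$gamma
  phi <- params$phi; xi <- params$xi
  if (tau <= 0) stop("keeling_CSI_star requires tau > 0", call. = FALSE)
  if (!stability_conditions(params)$feasibility_ok)
    stop("no feasible C*_SI: phi >= (n-2)/(n-1)", call. = FALSE)
  beta <- tau * n
  den <- function(C) gamma + beta * C - 2 * xi * beta * C^2 * phi
  # multiply through by the denominator to avoid the pole
  g <- function(C) (1 + C - n * xi * (1 - C) * (1 - phi)) * den(C) +
    2 * beta * xi * phi * C^2
  lo <- 1e-9; hi <- 1 - 1e-9
  if (den(lo) * den(hi) < 0 || min(den(seq(lo, hi, length.out = 101))) < 0)
    warning("denominator of the C*_SI equation changes sign in (0, 1)")
  if (g(lo) * g(hi) > 0)
    stop("no feasible root of the C*_SI equation in (0, 1)", call. = FALSE)
  stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
}

#' Next-generation-matrix R0 for the simple-closure pairwise model
#'
#' Linearising the closed simple-closure system at the disease-free state in
#' the infection variables \eqn{([I], [SI])}, with the fast variables at
#' their quasi-equilibrium \eqn{(\alpha, \delta)}, gives the new-infection
#' matrix \eqn{F} and transition matrix \eqn{V}:
#' \deqn{F = \begin{pmatrix} 0 & \tau \\
#'       0 & \tau(n-1)(1-\phi) + \tau\xi\phi\alpha\end{pmatrix},\qquad
#'       V = \begin{pmatrix}\gamma & 0\\
#'       0 & (\tau+\gamma) + \tau\xi\alpha\delta\phi/n\end{pmatrix}.}
#' \eqn{R_0} is the leading eigenvalue of \eqn{FV^{-1}}, equal to the closed
#' form
#' \deqn{R_0 = \frac{\tau n(n-1) - \tau(n-1)(n-\alpha)\phi}
#'       {n(\tau+\gamma) + \tau\xi\alpha\delta\phi}.}
#' The first-order expansion in \eqn{\phi} has
#' \eqn{r_0 = \tau(n-1)/(\tau+\gamma)} and
#' \deqn{r_1 = -\frac{\tau^2(n-1)}{(\tau+\gamma)^2}\left[
#'       \frac{2(\tau+\gamma)}{n\tau} + \frac{\xi\,\alpha_0\delta_0}{n}
#'       \right],}
#' the exact \eqn{\phi}-derivative of the eigenvalue at \eqn{\phi = 0} with
#' \eqn{(\alpha_0, \delta_0)} the unclustered quasi-equilibrium.
#'
#' @param params A [model_params()] object.
#' @param quasi_eq Optional `fast_state` from the simple-closure subsystem;
#'   computed via [solve_steady_state()] when omitted.
#' @return A `threshold_result` with extra fields `F`, `V`, `r0`, `r1` and
#'   `eigenvalue` (the numerically computed leading eigenvalue, equal to `R`).
#' @export
ngm_R0 <- function(params, quasi_eq = NULL) {
  n <- params$n; tau <- params$tau; gamma <- params$gamma
  phi <- params$phi; xi <- params$xi
  if (is.null(quasi_eq))
    quasi_eq <- solve_steady_state(cubic_coefficients(params, "simple"), params)
  a <- quasi_eq[["alpha"]]; d <- quasi_eq[["delta"]]
  F_mat <- matrix(c(0, 0, tau, tau * (n - 1) * (1 - phi) + tau * xi * phi * a),
                  2L, 2L)
  V_mat <- diag(c(gamma, (tau + gamma) + tau * xi * a * d * phi / n))
  ev <- max(Re(eigen(F_mat %*% solve(V_mat), only.values = TRUE)$values))
  R_closed <- (tau * n * (n - 1) - tau * (n - 1) * (n - a) * phi) /
    (n * (tau + gamma) + tau * xi * a * d * phi)
  alpha0 <- n - 2
  delta0 <- 2 * tau * (n - 2) / (gamma + tau * (n - 2))
  r0 <- tau * (n - 1) / (tau + gamma)
  r1 <- -tau^2 * (n - 1) / (tau + gamma)^2 *
    (2 * (tau + gamma) / (n * tau) + xi * alpha0 * delta0 / n)
  threshold_result(R_closed, "ngm", quasi_eq = quasi_eq,
                   valid = stability_conditions(params)$feasibility_ok,
                   extra = list(F = F_mat, V = V_mat, eigenvalue = ev,
                                r0 = r0, r1 = r1))
}

#' Motif-closure R0 (Li et al.)
#'
#' The threshold from a pairwise model closed over links in a motif rather
#' than nodes:
#' \deqn{R_0 = \frac{(n-1)\tau}{\tau + \gamma + \tau\phi},}
#' with first-order expansion
#' \eqn{R_0 \approx \frac{(n-1)\tau}{\tau+\gamma}
#' \left(1 - \phi\frac{\tau}{\tau+\gamma}\right)}.
#'
#' @param params A [model_params()] object.
#' @return A `threshold_result` with extra fields `r0` and `r1` (the
#'   first-order expansion coefficients).
#' @export
li_R0 <- function(params) {
  n <- params$n; tau <- params$tau; gamma <- params$gamma; phi <- params$phi
  R <- (n - 1) * tau / (tau + gamma + tau * phi)
  r0 <- (n - 1) * tau / (tau + gamma)
  r1 <- -r0 * tau / (tau + gamma)
  threshold_result(R, "li", extra = list(r0 = r0, r1 = r1))
}

#' Percolation-based R0 for clustered regular networks (Miller)
#'
#' For a regular network of degree \eqn{n} with Markovian transmission, the
#' per-link transmission probability is \eqn{T = \tau/(\tau+\gamma)} and a
#' global clustering coefficient \eqn{\phi} corresponds to each node
#' belonging on average to \eqn{\frac{1}{2}n(n-1)\phi} triangles, giving
#' \deqn{R_0 = \frac{\tau(n-1)}{\tau+\gamma}
#'       - (n-1)\phi\left(\frac{\tau}{\tau+\gamma}\right)^2.}
#' As a function of \eqn{(n, \tau, \gamma, \phi)} this coincides exactly
#' with the first-order expansion of the motif-closure threshold
#' ([li_R0()]).
#'
#' @param params A [model_params()] object.
#' @return A `threshold_result`.
#' @export
miller_R0_regular <- function(params) {
  n <- params$n; tau <- params$tau; gamma <- params$gamma; phi <- params$phi
  Tprob <- tau / (tau + gamma)
  R <- tau * (n - 1) / (tau + gamma) - (n - 1) * phi * Tprob^2
  threshold_result(R, "miller", extra = list(T = Tprob))
}
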