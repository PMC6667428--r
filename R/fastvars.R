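#' Right-hand side of the fast-variable subsystem
#'
#' During the early phase of an epidemic the ratios
#' \eqn{\alpha = [SI]/[I]} and \eqn{\delta = [II]/[I]} equilibrate much
#' faster than prevalence and converge to a quasi-equilibrium whose
#' \eqn{\alpha}-component determines the epidemic threshold
#' \eqn{R = \tau\alpha^*/\gamma}. For the simple closure the subsystem is
#' \deqn{\dot\alpha = -\tau\alpha + \tau\xi n(1-\phi)\alpha +
#'       \tau\xi\phi\alpha^2 - \tau\xi\phi\alpha^2\delta/n - \tau\alpha^2,}
#' \deqn{\dot\delta = 2\tau\alpha - \gamma\delta +
#'       2\tau\xi\phi\alpha^2\delta/n - \tau\alpha\delta,}
#' and for the compact improved closure
#' \deqn{\dot\alpha = -\tau\alpha - \tau\alpha^2 + \tau(n-1)\left(
#'       (1-\phi)\alpha + \phi\alpha\frac{n-\delta}{n+\delta}\right),}
#' \deqn{\dot\delta = 2\tau\alpha - \gamma\delta +
#'       2\tau(n-1)\frac{\phi\alpha\delta}{n+\delta} - \tau\alpha\delta.}
#'
#' @param fast Numeric vector `c(alpha, delta)`.
#' @param params A [model_params()] object.
#' @param closure `"simple"` or `"compact_improved"`.
#' @return Numeric vector `c(alpha = dalpha/dt, delta = ddelta/dt)`.
#' @export
rhs_fast <- function(fast, params, closure = c("simple", "compact_improved")) {
  closure <- match.arg(closure)
  a <- fast[[1L]]; d <- fast[[2L]]
  n <- params$n; tau <- params$tau; gamma <- params$gamma
  phi <- params$phi; xi <- params$xi
  if (closure == "simple") {
    da <- -tau * a + tau * xi * n * (1 - phi) * a + tau * xi * phi * a^2 -
      tau * xi * phi * a^2 * d / n - tau * a^2
    dd <- 2 * tau * a - gamma * d + 2 * tau * xi * phi * a^2 * d / n -
      tau * a * d
  } else {
    da <- -tau * a - tau * a^2 +
      tau * (n - 1) * ((1 - phi) * a + phi * a * (n - d) / (n + d))
    dd <- 2 * tau * a - gamma * d +
      2 * tau * (n - 1) * phi * a * d / (n + d) - tau * a * d
  }
  c(alpha = da, delta = dd)
}

#' Membership of the invariant region D
#'
#' The biologically feasible region for the fast variables is
#' \eqn{D = \{(\alpha, \delta): 0 \le \alpha \le n,\ 0 \le \delta \le
#' n - \alpha\}} (an infected node has at most \eqn{n} neighbours, so its
#' susceptible and infected neighbour counts sum to at most \eqn{n}). The
#' region is closed; membership uses non-strict inequalities with no
#' tolerance.
#'
#' @inheritParams rhs_fast
#' @return Logical.
#' @export
in_region_D <- function(fast, params) {
  a <- fast[[1L]]; d <- fast[[2L]]
  a >= 0 && a <= params$n && d >= 0 && a + d <= params$n
}

#' Null clines of the fast-variable subsystems
#'
#' Returns the null clines of [rhs_fast()] as functions of one variable.
#' For the simple closure (\eqn{\phi > 0}) both null clines are functions
#' \eqn{\delta(\alpha)}:
#' \deqn{\delta_1(\alpha) = \frac{n}{\xi\phi}\left(
#'       \frac{\xi n(1-\phi) - 1}{\alpha} + \xi\phi - 1\right),\qquad
#'       \delta_2(\alpha) = \frac{2\tau\alpha}
#'       {\gamma + \tau\alpha - 2\tau\xi\phi\alpha^2/n}.}
#' For the compact improved closure the \eqn{\dot\alpha = 0} cline is
#' \eqn{\delta_n(\alpha) = n((n-2)-\alpha)/(\alpha + 2\phi(n-1) - (n-2))} and
#' the \eqn{\dot\delta = 0} cline is parameterised the other way,
#' \eqn{\alpha_n(\delta) = \gamma\delta(n+\delta) / (\tau(-\delta^2 +
#' (2(n-1)\phi - (n-2))\delta + 2n))}.
#'
#' Evaluation within `1e-9` of a pole raises an error rather than returning a
#' huge value; plotting code must window poles explicitly.
#'
#' @inheritParams rhs_fast
#' @return For `closure = "simple"`, a list with functions `delta1(alpha)`
#'   and `delta2(alpha)`; for `"compact_improved"`, a list with
#'   `delta_n(alpha)` and `alpha_n(delta)`.
#' @export
nullclines <- function(params, closure = c("simple", "compact_improved")) {
  closure <- match.arg(closure)
  n <- params$n; tau <- params$tau; gamma <- params$gamma
  phi <- params$phi; xi <- params$xi
  guard <- function(den) {
    if (any(abs(den) < 1e-9))
      stop("null cline evaluated at (or within 1e-9 of) a singularity",
           call. = FALSE)
    den
  }
  if (closure == "simple") {
    if (phi <= 0)
      stop("simple-closure null clines require phi > 0 (at phi = 0 the dalpha/dt = 0 cline degenerates to the vertical line alpha = n - 2)",
           call. = FALSE)
    list(
      delta1 = function(alpha)
        n / (xi * phi) * ((xi * n * (1 - phi) - 1) / guard(alpha) + xi * phi - 1),
      delta2 = function(alpha)
        2 * tau * alpha / guard(gamma + tau * alpha - 2 * tau * xi * phi * alpha^2 / n)
    )
  } else {
    list(
      delta_n = function(alpha)
        n * ((n - 2) - alpha) / guard(alpha + 2 * phi * (n - 1) - (n - 2)),
      alpha_n = function(delta)
        gamma * delta * (n + delta) /
          guard(tau * (-delta^2 + (2 * (n - 1) * phi - (n - 2)) * delta + 2 * n))
    )
  }
}

#' Bendixson divergence of the fast subsystem
#'
#' The divergence of the fast vector field after dividing both equations by
#' \eqn{\alpha} (a Dulac-type rescaling). If it keeps one sign on the simply
#' connected region D, the Bendixson criterion rules out periodic orbits and
#' the unique interior steady state is globally stable. For the simple
#' closure
#' \deqn{B(\alpha, \delta) = -2\tau - \gamma/\alpha +
#'       \phi\,\tau\xi(n - \delta + 2\alpha)/n,}
#' and for the compact improved closure
#' \deqn{B(\alpha, \delta) = -2\tau - \gamma/\alpha +
#'       2\tau\phi n(n-1)/(n+\delta)^2,}
#' which is negative everywhere on D.
#'
#' @inheritParams rhs_fast
#' @return The divergence value (a real number).
#' @export
bendixson_divergence <- function(fast, params,
                                 closure = c("simple", "compact_improved")) {
  closure <- match.arg(closure)
  a <- fast[[1L]]; d <- fast[[2L]]
  if (a <= 0) stop("Bendixson divergence requires alpha > 0", call. = FALSE)
  n <- params$n; tau <- params$tau; gamma <- params$gamma
  phi <- params$phi; xi <- params$xi
  if (closure == "simple") {
    -2 * tau - gamma / a + phi * (tau * xi / n) * (n - d + 2 * a)
  } else {
    -2 * tau - gamma / a + 2 * tau * phi * n * (n - 1) / (n + d)^2
  }
}

#' Feasibility and global-stability bounds for the fast subsystems
#'
#' Evaluates the three parameter conditions governing the fast subsystems:
#' * `feasibility_ok`: \eqn{\phi < (n-2)/(n-1)} — below this bound the simple
#'   closure's fast subsystem has a unique interior steady state; above it
#'   the disease dies out.
#' * `bendixson_ok`: \eqn{\phi < 2n/(3(n-1))} — sufficient for the Bendixson
#'   criterion to rule out limit cycles in D for the simple closure (for
#'   \eqn{n < 6} this is implied by the feasibility bound).
#' * `improved_feasibility_ok`: \eqn{2\phi < (n-2)/(n-1)} — the condition
#'   under which the \eqn{\alpha = 0} line of the compact improved subsystem
#'   repels into the interior (the sign condition on
#'   \eqn{d(\dot\alpha)/d\alpha} at \eqn{\alpha = 0}).
#'
#' Also flags the edge regime in which the singularity of the
#' \eqn{\dot\delta = 0} null cline of the simple closure lies inside
#' \eqn{(0, n)}; root bracketing handles it identically but downstream users
#' may wish to know.
#'
#' @param params A [model_params()] object.
#' @return An object of class `stability_report`: a list with logical flags
#'   `feasibility_ok`, `bendixson_ok`, `improved_feasibility_ok`,
#'   `delta2_singularity_in_range`, and `bounds`, a named vector of the three
#'   bound values.
#' @export
stability_conditions <- function(params) {
  n <- params$n; phi <- params$phi
  bounds <- c(feasibility = (n - 2) / (n - 1),
              bendixson = 2 * n / (3 * (n - 1)),
              improved_feasibility = (n - 2) / (2 * (n - 1)))
  if (n <= 2) {
    flags <- c(FALSE, FALSE, FALSE)
  } else {
    flags <- c(phi < bounds[["feasibility"]],
               phi < bounds[["bendixson"]],
               phi < bounds[["improved_feasibility"]])
  }
  # singularity of delta2: positive root of gamma + tau a - 2 tau xi phi a^2/n
  sing_in_range <- FALSE
  if (params$tau > 0 && phi > 0) {
    cc <- 2 * params$tau * params$xi * phi / n
    disc <- params$tau^2 + 4 * cc * params$gamma
    a_pole <- (params$tau + sqrt(disc)) / (2 * cc)
    sing_in_range <- a_pole > 0 && a_pole < n
  }
  structure(list(feasibility_ok = flags[[1L]],
                 bendixson_ok = flags[[2L]],
                 improved_feasibility_ok = flags[[3L]],
                 delta2_singularity_in_range = sing_in_range,
                 bounds = bounds),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Fast-subsystem stability conditions:\n")
  cat(sprintf("  feasibility          phi < %-8.4g : %s\n",
              x$bounds[["feasibility"]], x$feasibility_ok))
  cat(sprintf("  Bendixson            phi < %-8.4g : %s\n",
              x$bounds[["bendixson"]], x$bendixson_ok))
  cat(sprintf("  improved feasibility phi < %-8.4g : %s\n",
              x$bounds[["improved_feasibility"]], x$improved_feasibility_ok))
  if (x$delta2_singularity_in_range)
    cat("  note: delta2 null-cline singularity lies in (0, n) (edge regime)\n")
  invisible(x)
}

#' Quasi-equilibrium of the fast variables
#'
#' Computes the unique interior steady state of [rhs_fast()] in the region D,
#' by one of two routes:
#' * `"ode_relaxation"`: integrate the fast subsystem from the fast-variable
#'   image of the standard initial conditions,
#'   \eqn{(\alpha, \delta)(0) = (n(N-1)/N,\ n/N)}, until
#'   \eqn{\|\dot{(\alpha,\delta)}\|_\infty < 10^{-10}} (or \eqn{t > 200/\gamma},
#'   in which case an error is raised).
#' * `"root_find"`: damped Newton iteration on `rhs_fast = 0` started from
#'   the first-order asymptotic expansion (see [expansion()]).
#'
#' The two routes agree to well below `1e-6` for feasible parameters and are
#' cross-checked in the package tests.
#'
#' @inheritParams rhs_fast
#' @param method `"root_find"` (default) or `"ode_relaxation"`.
#' @return Named numeric vector `c(alpha, delta)` of class `fast_state`.
#' @examples
#' p <- model_params(10000, 5, 1, 1, 0)
#' quasi_equilibrium(p, "simple")  # (n-2, 2*tau*(n-2)/(gamma+tau*(n-2))) = (3, 1.5)
#' @export
quasi_equilibrium <- function(params, closure = c("simple", "compact_improved"),
                              method = c("root_find", "ode_relaxation")) {
  closure <- match.arg(closure)
  method <- match.arg(method)
  n <- params$n; gamma <- params$gamma
  sc <- stability_conditions(params)
  if (closure == "simple" && !sc$feasibility_ok)
    stop("no interior quasi-equilibrium: phi >= (n-2)/(n-1) (disease dies out)",
         call. = FALSE)
  if (params$tau == 0)
    stop("no interior quasi-equilibrium for tau = 0", call. = FALSE)
  if (method == "ode_relaxation") {
    y <- c(alpha = n * (params$N - 1) / params$N, delta = n / params$N)
    deriv <- function(t, y, parms) list(rhs_fast(y, params, closure))
    # the subsystem's rates scale with both gamma and tau, so the horizon
    # uses the slower of the two; near the feasibility boundary the slowest
    # eigenvalue is small and the approach takes many recovery periods
    rate <- min(gamma, params$tau)
    t_end <- 0
    repeat {
      chunk <- 10 / rate
      sol <- deSolve::lsoda(y, times = c(0, chunk), deriv, parms = NULL,
                            rtol = 1e-12, atol = 1e-12)
      y <- sol[2L, c("alpha", "delta")]
      t_end <- t_end + chunk
      if (max(abs(rhs_fast(y, params, closure))) < 1e-10) break
      if (t_end > 200 / rate)
        stop("fast-variable relaxation did not converge by t = 200/min(gamma, tau)",
             call. = FALSE)
    }
    out <- y
  } else {
    x <- unclass(expansion(params, closure)$fast_state)
    if (!in_region_D(x, params)) x <- pmax(pmin(x, c(n, n) * 0.9), 1e-3)
    f <- rhs_fast(x, params, closure)
    for (iter in seq_len(200L)) {
      if (max(abs(f)) < 1e-13) break
      J <- matrix(0, 2L, 2L)
      h <- pmax(1e-7, abs(x) * 1e-7)
      for (j in 1:2) {
        e <- c(0, 0); e[j] <- h[j]
        J[, j] <- (rhs_fast(x + e, params, closure) -
                     rhs_fast(x - e, params, closure)) / (2 * h[j])
      }
      step <- tryCatch(solve(J, f), error = function(e) f * 0)
      lam <- 1
      repeat {
        x_new <- x - lam * step
        f_new <- rhs_fast(x_new, params, closure)
        if (max(abs(f_new)) < max(abs(f)) || lam < 1e-6) break
        lam <- lam / 2
      }
      x <- x_new; f <- f_new
    }
    if (max(abs(f)) > 1e-10)
      stop("Newton iteration for the quasi-equilibrium did not converge",
           call. = FALSE)
    out <- x
  }
  out <- c(alpha = unname(out[[1L]]), delta = unname(out[[2L]]))
  if (out[[1L]] <= 0 || out[[1L]] > n || out[[2L]] < -1e-9 ||
      out[[1L]] + out[[2L]] > n + 1e-9)
    stop("fast-variable steady state lies outside the feasible region D",
         call. = FALSE)
  structure(out, class = "fast_state")
}
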