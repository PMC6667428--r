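#' Model parameters for a pairwise SIR epidemic on a clustered regular network
#'
#' Bundles the five parameters of the model together with the derived
#' convenience constant \eqn{\xi = (n-1)/n} used throughout the closed
#' equations.
#'
#' @param N Population size (number of nodes), a positive number.
#' @param n Common degree of the regular network, \eqn{n \ge 2} (the model is
#'   only epidemiologically interesting for \eqn{n > 2}).
#' @param tau Per-link transmission rate (1/time), \eqn{\tau \ge 0}. Infection
#'   passes across each susceptible--infected link as a Poisson process with
#'   this rate.
#' @param gamma Recovery rate (1/time), \eqn{\gamma > 0}.
#' @param phi Global clustering coefficient of the network, in \eqn{[0, 1]}.
#'   See [clustering_coefficient()].
#'
#' @return An object of class `pw_params`: a list with elements `N`, `n`,
#'   `tau`, `gamma`, `phi` and the derived `xi = (n-1)/n`.
#' @examples
#' p <- model_params(N = 10000, n = 5, tau = 1, gamma = 1, phi = 0.5)
#' p$xi  # 4/5
#' @export
model_params <- function(N, n, tau, gamma, phi) {
  stopifnot(
    is.numeric(N), length(N) == 1L, is.finite(N), N > 0,
    is.numeric(n), length(n) == 1L, is.finite(n), n >= 2,
    is.numeric(tau), length(tau) == 1L, is.finite(tau), tau >= 0,
    is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0,
    is.numeric(phi), length(phi) == 1L, is.finite(phi), phi >= 0, phi <= 1
  )
  structure(
    list(N = as.numeric(N), n = as.numeric(n), tau = as.numeric(tau),
         gamma = as.numeric(gamma), phi = as.numeric(phi),
         xi = (as.numeric(n) - 1) / as.numeric(n)),
    class = "pw_params"
  )
}

#' @export
print.pw_params <- function(x, ...) {
  cat(sprintf(
    "Pairwise SIR parameters: N = %g, n = %g, tau = %g, gamma = %g, phi = %g (xi = %g)\n",
    x$N, x$n, x$tau, x$gamma, x$phi, x$xi))
  invisible(x)
}

#' Pairwise model state: expected counts of singles and pairs
#'
#' The state of the closed pairwise system: expected counts of susceptible and
#' infected nodes and of the dynamically relevant pairs. Pairs are counted once
#' in each direction, so `SS` and `II` are even-count quantities and
#' `SI` counts both orientations of a susceptible--infected link. The recovered
#' count is implicit as \eqn{[R] = N - [S] - [I]}. All counts are continuous
#' expectations; no integrality is imposed.
#'
#' @param S,I Expected numbers of susceptible and infected nodes (\eqn{\ge 0}).
#' @param SI,SS,II Expected pair counts (\eqn{\ge 0}).
#'
#' @return An object of class `pw_state`: a named numeric vector with elements
#'   `S`, `I`, `SI`, `SS`, `II`.
#' @seealso [initial_conditions()] for the standard seeding used in numerical
#'   experiments.
#' @export
pairwise_state <- function(S, I, SI, SS, II) {
  x <- c(S = as.numeric(S), I = as.numeric(I), SI = as.numeric(SI),
         SS = as.numeric(SS), II = as.numeric(II))
  if (any(!is.finite(x))) stop("pairwise state must be finite", call. = FALSE)
  if (any(x < 0)) stop("pairwise state counts must be non-negative", call. = FALSE)
  structure(x, class = "pw_state")
}

# Validate a state against the stub-count bounds of a regular network of
# degree n; used by tests and by integrate_epidemic() post-checks.
check_state <- function(state, params, tol = 1e-8) {
  n <- params$n; N <- params$N
  s <- unclass(state)
  ok <- s[["S"]] + s[["I"]] <= N * (1 + tol) &&
    s[["SS"]] <= n * s[["S"]] * (1 + tol) + tol &&
    s[["II"]] <= n * s[["I"]] * (1 + tol) + tol &&
    s[["SI"]] <= n * s[["S"]] * (1 + tol) + tol &&
    s[["SI"]] <= n * s[["I"]] * (1 + tol) + tol
  isTRUE(ok)
}

#' Standard initial conditions for the closed pairwise systems
#'
#' Seeds the epidemic with `I0` infected nodes placed uniformly at random,
#' which makes all pair counts take their random-labelling values:
#' \deqn{[S]_0 = N - I_0,\quad [I]_0 = I_0,\quad [SI]_0 = n I_0 S_0 / N,\quad
#'       [SS]_0 = n S_0^2 / N,\quad [II]_0 = n I_0^2 / N.}
#' At these initial conditions all pair correlations equal one (see
#' [correlations()]).
#'
#' @param params A [model_params()] object.
#' @param I0 Initial expected number of infected nodes, \eqn{0 < I_0 < N}.
#'   Defaults to 1.
#' @return A [pairwise_state()].
#' @examples
#' p <- model_params(10000, 5, 1, 1, 0.5)
#' initial_conditions(p, I0 = 1)
#' @export
initial_conditions <- function(params, I0 = 1) {
  stopifnot(inherits(params, "pw_params"))
  if (!is.numeric(I0) || length(I0) != 1L || !is.finite(I0) ||
      I0 <= 0 || I0 >= params$N)
    stop("I0 must satisfy 0 < I0 < N", call. = FALSE)
  N <- params$N; n <- params$n
  S0 <- N - I0
  pairwise_state(S = S0, I = I0,
                 SI = n * I0 * S0 / N,
                 SS = n * S0 * S0 / N,
                 II = n * I0 * I0 / N)
}

#' Pair correlation factors
#'
#' The correlation factor \eqn{C_{AB} = N[AB] / (n[A][B])} compares the
#' observed pair count to its value under random labelling: \eqn{C_{AB} > 1}
#' indicates positive correlation between the states of neighbouring nodes,
#' \eqn{C_{AB} < 1} negative correlation. During an SIR epidemic one expects
#' \eqn{C_{SI} \le 1}, \eqn{C_{II} \ge 1} and \eqn{C_{SS} \ge 1}.
#'
#' @param state A [pairwise_state()] with `S > 0` and `I > 0`.
#' @param params A [model_params()] object.
#' @return A list with elements `C_SI`, `C_II`, `C_SS`.
#' @export
correlations <- function(state, params) {
  stopifnot(inherits(params, "pw_params"))
  s <- unclass(state)
  if (s[["S"]] <= 0 || s[["I"]] <= 0)
    stop("correlations are undefined when [S] or [I] is zero", call. = FALSE)
  N <- params$N; n <- params$n
  list(C_SI = N * s[["SI"]] / (n * s[["S"]] * s[["I"]]),
       C_II = N * s[["II"]] / (n * s[["I"]]^2),
       C_SS = N * s[["SS"]] / (n * s[["S"]]^2))
}
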