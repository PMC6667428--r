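#' Right-hand side of the closed pairwise SIR system
#'
#' Evaluates the time derivatives of the expected counts
#' \eqn{([S], [I], [SI], [SS], [II])} for the pairwise SIR model closed with
#' either the simple clustered closure or the compact improved closure. The
#' unclosed equations are
#' \deqn{\dot{[S]} = -\tau[SI],\quad \dot{[I]} = \tau[SI] - \gamma[I],}
#' \deqn{\dot{[SI]} = \tau([SSI] - [ISI] - [SI]) - \gamma[SI],\quad
#'       \dot{[SS]} = -2\tau[SSI],\quad
#'       \dot{[II]} = 2\tau([ISI] + [SI]) - 2\gamma[II],}
#' with the triples supplied by the requested closure (see [closures]).
#' Divisions are evaluated in a factored form so that any term carrying a
#' \eqn{1/[I]} or \eqn{1/[I]^2} is multiplied by at least one power of
#' \eqn{[SI]} or \eqn{[II]} and is defined as zero when that numerator
#' vanishes; this matches the limits implicit in the closed equations and
#' avoids spurious failures at extinction.
#'
#' @param state A [pairwise_state()] (or named numeric with the same fields).
#' @param params A [model_params()] object.
#' @param closure `"simple"` or `"compact_improved"`.
#' @return Named numeric vector of derivatives `(S, I, SI, SS, II)`.
#' @export
rhs_closed <- function(state, params, closure = c("simple", "compact_improved")) {
  closure <- match.arg(closure)
  s <- unclass(state)
  tau <- params$tau; gamma <- params$gamma
  trip <- switch(closure,
    simple = triples_simple(s[["S"]], s[["I"]], s[["SI"]], s[["SS"]], s[["II"]], params),
    compact_improved = triples_compact_improved(s[["S"]], s[["I"]], s[["SI"]],
                                                s[["SS"]], s[["II"]], params))
  SSI <- trip[["SSI"]]; ISI <- trip[["ISI"]]
  c(S = -tau * s[["SI"]],
    I = tau * s[["SI"]] - gamma * s[["I"]],
    SI = tau * (SSI - ISI - s[["SI"]]) - gamma * s[["SI"]],
    SS = -2 * tau * SSI,
    II = 2 * tau * (ISI + s[["SI"]]) - 2 * gamma * s[["II"]])
}

#' Integrate the closed pairwise SIR system
#'
#' Solves the closed five-dimensional system with an adaptive stiff-capable
#' method (`deSolve::lsoda`). The fast--slow structure of the system makes it
#' mildly stiff at early times, hence the tight default tolerances.
#'
#' @inheritParams rhs_closed
#' @param I0 Initial infected count, passed to [initial_conditions()].
#' @param t_max Integration horizon (default 1000, long enough for the
#'   epidemic to die out at the default parameters).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param times Optional explicit output time points (must start at 0);
#'   by default 501 equally spaced points on `[0, t_max]`.
#' @return An object of class `pw_trajectory`: a list with elements `times`,
#'   `states` (a data.frame with columns `time, S, I, SI, SS, II`), `params`
#'   and `closure`.
#' @examples
#' p <- model_params(10000, 5, 1, 1, 0.5)
#' tr <- integrate_epidemic(p, "simple", t_max = 30)
#' max(tr$states$I) / p$N  # peak prevalence
#' @export
integrate_epidemic <- function(params, closure = c("simple", "compact_improved"),
                               I0 = 1, t_max = 1000, rtol = 1e-8, atol = 1e-10,
                               times = NULL) {
  closure <- match.arg(closure)
  stopifnot(inherits(params, "pw_params"))
  y0 <- unclass(initial_conditions(params, I0))
  if (is.null(times)) times <- seq(0, t_max, length.out = 501L)
  deriv <- function(t, y, parms) {
    # clip tiny negative excursions produced by the solver
    y[y < 0 & y > -atol * 10] <- 0
    list(rhs_closed(y, params, closure))
  }
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("ODE solver failed (istate = %d) for closure '%s'",
                 attr(sol, "istate")[1L], closure), call. = FALSE)
  states <- as.data.frame(sol)
  names(states)[1L] <- "time"
  structure(list(times = states$time, states = states, params = params,
                 closure = closure),
            class = "pw_trajectory")
}

#' @export
print.pw_trajectory <- function(x, ...) {
  cat(sprintf("Pairwise SIR trajectory (%s closure), %d time points on [0, %g]\n",
              x$closure, length(x$times), max(x$times)))
  cat(sprintf("  peak prevalence [I]/N = %.4g, final [S]/N = %.4g\n",
              max(x$states$I) / x$params$N,
              x$states$S[nrow(x$states)] / x$params$N))
  invisible(x)
}

#' Final epidemic size (attack rate)
#'
#' Integrates the closed system to `t_max` and returns the fraction of the
#' population ever infected, \eqn{(N - [S](t_{max}))/N} (initial seeds
#' included).
#'
#' @inheritParams integrate_epidemic
#' @return Attack rate in \eqn{[0, 1]}.
#' @export
final_epidemic_size <- function(params, closure = c("simple", "compact_improved"),
                                I0 = 1, t_max = 1000) {
  closure <- match.arg(closure)
  # only the endpoint is needed; keep the output grid small
  tr <- integrate_epidemic(params, closure, I0 = I0, t_max = t_max,
                           times = c(0, t_max / 2, t_max))
  S_end <- tr$states$S[nrow(tr$states)]
  (params$N - S_end) / params$N
}

#' Export a trajectory to CSV with a JSON metadata sidecar
#'
#' Writes the state table as CSV (columns `time,S,I,SI,SS,II`) and the model
#' parameters plus closure tag as a JSON sidecar next to it.
#'
#' @param trajectory A `pw_trajectory` from [integrate_epidemic()].
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path; defaults to `csv_path` with extension
#'   `.json`.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(trajectory, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(trajectory, "pw_trajectory"))
  utils::write.csv(trajectory$states, csv_path, row.names = FALSE)
  meta <- c(unclass(trajectory$params), list(closure = trajectory$closure))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
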