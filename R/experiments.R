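#' Specification of a threshold/final-size parameter sweep
#'
#' @param tau_grid Ordered positive transmission rates.
#' @param n_grid Ordered degrees, each \eqn{\ge 3}.
#' @param phi_list Clustering coefficients in \eqn{[0, 1]}.
#' @param gamma Recovery rate (default 1, so time is measured in infectious
#'   periods).
#' @param N Population size (default 10000).
#' @param closure Closure tag for the ODE integrations.
#' @param I0 Seed count (default 1).
#' @param t_max Integration horizon (default 1000).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(tau_grid = seq(0.05, 2, by = 0.05),
                       n_grid = 3:15,
                       phi_list = c(0, 0.15, 0.3, 0.45, 0.6),
                       gamma = 1, N = 10000,
                       closure = c("simple", "compact_improved"),
                       I0 = 1, t_max = 1000) {
  closure <- match.arg(closure)
  stopifnot(length(tau_grid) >= 1L, !is.unsorted(tau_grid), all(tau_grid >= 0),
            length(n_grid) >= 1L, !is.unsorted(n_grid), all(n_grid >= 3),
            length(phi_list) >= 1L, all(phi_list >= 0 & phi_list <= 1),
            gamma > 0, N > 0, I0 > 0, I0 < N, t_max > 0)
  structure(list(tau_grid = tau_grid, n_grid = n_grid, phi_list = phi_list,
                 gamma = gamma, N = N, closure = closure, I0 = I0,
                 t_max = t_max),
            class = "sweep_spec")
}

#' Run a threshold and final-size sweep
#'
#' For every grid point \eqn{(n, \tau, \phi)} in the spec, integrates the
#' closed pairwise system to obtain the final epidemic size and computes the
#' epidemic threshold both from the steady-state cubic and from the
#' first-order asymptotic expansion. Grid points where the fast subsystem has
#' no feasible interior steady state are recorded with `feasible = FALSE`
#' and `NA` thresholds; individual failures never abort the sweep.
#'
#' @param spec A [sweep_spec()].
#' @return A list of class `sweep_result` with `records` (a data.frame with
#'   columns `n, tau, phi, final_size, R_cubic, R_asymptotic, feasible`) and
#'   `spec`.
#' @export
run_threshold_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(tau = spec$tau_grid, n = spec$n_grid,
                      phi = spec$phi_list, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tau <- grid$tau[i]; n <- grid$n[i]; phi <- grid$phi[i]
    p <- model_params(spec$N, n, tau, spec$gamma, phi)
    fs <- tryCatch(final_epidemic_size(p, spec$closure, spec$I0, spec$t_max),
                   error = function(e) NA_real_)
    feasible <- if (spec$closure == "simple")
      stability_conditions(p)$feasibility_ok else TRUE
    Rc <- Ra <- NA_real_
    if (feasible && tau > 0) {
      Rc <- tryCatch(threshold(p, spec$closure, "cubic_numeric")$R,
                     error = function(e) NA_real_)
      Ra <- tryCatch(threshold(p, spec$closure, "asymptotic")$R,
                     error = function(e) NA_real_)
      if (is.na(Rc)) feasible <- FALSE
    } else if (tau == 0) {
      Rc <- Ra <- 0
    }
    data.frame(n = n, tau = tau, phi = phi, final_size = fs,
               R_cubic = Rc, R_asymptotic = Ra, feasible = feasible)
  })
  structure(list(records = do.call(rbind, rows), spec = spec),
            class = "sweep_result")
}

#' Export sweep records to CSV with a JSON metadata sidecar
#'
#' @param result A `sweep_result` from [run_threshold_sweep()].
#' @param csv_path Output CSV path.
#' @param json_path Output JSON sidecar path.
#' @return Invisibly, the CSV path.
#' @export
write_sweep <- function(result, csv_path,
                        json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(result, "sweep_result"))
  utils::write.csv(result$records, csv_path, row.names = FALSE)
  meta <- c(unclass(result$spec),
            list(package_version = as.character(utils::packageVersion("pairwiseSIR"))))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Critical transmission rate contour R = 1
#'
#' For each degree in `n_grid`, finds by bisection the transmission rate
#' \eqn{\tau_c} at which the chosen threshold crosses 1 (the threshold is
#' monotone increasing in \eqn{\tau} at fixed \eqn{n, \phi}; the bracket is
#' checked before bisecting). At \eqn{\phi = 0} the closed form is
#' \eqn{\tau_c = \gamma/(n-2)} for both closures.
#'
#' @param n_grid Degrees (each > 2).
#' @param phi Clustering coefficient.
#' @param gamma Recovery rate.
#' @param closure Closure tag.
#' @param method Threshold method, `"cubic_numeric"` or `"asymptotic"`.
#' @param target Threshold level to cross (default 1).
#' @param tau_range Bracketing interval for the bisection.
#' @param tol Bisection tolerance on \eqn{|R - target|} (in \eqn{\tau}).
#' @param N Population size stored in the parameter objects (the threshold
#'   itself does not depend on it).
#' @return A data.frame with columns `n`, `tau_critical`; degrees whose
#'   bracket contains no sign change are omitted with a warning.
#' @export
extract_threshold_contour <- function(n_grid, phi, gamma = 1,
                                      closure = c("simple", "compact_improved"),
                                      method = c("cubic_numeric", "asymptotic"),
                                      target = 1, tau_range = c(1e-4, 10),
                                      tol = 1e-8, N = 10000) {
  closure <- match.arg(closure)
  method <- match.arg(method)
  rows <- lapply(n_grid, function(n) {
    f <- function(tau) {
      p <- model_params(N, n, tau, gamma, phi)
      tryCatch(threshold(p, closure, method)$R - target,
               error = function(e) NA_real_)
    }
    flo <- f(tau_range[1L]); fhi <- f(tau_range[2L])
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      warning(sprintf("no R = %g crossing in tau bracket for n = %g", target, n))
      return(NULL)
    }
    tau_c <- stats::uniroot(f, tau_range, tol = tol)$root
    data.frame(n = n, tau_critical = tau_c)
  })
  do.call(rbind, rows)
}

#' Time course of prevalence and fast variables
#'
#' Integrates the closed pairwise system and reports, at each output time,
#' the prevalence \eqn{[I]/N} and the fast variables
#' \eqn{\alpha = [SI]/[I]}, \eqn{\delta = [II]/[I]}. At the reference
#' parameters (\eqn{N = 10^4}, \eqn{n = 5}, \eqn{\phi = 0.5},
#' \eqn{\tau = \gamma = 1}) both fast variables visibly plateau at their
#' quasi-equilibrium well before prevalence peaks.
#'
#' @inheritParams integrate_epidemic
#' @return A data.frame with columns `t`, `prevalence`, `alpha`, `delta`.
#' @export
timecourse_report <- function(params, closure = c("simple", "compact_improved"),
                              I0 = 1, t_max = 1000, times = NULL) {
  closure <- match.arg(closure)
  tr <- integrate_epidemic(params, closure, I0 = I0, t_max = t_max,
                           times = times)
  st <- tr$states
  data.frame(t = st$time,
             prevalence = st$I / params$N,
             alpha = ifelse(st$I > 0, st$SI / st$I, NA_real_),
             delta = ifelse(st$I > 0, st$II / st$I, NA_real_))
}

#' Phase-plane data for the fast subsystem
#'
#' Samples the null clines of the fast subsystem over the invariant region D
#' (windowing singularities), the boundary \eqn{\alpha + \delta = n}, and one
#' trajectory of [rhs_fast()] from the fast-variable image of the standard
#' initial conditions. The trajectory is integrated until it is within
#' `1e-6` of the quasi-equilibrium. When the parameters are infeasible the
#' boundary and trajectory are still returned, with a warning.
#'
#' @inheritParams rhs_fast
#' @param n_points Number of sample points per curve.
#' @return A data.frame with columns `alpha`, `delta`, `source` where
#'   `source` is one of `"nullcline1"`, `"nullcline2"`, `"boundary"`,
#'   `"trajectory"`.
#' @export
phase_plane_report <- function(params, closure = c("simple", "compact_improved"),
                               n_points = 200L) {
  closure <- match.arg(closure)
  n <- params$n
  pieces <- list()
  nc <- tryCatch(nullclines(params, closure), error = function(e) NULL)
  safe_eval <- function(f, x) vapply(x, function(xx)
    tryCatch(f(xx), error = function(e) NA_real_), numeric(1))
  if (!is.null(nc)) {
    grid <- seq(1e-4, n, length.out = n_points)
    if (closure == "simple") {
      d1 <- safe_eval(nc$delta1, grid); d2 <- safe_eval(nc$delta2, grid)
      pieces$n1 <- data.frame(alpha = grid, delta = d1, source = "nullcline1")
      pieces$n2 <- data.frame(alpha = grid, delta = d2, source = "nullcline2")
    } else {
      d1 <- safe_eval(nc$delta_n, grid)
      dgrid <- seq(0, n, length.out = n_points)
      a2 <- safe_eval(nc$alpha_n, dgrid)
      pieces$n1 <- data.frame(alpha = grid, delta = d1, source = "nullcline1")
      pieces$n2 <- data.frame(alpha = a2, delta = dgrid, source = "nullcline2")
    }
    # window to D with a margin; poles become NA rows which are dropped
    for (k in c("n1", "n2")) {
      d <- pieces[[k]]
      keep <- is.finite(d$alpha) & is.finite(d$delta) &
        d$delta >= -0.1 * n & d$delta <= 1.1 * n & d$alpha >= -0.1 * n &
        d$alpha <= 1.1 * n
      pieces[[k]] <- d[keep, ]
    }
  }
  b <- seq(0, n, length.out = n_points)
  pieces$boundary <- data.frame(alpha = b, delta = n - b, source = "boundary")
  qe <- tryCatch(quasi_equilibrium(params, closure), error = function(e) NULL)
  if (is.null(qe))
    warning("infeasible parameters: returning boundary and trajectory only")
  y <- c(alpha = n * (params$N - 1) / params$N, delta = n / params$N)
  deriv <- function(t, y, parms) list(rhs_fast(y, params, closure))
  tt <- seq(0, 50 / params$gamma, length.out = 500L)
  sol <- deSolve::lsoda(y, tt, deriv, parms = NULL, rtol = 1e-10, atol = 1e-12)
  traj <- data.frame(alpha = sol[, "alpha"], delta = sol[, "delta"],
                     source = "trajectory")
  if (!is.null(qe)) {
    dist <- sqrt((traj$alpha - qe[["alpha"]])^2 + (traj$delta - qe[["delta"]])^2)
    cut <- which(dist < 1e-6)[1L]
    if (!is.na(cut)) traj <- traj[seq_len(cut), ]
  }
  pieces$trajectory <- traj
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Read a model configuration file
#'
#' Reads a YAML or JSON configuration with keys `N`, `n`, `tau`, `gamma`,
#' `phi`, `closure`, `I0`, `t_max`, `rtol`, `atol` (missing keys fall back
#' to defaults). Used by the command-line interface; exported so scripted
#' analyses can share configuration files with it.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params` (a [model_params()]), `closure`,
#'   `I0`, `t_max`, `rtol`, `atol`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- list(N = 10000, n = 5, tau = 1, gamma = 1, phi = 0,
                   closure = "simple", I0 = 1, t_max = 1000,
                   rtol = 1e-8, atol = 1e-10)
  cfg <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
  list(params = model_params(cfg$N, cfg$n, cfg$tau, cfg$gamma, cfg$phi),
       closure = match.arg(cfg$closure, c("simple", "compact_improved")),
       I0 = cfg$I0, t_max = cfg$t_max, rtol = cfg$rtol, atol = cfg$atol)
}
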