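#' Household model parameters
#'
#' Parameters for a two-layer network model: complete households of size
#' three plus global contacts assigned as a configuration-like network with
#' regular global degree \eqn{\mu_D}. With equal infection rates on both
#' layers, the households act purely as a device for introducing clustering.
#'
#' @param lambda_G Global (between-household) per-link infection rate.
#' @param lambda_L Local (within-household) per-link infection rate.
#' @param gamma Recovery rate, > 0.
#' @param mu_D Mean (regular) global degree, \eqn{\ge 0}.
#' @return An object of class `household_params`.
#' @export
household_params <- function(lambda_G, lambda_L, gamma, mu_D) {
  stopifnot(lambda_G >= 0, lambda_L >= 0, gamma > 0, mu_D >= 0)
  structure(list(lambda_G = lambda_G, lambda_L = lambda_L,
                 gamma = gamma, mu_D = mu_D),
            class = "household_params")
}

#' Clustering coefficient of the size-three household network
#'
#' For households of size three with regular global degree \eqn{\mu_D}, the
#' global clustering coefficient is
#' \eqn{\phi = 2 / (2 + \mu_D(3 + \mu_D))}, with inverse
#' \eqn{\mu_D = \frac{1}{2}\sqrt{1 + 8/\phi} - \frac{3}{2}}.
#'
#' @param mu_D Regular global degree, \eqn{\ge 0}.
#' @param phi Clustering coefficient in \eqn{(0, 1]}.
#' @return `household_phi()` returns \eqn{\phi}; `household_mu_D()` returns
#'   \eqn{\mu_D}.
#' @export
household_phi <- function(mu_D) {
  stopifnot(mu_D >= 0)
  2 / (2 + mu_D * (3 + mu_D))
}

#' @rdname household_phi
#' @export
household_mu_D <- function(phi) {
  if (phi <= 0 || phi > 1)
    stop("mu_D is finite only for phi in (0, 1] (phi = 0 needs infinite global degree)",
         call. = FALSE)
  0.5 * sqrt(1 + 8 / phi) - 1.5
}

#' Household reproduction number R*
#'
#' The threshold parameter of the two-layer household model:
#' \deqn{R_* = (1 - M(\lambda_G))\left((1 + \mu_T)\mu_D - 1\right),}
#' where \eqn{M(\theta) = \theta/(\gamma+\theta)} and
#' \deqn{\mu_T = 2\left[1 - M^2(\lambda_L) -
#'       M(2\lambda_L)(1 - M(\lambda_L))\right]}
#' is the mean number of secondary within-household cases. \eqn{R_*} is a
#' household-level reproduction number: it is not the classical \eqn{R_0},
#' but both cross one together. Written in terms of the clustering
#' coefficient via \eqn{\mu_D = \frac{1}{2}\sqrt{1+8/\phi} - \frac{3}{2}},
#' \deqn{R_* = T_1 + T_2\sqrt{1 + 8/\phi},\qquad
#'       T_1 = -(1-M(\lambda_G))\left(1 + \tfrac{3}{2}(1+\mu_T)\right),\quad
#'       T_2 = \tfrac{1}{2}(1-M(\lambda_G))(1+\mu_T),}
#' so \eqn{R_*} decreases as \eqn{\phi} increases, like
#' \eqn{O(\phi^{-1/2})} for small \eqn{\phi} (the small-\eqn{\phi} series is
#' \eqn{R_* \approx T_1 + 2\sqrt{2}\,T_2/\sqrt{\phi} +
#' T_2\sqrt{\phi}/(4\sqrt{2})}).
#'
#' @param hh A [household_params()] object.
#' @param phi Optional clustering coefficient in \eqn{(0, 1]}; when given,
#'   the global degree is derived as \eqn{\mu_D(\phi)} and overrides
#'   `hh$mu_D`.
#' @return A `threshold_result` with extra fields `mu_D`, `mu_T`, `T1`,
#'   `T2` and `series` (the truncated small-\eqn{\phi} series value, `NA`
#'   when `phi` is not supplied).
#' @examples
#' hh <- household_params(lambda_G = 1, lambda_L = 1, gamma = 1, mu_D = 2)
#' household_R_star(hh)$R
#' @export
household_R_star <- function(hh, phi = NULL) {
  stopifnot(inherits(hh, "household_params"))
  gamma <- hh$gamma
  M <- function(theta) theta / (gamma + theta)
  mu_D <- if (is.null(phi)) hh$mu_D else household_mu_D(phi)
  ML <- M(hh$lambda_L)
  mu_T <- 2 * (1 - ML^2 - M(2 * hh$lambda_L) * (1 - ML))
  MG <- M(hh$lambda_G)
  R <- (1 - MG) * ((1 + mu_T) * mu_D - 1)
  T1 <- -(1 - MG) - 1.5 * (1 - MG) * (1 + mu_T)
  T2 <- 0.5 * (1 - MG) * (1 + mu_T)
  series <- if (is.null(phi)) NA_real_ else
    T1 + 2 * sqrt(2) * T2 / sqrt(phi) + T2 * sqrt(phi) / (4 * sqrt(2))
  threshold_result(R, "household",
                   extra = list(mu_D = mu_D, mu_T = mu_T, T1 = T1, T2 = T2,
                                series = series))
}
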