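#' Moment closures for the triples [ASI]
#'
#' The unclosed pairwise SIR system involves the expected triple counts
#' \eqn{[SSI]} and \eqn{[ISI]}. Each closure expresses a triple \eqn{[ASI]}
#' in terms of pairs and singles, making the system self-contained:
#'
#' * `closure_unclustered()`: \eqn{[ASI] = \frac{n-1}{n}\frac{[AS][SI]}{[S]}},
#'   valid for networks without clustering. It conserves the pair-level
#'   relation \eqn{\sum_A [ASI] = (n-1)[SI]}.
#' * `closure_simple()`: the classic clustered closure,
#'   \eqn{[ASI] = \frac{n-1}{n}\frac{[AS][SI]}{[S]}\left((1-\phi) +
#'   \phi\frac{N[AI]}{n[A][I]}\right)}, which discounts (or inflates) the
#'   unclustered estimate by the pair correlation \eqn{C_{AI}} on the
#'   clustered part of the network. For \eqn{\phi > 0} it does not conserve
#'   \eqn{\sum_A [ASI] = (n-1)[SI]}.
#' * `closure_improved_full()`: the improved closure, which renormalises the
#'   clustered part over all states \eqn{a \in \{S, I, R\}} so that the
#'   pair-level relation holds exactly:
#'   \eqn{[ASI] = (n-1)\left((1-\phi)\frac{[AS][SI]}{n[S]} +
#'   \phi\frac{[AS][SI][IA]}{[A]\sum_a [aS][aI]/[a]}\right)}.
#' * `closure_compact_improved()`: the same construction but with the
#'   normalising sum restricted to \eqn{a \in \{S, I\}} (the recovered class
#'   is dropped from the clustered part), which keeps the closed system in
#'   the five dynamically relevant variables:
#'   \eqn{[ASI] = (n-1)\left((1-\phi)\frac{[AS][SI]}{n[S]} +
#'   \phi\frac{[AS][SI][IA]}{[A]\left([SS][SI]/[S] + [SI][II]/[I]\right)}\right)}.
#'
#' All closures reduce to the unclustered one at \eqn{\phi = 0}, and on any
#' random-labelling state (all pair correlations equal to one).
#'
#' @param state A [pairwise_state()].
#' @param params A [model_params()] object.
#' @param A Which triple to close: `"S"` for \eqn{[SSI]}, `"I"` for
#'   \eqn{[ISI]} (and `"R"` for \eqn{[RSI]} in `closure_improved_full()`).
#' @param SR,IR For `closure_improved_full()` only: the expected pair counts
#'   \eqn{[SR]} and \eqn{[IR]} (the recovered single count is taken as
#'   \eqn{N - [S] - [I]}).
#' @return An object of class `triple_estimate`: a list with fields `value`
#'   (the closed triple count), `kind` (`"[SSI]"`, `"[ISI]"` or `"[RSI]"`)
#'   and `closure`.
#' @examples
#' p <- model_params(10000, 5, 1, 1, 0.5)
#' st <- pairwise_state(S = 9000, I = 100, SI = 500, SS = 40000, II = 80)
#' closure_simple(st, p, "S")
#' @name closures
NULL

triple_estimate <- function(value, A, closure) {
  structure(list(value = value,
                 kind = paste0("[", A, "SI]"),
                 closure = closure),
            class = "triple_estimate")
}

#' @export
print.triple_estimate <- function(x, ...) {
  cat(sprintf("%s = %g  (%s closure)\n", x$kind, x$value, x$closure))
  invisible(x)
}

#' @rdname closures
#' @export
closure_unclustered <- function(state, params, A = c("S", "I")) {
  A <- match.arg(A)
  s <- unclass(state)
  if (s[["S"]] <= 0)
    stop("unclustered closure undefined at [S] = 0", call. = FALSE)
  AS <- if (A == "S") s[["SS"]] else s[["SI"]]
  val <- params$xi * AS * s[["SI"]] / s[["S"]]
  triple_estimate(val, A, "unclustered")
}

#' @rdname closures
#' @export
closure_simple <- function(state, params, A = c("S", "I")) {
  A <- match.arg(A)
  s <- unclass(state)
  if (s[["S"]] <= 0 || s[["I"]] <= 0)
    stop("simple closure undefined when [S] or [I] is zero", call. = FALSE)
  N <- params$N; n <- params$n; phi <- params$phi
  AS <- if (A == "S") s[["SS"]] else s[["SI"]]
  AI <- if (A == "S") s[["SI"]] else s[["II"]]
  Acount <- if (A == "S") s[["S"]] else s[["I"]]
  C_AI <- N * AI / (n * Acount * s[["I"]])
  val <- params$xi * AS * s[["SI"]] / s[["S"]] * ((1 - phi) + phi * C_AI)
  triple_estimate(val, A, "simple")
}

#' @rdname closures
#' @export
closure_improved_full <- function(state, params, A = c("S", "I", "R"),
                                  SR = 0, IR = 0) {
  A <- match.arg(A)
  s <- unclass(state)
  N <- params$N; n <- params$n; phi <- params$phi
  R <- N - s[["S"]] - s[["I"]]
  singles <- c(S = s[["S"]], I = s[["I"]], R = R)
  aS <- c(S = s[["SS"]], I = s[["SI"]], R = SR)
  aI <- c(S = s[["SI"]], I = s[["II"]], R = IR)
  if (any(singles[c("S", "I")] <= 0))
    stop("improved closure undefined when [S] or [I] is zero", call. = FALSE)
  # terms with [a] = 0 contribute zero to the normalising sum only if their
  # pair numerators vanish too
  terms <- ifelse(singles > 0, aS * aI / ifelse(singles > 0, singles, 1), NA)
  if (any(is.na(terms) & (aS * aI != 0)))
    stop("improved closure: [a] = 0 with non-zero pairs", call. = FALSE)
  terms[is.na(terms)] <- 0
  norm_sum <- sum(terms)
  if (singles[[A]] <= 0)
    stop(sprintf("improved closure undefined when [%s] = 0", A), call. = FALSE)
  if (norm_sum <= 0 && phi > 0)
    stop("improved closure: normalising sum is zero", call. = FALSE)
  clustered <- if (phi > 0)
    aS[[A]] * s[["SI"]] * aI[[A]] / (singles[[A]] * norm_sum) else 0
  val <- (n - 1) * ((1 - phi) * aS[[A]] * s[["SI"]] / (n * s[["S"]]) + phi * clustered)
  triple_estimate(val, A, "improved_full")
}

#' @rdname closures
#' @export
closure_compact_improved <- function(state, params, A = c("S", "I")) {
  A <- match.arg(A)
  s <- unclass(state)
  if (s[["S"]] <= 0 || s[["I"]] <= 0)
    stop("compact improved closure undefined when [S] or [I] is zero",
         call. = FALSE)
  n <- params$n; phi <- params$phi
  AS <- if (A == "S") s[["SS"]] else s[["SI"]]
  IA <- if (A == "S") s[["SI"]] else s[["II"]]
  Acount <- if (A == "S") s[["S"]] else s[["I"]]
  numer <- AS * s[["SI"]] * IA
  denom <- Acount * (s[["SS"]] * s[["SI"]] / s[["S"]] +
                       s[["SI"]] * s[["II"]] / s[["I"]])
  clustered <- if (phi == 0 || numer == 0) {
    0
  } else if (denom <= 0) {
    stop("compact improved closure: zero denominator with non-zero numerator",
         call. = FALSE)
  } else numer / denom
  val <- (n - 1) * ((1 - phi) * AS * s[["SI"]] / (n * s[["S"]]) + phi * clustered)
  triple_estimate(val, A, "compact_improved")
}

# --- internal guarded closure kernels used by the ODE right-hand sides -----
#
# Return c(SSI, ISI) with every division factored so that terms carrying a
# 1/[I] or 1/[I]^2 are multiplied by at least one power of [SI] or [II]; a
# term whose numerator is exactly zero is defined as zero. This matches the
# limits implicit in the closed equations and keeps the solver stable near
# extinction.

triples_simple <- function(S, I, SI, SS, II, params) {
  n <- params$n; N <- params$N; phi <- params$phi; xi <- params$xi
  if (S <= 0 || SI == 0) return(c(SSI = 0, ISI = 0))
  base_S <- xi * SS * SI / S
  base_I <- xi * SI * SI / S
  corr_S <- if (SI == 0 || I <= 0) 0 else phi * N * SI / (n * S * I)
  corr_I <- if (II == 0 || I <= 0) 0 else phi * N * II / (n * I * I)
  c(SSI = base_S * ((1 - phi) + corr_S),
    ISI = base_I * ((1 - phi) + corr_I))
}

triples_compact_improved <- function(S, I, SI, SS, II, params) {
  n <- params$n; phi <- params$phi
  if (S <= 0 || SI == 0) return(c(SSI = 0, ISI = 0))
  base_S <- (1 - phi) * SS * SI / (n * S)
  base_I <- (1 - phi) * SI * SI / (n * S)
  # clustered parts in the equivalent form
  #   [A=S]: SS*SI*I / (SS*I + II*S),  [A=I]: SI*II*S / (SS*I + II*S)
  den <- SS * I + II * S
  if (phi > 0 && den > 0) {
    clu_S <- SS * SI * I / den
    clu_I <- SI * II * S / den
  } else {
    clu_S <- 0; clu_I <- 0
  }
  c(SSI = (n - 1) * (base_S + phi * clu_S),
    ISI = (n - 1) * (base_I + phi * clu_I))
}
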