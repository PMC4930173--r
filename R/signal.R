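#' Define an external chemoattractant field
#'
#' The external signal `S(r, t)` that regulates the susceptibility to
#' contact inhibition of locomotion. Individual cells sense only this local
#' level, never its gradient. Supported kinds:
#' \describe{
#'   \item{uniform}{`S = S0` everywhere.}
#'   \item{linear}{`S = S0 + S1 * (axis . r)`; sampling a non-positive
#'     value is an error rather than a clamp.}
#'   \item{exponential}{`S = S0 * exp(S1 * (axis . r))`, the shallow
#'     gradient used throughout, because its relative gradient is
#'     position-independent.}
#'   \item{step_in_time}{uniform `S0` before `t_step`, `S0_after` after;
#'     used to probe adaptation.}
#' }
#'
#' @param kind Field type, see above.
#' @param S0 Base signal level (must be positive).
#' @param S1 Gradient parameter per cell diameter (linear/exponential).
#' @param axis Gradient direction; normalized internally.
#' @param t_step,S0_after Step time and post-step level for
#'   `"step_in_time"`.
#' @return An object of class `signal_field`.
#' @examples
#' sf <- signal_field("exponential", S0 = 1, S1 = 0.025)
#' signal_at(sf, c(40, 0)) # exp(1)
#' @export
signal_field <- function(kind = c("uniform", "linear", "exponential",
                                  "step_in_time"),
                         S0 = 1, S1 = 0, axis = c(1, 0),
                         t_step = NA_real_, S0_after = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(S0 > 0, length(axis) == 2, is.finite(S1))
  nr <- sqrt(sum(axis^2))
  if (nr <= 0) rlang::abort("signal_field: axis must be a nonzero vector")
  if (kind == "step_in_time") {
    stopifnot(is.finite(t_step), is.finite(S0_after), S0_after > 0)
  }
  structure(list(kind = kind, S0 = S0, S1 = S1, axis = axis / nr,
                 t_step = t_step, S0_after = S0_after),
            class = "signal_field")
}

#' @export
print.signal_field <- function(x, ...) {
  cat("<signal_field> kind=", x$kind, " S0=", x$S0,
      if (x$kind %in% c("linear", "exponential")) paste0(" S1=", x$S1),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a signal field
#'
#' @param field A [signal_field()].
#' @param r A length-2 position, an N x 2 matrix, or a data frame with
#'   columns `x`, `y`.
#' @param t Time (only used by `"step_in_time"` fields).
#' @return Numeric vector of signal values, all positive.
#' @export
signal_at <- function(field, r, t = 0) {
  stopifnot(inherits(field, "signal_field"))
  if (is.null(dim(r)) && !is.data.frame(r)) r <- matrix(r, ncol = 2)
  pos <- as_positions(r)
  u <- pos %*% field$axis
  s <- switch(field$kind,
    uniform = rep(field$S0, nrow(pos)),
    linear = field$S0 + field$S1 * drop(u),
    exponential = field$S0 * exp(field$S1 * drop(u)),
    step_in_time = rep(if (t < field$t_step) field$S0 else field$S0_after,
                       nrow(pos)))
  if (any(s <= 0))
    rlang::abort("signal_at: signal is non-positive at a sampled point")
  as.numeric(s)
}

#' Minimal CIL susceptibility
#'
#' The minimal model of signal regulation: the susceptibility to contact
#' inhibition of locomotion is directly proportional to the local signal,
#' `beta_i = beta_bar * S(r_i)`, with no internal processing.
#'
#' @param S Signal level(s), non-negative.
#' @param beta_bar Susceptibility scale.
#' @return `beta_bar * S`.
#' @export
susceptibility_minimal <- function(S, beta_bar) {
  stopifnot(all(S >= 0))
  beta_bar * S
}

#' Switchlike amplification function
#'
#' The sigmoid `g(x) = (1 + tanh((x - 1) / lam)) / 2`, centred at `x = 1`
#' with switch width `lam`. For `lam << 1` this turns the graded response
#' ratio `R/R0` into a nearly binary front/back decision.
#'
#' @param x Dimensionless response ratio (typically `R / R0`).
#' @param lam Switch width (default `1e-2`).
#' @return Values in (0, 1), monotone in `x`, with `g(1) = 1/2` and
#'   `g(1 - d) + g(1 + d) = 1`.
#' @export
amplification_g <- function(x, lam = 1e-2) {
  stopifnot(lam > 0)
  0.5 * (1 + tanh((x - 1) / lam))
}

#' CIL susceptibility from a processed response
#'
#' Maps the per-cell response `R` of the LEGI network to a CIL
#' susceptibility: either linearly, `beta = beta_bar * R / R0`, or through
#' the switchlike amplification `beta = beta_bar * g(R / R0, lam)`. `R0` is
#' the steady-state response in a uniform signal (see [legi_r0()]), so a
#' cell above/below `R0` sits above/below the midpoint of the switch.
#'
#' @param R Per-cell response values (non-negative).
#' @param rates A [legi_rates()] object, used to compute `R0`.
#' @param beta_bar Susceptibility scale.
#' @param mode `"linear"` or `"switch"`.
#' @param lam Switch width for `"switch"` mode.
#' @param R0 Optional explicit normalization, overriding `legi_r0(rates)`.
#' @return Per-cell susceptibilities `beta_i`.
#' @export
susceptibility_from_response <- function(R, rates, beta_bar,
                                         mode = c("linear", "switch"),
                                         lam = 1e-2, R0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(R >= 0))
  if (is.null(R0)) R0 <- legi_r0(rates)
  x <- R / R0
  if (mode == "linear") beta_bar * x else beta_bar * amplification_g(x, lam)
}
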