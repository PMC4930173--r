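#' Model parameters
#'
#' Collects every constant of the coupled position/polarity/LEGI dynamics
#' plus the integration controls. Simulation units: one length unit is a
#' cell diameter (the equilibrium cell-cell separation), one time unit is
#' the polarity relaxation time `tau`.
#'
#' @param tau Polarity relaxation time (default 1; the time unit).
#' @param sigma Polarity noise strength (default 1), giving an isolated
#'   cell an RMS speed of `sqrt(2) * sigma * sqrt(tau)`.
#' @param beta_bar Scale of the susceptibility to contact inhibition of
#'   locomotion.
#' @param v_r,v_a Repulsion and adhesion spring strengths of the pair
#'   force. Rigid clusters use `v_r = v_a = 500`; co-attraction runs use
#'   `v_r = 100, v_a = 0`.
#' @param D0 Interaction and contact range in cell diameters (default
#'   1.2). Contact inhibition acts over exactly this range.
#' @param chi Co-attraction (chemotaxis-to-secretion) strength; 0 disables
#'   the secreted field entirely.
#' @param ell Degradation length of the secreted field (default 5).
#' @param g0 Gradient-magnitude threshold of the co-attraction response.
#' @param response_mode How the signal sets the CIL susceptibility:
#'   `"minimal"` (`beta = beta_bar * S`), `"legi_linear"`
#'   (`beta = beta_bar * R/R0`) or `"legi_switch"`
#'   (`beta = beta_bar * g(R/R0)`).
#' @param lam Switch width of the amplification sigmoid.
#' @param legi [legi_rates()] used by the LEGI modes.
#' @param legi_kinetics `"quasi_static"` (default: only the inhibitor is
#'   integrated in time; activator and response are enslaved to their
#'   steady states) or `"full"` (all three variables integrated).
#' @param dt Integration time step. Defaults to `1e-3`; rigid
#'   high-adhesion runs should use `1e-4`.
#' @return An object of class `model_params`.
#' @examples
#' model_params(beta_bar = 70, chi = 15)
#' @export
model_params <- function(tau = 1, sigma = 1, beta_bar = 20,
                         v_r = 100, v_a = 0, D0 = 1.2,
                         chi = 0, ell = 5, g0 = 1e-5,
                         response_mode = c("minimal", "legi_linear",
                                           "legi_switch"),
                         lam = 1e-2, legi = legi_rates(),
                         legi_kinetics = c("quasi_static", "full"),
                         dt = 1e-3) {
  response_mode <- match.arg(response_mode)
  legi_kinetics <- match.arg(legi_kinetics)
  stopifnot(tau > 0, sigma >= 0, beta_bar >= 0, v_r >= 0, v_a >= 0,
            D0 > 1, chi >= 0, ell > 0, g0 >= 0, lam > 0, dt > 0,
            inherits(legi, "legi_rates"))
  structure(list(tau = tau, sigma = sigma, beta_bar = beta_bar,
                 v_r = v_r, v_a = v_a, D0 = D0, chi = chi, ell = ell,
                 g0 = g0, response_mode = response_mode, lam = lam,
                 legi = legi, legi_kinetics = legi_kinetics, dt = dt),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> mode=", x$response_mode,
      " beta_bar=", x$beta_bar, " chi=", x$chi,
      " v_r=", x$v_r, " v_a=", x$v_a, " D0=", x$D0,
      " dt=", x$dt, "\n", sep = "")
  invisible(x)
}

# Flatten params + signal field into the list the C++ core expects.
cpp_par <- function(params, field) {
  stopifnot(inherits(params, "model_params"),
            inherits(field, "signal_field"))
  mode <- match(params$response_mode,
                c("minimal", "legi_linear", "legi_switch")) - 1L
  kin <- match(params$legi_kinetics, c("quasi_static", "full")) - 1L
  kind <- match(field$kind,
                c("uniform", "linear", "exponential", "step_in_time")) - 1L
  r <- params$legi
  list(dt = params$dt, tau = params$tau, sigma = params$sigma,
       beta_bar = params$beta_bar, v_r = params$v_r, v_a = params$v_a,
       D0 = params$D0, chi = params$chi, ell = params$ell, g0 = params$g0,
       lam = params$lam, response_mode = mode, legi_kinetics = kin,
       kA = r$kA, k_mA = r$k_mA, kI = r$kI, k_mI = r$k_mI,
       kR = r$kR, k_mR = r$k_mR, kD = r$kD,
       r0ref = legi_r0(r),
       sig_kind = kind, S0 = field$S0, S1 = field$S1,
       ax = field$axis[1], ay = field$axis[2],
       t_step = if (is.na(field$t_step)) Inf else field$t_step,
       S0_after = if (is.na(field$S0_after)) field$S0 else field$S0_after)
}
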