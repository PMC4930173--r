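#' Steady states of the reduced rotation model
#'
#' A rigid circular cluster of cells with radial polarity bias admits a
#' two-variable reduction: the total tangential "torque" `Omega` (which is
#' also the rotation rate) and the total radial polarity moment `W` obey
#' `dW/dt = Omega^2 - W/tau + W0/tau` and
#' `dOmega/dt = -(1/tau + W) Omega`, where `W0` collects the radial bias
#' (CIL outward, co-attraction inward; co-attraction drives `W0`
#' negative). The non-rotating state `(Omega, W) = (0, W0)` is stable for
#' `W0 tau > -1`; at `W0 tau = -1` it loses stability in a pitchfork
#' bifurcation to two mirror-image rotating states
#' `Omega = +/- (1/tau) sqrt(-1 - W0 tau)` with `W = -1/tau`.
#'
#' @param W0 Radial-bias parameter (polarity-moment units).
#' @param tau Polarity relaxation time.
#' @return A tibble with columns `omega`, `W`, `stable`.
#' @examples
#' reduced_steady_states(W0 = -2) # rotating states at omega = +/- 1
#' @export
reduced_steady_states <- function(W0, tau = 1) {
  stopifnot(tau > 0)
  out <- tibble::tibble(omega = 0, W = W0, stable = W0 * tau > -1)
  if (W0 * tau < -1) {
    om <- sqrt(-1 - W0 * tau) / tau
    out <- dplyr::bind_rows(out,
      tibble::tibble(omega = c(om, -om), W = -1 / tau, stable = TRUE))
  }
  out
}

#' Integrate the reduced rotation model
#'
#' Solves the two-variable reduced dynamics from given initial conditions.
#' `Omega = 0` is an invariant manifold, so symmetry breaking requires a
#' nonzero initial angular momentum (in the full model, noise provides
#' it).
#'
#' @param W0 Radial-bias parameter.
#' @param W_init,Omega_init Initial conditions.
#' @param T Integration time.
#' @param tau Polarity relaxation time.
#' @param n_out Number of output points.
#' @return A tibble with columns `time`, `W`, `omega`.
#' @export
integrate_reduced <- function(W0, W_init = 0, Omega_init = 0, T = 50,
                              tau = 1, n_out = 501) {
  stopifnot(T > 0, tau > 0)
  deriv <- function(t, y, parms) {
    W <- y[1]; Om <- y[2]
    list(c(Om^2 - W / tau + W0 / tau,
           -(1 / tau + W) * Om))
  }
  sol <- deSolve::ode(y = c(W_init, Omega_init),
                      times = seq(0, T, length.out = n_out),
                      func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  tibble::tibble(time = sol[, 1], W = sol[, 2], omega = sol[, 3])
}

# Residual sum of squares and amplitude for a candidate critical point.
pitchfork_rss <- function(chi_c, chi, y) {
  s <- sqrt(pmax(chi - chi_c, 0))
  denom <- sum(s^2)
  omega0 <- if (denom > 0) max(0, sum(y * s) / denom) else 0
  list(omega0 = omega0, rss = sum((y - omega0 * s)^2))
}

#' Fit a square-root pitchfork to angular velocity versus co-attraction
#'
#' Least-squares fit of the supercritical pitchfork form
#' `|Omega|(chi) = 0` for `chi <= chi_c` and
#' `Omega0 * sqrt(chi - chi_c)` for `chi > chi_c`, jointly over
#' `(Omega0, chi_c)`. For fixed `chi_c` the amplitude has a closed-form
#' least-squares solution, so the fit reduces to a one-dimensional search
#' over `chi_c`: a deterministic dense grid over the data range followed
#' by local refinement, with ties broken toward the smaller residual and
#' then the smaller `chi_c`.
#'
#' @param chi_values Strictly increasing co-attraction strengths (>= 3).
#' @param omega_means Branch-averaged angular-velocity magnitudes at each
#'   `chi`.
#' @return An object of class `pitchfork_fit`: a list with `omega0`,
#'   `chi_c`, `residual` (RSS), `n_points`, and the input `data`.
#' @examples
#' chi <- seq(5, 95, by = 15)
#' y <- ifelse(chi > 25.6, 0.671 * sqrt(pmax(chi - 25.6, 0)), 0)
#' fit_pitchfork(chi, y)
#' @export
fit_pitchfork <- function(chi_values, omega_means) {
  stopifnot(length(chi_values) == length(omega_means),
            length(chi_values) >= 3,
            all(diff(chi_values) > 0),
            all(is.finite(omega_means)))
  if (max(abs(omega_means)) < 1e-12)
    rlang::abort(paste0(
      "fit_pitchfork: all angular velocities are zero; chi_c is not ",
      "identifiable (lower bound: ", max(chi_values), ")"),
      class = "coguide_fit_degenerate")
  y <- abs(omega_means)
  lo <- min(chi_values) - diff(range(chi_values))
  hi <- max(chi_values)
  grid <- seq(lo, hi, length.out = 2001)
  rss <- vapply(grid, function(cc) pitchfork_rss(cc, chi_values, y)$rss,
                numeric(1))
  best <- which(rss <= min(rss) + 1e-15)[1]
  span <- grid[c(max(1, best - 1), min(length(grid), best + 1))]
  opt <- stats::optimize(function(cc) pitchfork_rss(cc, chi_values, y)$rss,
                         interval = span, tol = 1e-10)
  cand <- if (opt$objective < rss[best]) opt$minimum else grid[best]
  sol <- pitchfork_rss(cand, chi_values, y)
  structure(list(omega0 = sol$omega0, chi_c = cand,
                 residual = sol$rss, n_points = length(chi_values),
                 data = tibble::tibble(chi = chi_values, omega = y)),
            class = "pitchfork_fit")
}

#' @export
print.pitchfork_fit <- function(x, ...) {
  cat("<pitchfork_fit> omega0 = ", signif(x$omega0, 4),
      ", chi_c = ", signif(x$chi_c, 4),
      " (RSS ", signif(x$residual, 3), ", n = ", x$n_points, ")\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pitchfork fit
#'
#' @param x A [fit_pitchfork()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.pitchfork_fit <- function(x, ...) {
  tibble::tibble(term = c("omega0", "chi_c"),
                 estimate = c(x$omega0, x$chi_c))
}

#' Glance at a pitchfork fit
#'
#' @param x A [fit_pitchfork()] result.
#' @param ... Unused.
#' @return A one-row tibble with `omega0`, `chi_c`, `residual`,
#'   `n_points`.
#' @export
glance.pitchfork_fit <- function(x, ...) {
  tibble::tibble(omega0 = x$omega0, chi_c = x$chi_c,
                 residual = x$residual, n_points = x$n_points)
}

#' Evaluate a fitted pitchfork curve
#'
#' @param fit A [fit_pitchfork()] result.
#' @param chi Values at which to evaluate.
#' @return `Omega0 * sqrt(max(chi - chi_c, 0))`.
#' @export
predict_pitchfork <- function(fit, chi) {
  stopifnot(inherits(fit, "pitchfork_fit"))
  fit$omega0 * sqrt(pmax(chi - fit$chi_c, 0))
}

#' Branch-averaged angular velocities of a rotation sweep
#'
#' For each co-attraction strength, averages the signed trajectory angular
#' velocities separately over the counter-clockwise and clockwise
#' branches, then averages the branch magnitudes — the standard input to
#' [fit_pitchfork()].
#'
#' @param sweep A tibble with columns `chi` and `omega` (one row per
#'   trajectory), e.g. from [sweep_rotation()].
#' @return A tibble with columns `chi`, `omega` (branch-averaged
#'   magnitude), `n_traj`.
#' @export
branch_average <- function(sweep) {
  stopifnot(all(c("chi", "omega") %in% names(sweep)))
  sweep |>
    dplyr::group_by(.data$chi) |>
    dplyr::summarise(
      omega = {
        pos <- .data$omega[.data$omega > 0]
        neg <- .data$omega[.data$omega < 0]
        br <- c(if (length(pos)) mean(pos),
                if (length(neg)) -mean(neg))
        if (length(br)) mean(br) else 0
      },
      n_traj = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$chi)
}
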