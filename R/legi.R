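#' LEGI reaction rates
#'
#' First-order rate constants of the local-excitation global-inhibition
#' network, in units of the inverse polarity relaxation time. The signal
#' produces a cell-local activator A (rates `kA`, `k_mA` for production and
#' decay) and an inhibitor I (`kI`, `k_mI`) that is exchanged between
#' contacting cells at rate `kD` (e.g. through gap junctions). A and I
#' respectively up- and down-regulate the response R (`kR`, `k_mR`).
#'
#' Defaults: inhibitor production/decay at the polarity relaxation rate
#' (`kI = k_mI = 1`) and `kD = 4`, so the communication quality parameter
#' `alpha = k_mI / kD = 0.25` matches gap-junction transfer times of a few
#' minutes. Excitation is taken five-fold faster than inhibition
#' (`kA = k_mA = 5`): only the ratio `kA/k_mA` matters at steady state, but
#' a faster local branch is what produces the transient overshoot of the
#' response after a signal step. The readout is fast and weakly produced
#' (`kR = 0.05`, `k_mR = 50`, so `kR/k_mR = 1e-3`), keeping the exact
#' steady state of R within 0.1% of the ratio form `R0 * (A/I)`.
#'
#' @param kA,k_mA Activator production and decay rates.
#' @param kI,k_mI Inhibitor production and decay rates.
#' @param kR,k_mR Response production and decay rates.
#' @param kD Intercellular inhibitor transfer rate per contact.
#' @return An object of class `legi_rates`.
#' @examples
#' r <- legi_rates()
#' legi_alpha(r) # 0.25
#' @export
legi_rates <- function(kA = 5, k_mA = 5, kI = 1, k_mI = 1,
                       kR = 0.05, k_mR = 50, kD = 4) {
  vals <- c(kA = kA, k_mA = k_mA, kI = kI, k_mI = k_mI,
            kR = kR, k_mR = k_mR, kD = kD)
  if (any(vals < 0)) rlang::abort("legi_rates: rates must be non-negative")
  if (k_mA <= 0 || k_mR <= 0)
    rlang::abort("legi_rates: decay rates k_mA and k_mR must be positive")
  structure(as.list(vals), class = "legi_rates")
}

#' @export
print.legi_rates <- function(x, ...) {
  cat("<legi_rates> kA=", x$kA, " k_mA=", x$k_mA, " kI=", x$kI,
      " k_mI=", x$k_mI, " kR=", x$kR, " k_mR=", x$k_mR, " kD=", x$kD,
      " (alpha=", legi_alpha(x), ")\n", sep = "")
  invisible(x)
}

#' @describeIn legi_rates Communication quality `alpha = k_mI / kD`; small
#'   values mean near-ideal cluster-wide inhibitor equilibration.
#' @param rates A `legi_rates` object.
#' @export
legi_alpha <- function(rates) {
  stopifnot(inherits(rates, "legi_rates"))
  if (rates$kD <= 0) return(Inf)
  rates$k_mI / rates$kD
}

#' Steady-state response scale R0
#'
#' The response of the LEGI network in a spatially uniform signal, which is
#' independent of the signal level (perfect adaptation). With
#' `rho = (kR/k_mR)(kA/k_mA)(k_mI/kI)`, the exact uniform steady state is
#' `R0 = rho / (1 + rho)`; the ratio approximation `R0 = rho` holds when
#' response decay is much faster than production (`k_mR >> kR`).
#'
#' @param rates A [legi_rates()] object.
#' @param exact If `TRUE` (default) return the exact uniform steady state;
#'   otherwise the ratio approximation `rho`.
#' @return The scalar response scale.
#' @export
legi_r0 <- function(rates, exact = TRUE) {
  stopifnot(inherits(rates, "legi_rates"))
  if (rates$kI <= 0)
    rlang::abort("legi_r0: kI must be positive to define R0")
  rho <- (rates$kR / rates$k_mR) * (rates$kA / rates$k_mA) *
    (rates$k_mI / rates$kI)
  if (exact) rho / (1 + rho) else rho
}

check_legi_state <- function(state, n) {
  stopifnot(is.list(state), all(c("A", "I", "R") %in% names(state)))
  for (nm in c("A", "I", "R")) {
    v <- state[[nm]]
    if (length(v) != n || any(!is.finite(v)) || any(v < 0))
      rlang::abort(paste0("legi state: `", nm,
                          "` must be length-", n, ", finite, non-negative"))
  }
  state
}

#' Time derivatives of the LEGI network on a contact graph
#'
#' Right-hand sides of the activator/inhibitor/response kinetics:
#' `dA_i = kA S_i - k_mA A_i`;
#' `dI_i = kI S_i - k_mI I_i - kD n_i I_i + kD sum_(j~i) I_j`;
#' `dR_i = kR A_i (1 - R_i) - k_mR I_i R_i`.
#' The transfer terms form a graph Laplacian, so they conserve the total
#' inhibitor exactly.
#'
#' @param state List with numeric vectors `A`, `I`, `R` (one entry per
#'   cell, all non-negative).
#' @param S_i Per-cell signal values.
#' @param graph A [contact_graph()] matching the cell count.
#' @param rates A [legi_rates()] object.
#' @return A list with vectors `dA`, `dI`, `dR`.
#' @export
legi_rhs <- function(state, S_i, graph, rates) {
  stopifnot(inherits(graph, "contact_graph"),
            inherits(rates, "legi_rates"),
            length(S_i) == graph$n)
  state <- check_legi_state(state, graph$n)
  nbr_sum <- vapply(graph$adjacency,
                    function(nb) sum(state$I[nb]), numeric(1))
  list(
    dA = rates$kA * S_i - rates$k_mA * state$A,
    dI = rates$kI * S_i - rates$k_mI * state$I -
      rates$kD * graph$n_contacts * state$I + rates$kD * nbr_sum,
    dR = rates$kR * state$A * (1 - state$R) -
      rates$k_mR * state$I * state$R)
}

#' Steady state of the LEGI network
#'
#' The activator decouples per cell, `A_i = (kA/k_mA) S_i`. The inhibitor
#' solves the linear system `(k_mI Id + kD L) I = kI S` where `L` is the
#' contact-graph Laplacian -- symmetric positive definite whenever
#' `k_mI > 0`, and solvable for `k_mI = 0` only on connected graphs up to
#' the conservation constraint. The response takes its exact steady state
#' `R_i = kR A_i / (kR A_i + k_mR I_i)`, which reduces to the ratio form
#' `(kR/k_mR) A_i / I_i` when `k_mR >> kR`.
#'
#' @param S_i Per-cell signal values.
#' @param graph A [contact_graph()].
#' @param rates A [legi_rates()] object.
#' @return A tibble with columns `cell`, `S`, `A`, `I`, `R`.
#' @export
legi_steady_state <- function(S_i, graph, rates) {
  stopifnot(inherits(graph, "contact_graph"),
            inherits(rates, "legi_rates"),
            length(S_i) == graph$n)
  n <- graph$n
  A <- (rates$kA / rates$k_mA) * S_i
  M <- diag(rates$k_mI + rates$kD * graph$n_contacts, n)
  ed <- graph_edges(graph)
  if (nrow(ed)) {
    M[ed] <- M[ed] - rates$kD
    M[ed[, c(2, 1), drop = FALSE]] <- M[ed[, c(2, 1), drop = FALSE]] - rates$kD
  }
  if (rates$k_mI <= 0 && graph_components(graph) > 1L)
    rlang::abort("legi_steady_state: singular system (k_mI = 0 on a disconnected graph)")
  I <- drop(solve(M, rates$kI * S_i))
  R <- rates$kR * A / (rates$kR * A + rates$k_mR * I)
  tibble::tibble(cell = seq_len(n), S = S_i, A = A, I = I, R = R)
}

#' Integrate the full LEGI kinetics on a fixed cluster
#'
#' Solves the three-variable LEGI system in time on a static contact graph
#' with a (possibly time-dependent) signal, using a stiff ODE solver. This
#' is the tool for step-response (adaptation) experiments where the
#' transient matters.
#'
#' @param field A [signal_field()]; `"step_in_time"` fields probe
#'   adaptation.
#' @param positions Fixed cell positions.
#' @param rates A [legi_rates()] object.
#' @param times Output time points (increasing, starting at the initial
#'   time).
#' @param state0 Optional initial state list (`A`, `I`, `R`); defaults to
#'   the steady state for the signal at `times[1]`.
#' @param D0 Contact cutoff for the graph.
#' @return A tibble in long format: `time`, `cell`, `A`, `I`, `R`.
#' @export
legi_integrate <- function(field, positions, rates, times,
                           state0 = NULL, D0 = 1.2) {
  pos <- as_positions(positions)
  graph <- contact_graph(pos, cutoff = D0)
  n <- graph$n
  if (is.null(state0)) {
    s0 <- signal_at(field, pos, t = times[1])
    ss <- legi_steady_state(s0, graph, rates)
    state0 <- list(A = ss$A, I = ss$I, R = ss$R)
  }
  state0 <- check_legi_state(state0, n)
  deriv <- function(t, yv, parms) {
    st <- list(A = yv[seq_len(n)], I = yv[n + seq_len(n)],
               R = yv[2 * n + seq_len(n)])
    S_i <- signal_at(field, pos, t = t)
    d <- legi_rhs_unchecked(st, S_i, graph, rates)
    list(c(d$dA, d$dI, d$dR))
  }
  y0 <- c(state0$A, state0$I, state0$R)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)
  tidyr::pivot_longer(
    tibble::as_tibble(stats::setNames(out, c("time", paste0("A", 1:n),
                                             paste0("I", 1:n),
                                             paste0("R", 1:n)))),
    cols = -"time",
    names_to = c(".value", "cell"),
    names_pattern = "([AIR])(\\d+)") |>
    dplyr::mutate(cell = as.integer(.data$cell))
}

# legi_rhs without state validation, for use inside ODE solvers where
# tiny negative excursions from the integrator are tolerable.
legi_rhs_unchecked <- function(state, S_i, graph, rates) {
  nbr_sum <- vapply(graph$adjacency,
                    function(nb) sum(state$I[nb]), numeric(1))
  list(
    dA = rates$kA * S_i - rates$k_mA * state$A,
    dI = rates$kI * S_i - rates$k_mI * state$I -
      rates$kD * graph$n_contacts * state$I + rates$kD * nbr_sum,
    dR = rates$kR * state$A * (1 - state$R) -
      rates$k_mR * state$I * state$R)
}
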