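# Extract the frames of a trajectory tibble inside a time window as
# matrices (times, X, Y of dim n_frames x N).
traj_frames <- function(traj, window = NULL) {
  stopifnot(all(c("t", "cell", "x", "y") %in% names(traj)))
  tt <- sort(unique(traj$t))
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    tt <- tt[tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9]
    if (length(tt) < 2)
      rlang::abort("window contains fewer than two snapshots")
  }
  sub <- traj[traj$t %in% tt, ]
  n <- length(unique(sub$cell))
  ord <- order(sub$t, sub$cell)
  sub <- sub[ord, ]
  list(times = tt,
       X = matrix(sub$x, nrow = length(tt), ncol = n, byrow = TRUE),
       Y = matrix(sub$y, nrow = length(tt), ncol = n, byrow = TRUE))
}

#' Mean cluster velocity over a time window
#'
#' Centroid displacement across the window divided by the window duration.
#' This equals the time-averaged instantaneous centroid velocity but is
#' insensitive to the snapshot cadence.
#'
#' @param traj A `cg_trajectory` (or any long tibble with `t`, `cell`,
#'   `x`, `y`).
#' @param window Length-2 time window; default the full trajectory.
#' @return A one-row tibble with `vx`, `vy`.
#' @export
cluster_velocity <- function(traj, window = NULL) {
  fr <- traj_frames(traj, window)
  nf <- length(fr$times)
  dt_tot <- fr$times[nf] - fr$times[1]
  tibble::tibble(
    vx = (mean(fr$X[nf, ]) - mean(fr$X[1, ])) / dt_tot,
    vy = (mean(fr$Y[nf, ]) - mean(fr$Y[1, ])) / dt_tot)
}

#' Chemotactic index of an ensemble
#'
#' `CI = <V_x> / <|V|>`: the ensemble-mean drift along the gradient
#' direction divided by the ensemble-mean speed. Equals 1 for motion
#' purely up the gradient and 0 for isotropic motion.
#'
#' @param velocities A tibble/data frame with columns `vx`, `vy` (one row
#'   per trajectory), or a numeric matrix with two columns.
#' @return The scalar chemotactic index, in `[-1, 1]`.
#' @export
chemotactic_index <- function(velocities) {
  if (is.matrix(velocities))
    velocities <- tibble::tibble(vx = velocities[, 1], vy = velocities[, 2])
  stopifnot(all(c("vx", "vy") %in% names(velocities)),
            nrow(velocities) >= 1)
  mean(velocities$vx) / mean(sqrt(velocities$vx^2 + velocities$vy^2))
}

#' Cluster angular velocity over a time window
#'
#' Per snapshot, the angular velocity of each cell about the instantaneous
#' centroid is `omega_i = (r_rel x v_rel)_z / |r_rel|^2` with velocities
#' from central finite differences of consecutive snapshots; cells at the
#' exact centroid are excluded. Averaging over cells and then over time
#' gives the trajectory's signed mean angular velocity; a rigid rotation
#' at rate `w` yields exactly `w` regardless of superposed translation.
#'
#' @inheritParams cluster_velocity
#' @return A one-row tibble with `omega` (signed) and `abs_omega`.
#' @export
angular_speed <- function(traj, window = NULL) {
  fr <- traj_frames(traj, window)
  nf <- length(fr$times)
  if (nf < 3)
    rlang::abort("angular_speed: need at least three snapshots in the window")
  if (ncol(fr$X) < 2)
    rlang::abort("angular_speed: need at least two cells")
  omega_t <- numeric(nf - 2)
  for (k in 2:(nf - 1)) {
    dtk <- fr$times[k + 1] - fr$times[k - 1]
    vx <- (fr$X[k + 1, ] - fr$X[k - 1, ]) / dtk
    vy <- (fr$Y[k + 1, ] - fr$Y[k - 1, ]) / dtk
    rx <- fr$X[k, ] - mean(fr$X[k, ])
    ry <- fr$Y[k, ] - mean(fr$Y[k, ])
    vxr <- vx - mean(vx); vyr <- vy - mean(vy)
    r2 <- rx^2 + ry^2
    keep <- r2 > 1e-18
    omega_t[k - 1] <- mean((rx[keep] * vyr[keep] - ry[keep] * vxr[keep]) /
                             r2[keep])
  }
  om <- mean(omega_t)
  tibble::tibble(omega = om, abs_omega = abs(om))
}

#' Number of cluster fragments
#'
#' Connected components of the contact graph at cutoff `D0`; 1 means the
#' cluster is intact.
#'
#' @param positions N x 2 matrix or data frame with `x`, `y`.
#' @param D0 Contact cutoff in cell diameters.
#' @return Integer component count.
#' @export
fragmentation_count <- function(positions, D0 = 1.2) {
  graph_components(contact_graph(as_positions(positions), cutoff = D0))
}

#' Chirality-drift coupling of an ensemble
#'
#' Pairs each trajectory's mean angular velocity with its drift
#' perpendicular to the gradient, and averages the drift separately over
#' the counter-clockwise (`omega > 0`) and clockwise (`omega < 0`)
#' branches. A nonzero branch-dependent drift is the signature of the
#' rotation breaking the mirror symmetry about the gradient axis.
#'
#' @param ensemble A tibble with columns `omega` and `vy`, e.g. from
#'   [run_ensemble()].
#' @return A list with `pairs` (tibble `omega`, `vy`) and `branch_means`
#'   (tibble `branch`, `mean_vy`, `n`).
#' @export
chirality_drift <- function(ensemble) {
  stopifnot(all(c("omega", "vy") %in% names(ensemble)))
  pairs <- tibble::tibble(omega = ensemble$omega, vy = ensemble$vy)
  bm <- pairs |>
    dplyr::mutate(branch = ifelse(.data$omega > 0, "ccw", "cw")) |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(mean_vy = mean(.data$vy), n = dplyr::n(),
                     .groups = "drop")
  list(pairs = pairs, branch_means = bm)
}

# Mean of |V| for V ~ N2(mu, s^2 I): quadrature over the Rice density.
rice_mean <- function(mu, s) {
  if (s <= 0) return(abs(mu))
  f <- function(r) {
    z <- r * mu / s^2
    (r^2 / s^2) * exp(-(r^2 + mu^2) / (2 * s^2) + z) *
      besselI(z, 0, expon.scaled = TRUE)
  }
  stats::integrate(f, 0, mu + 12 * s, rel.tol = 1e-9)$value
}

#' Rigid-cluster steady-state prediction of velocity and chemotactic index
#'
#' For a perfectly rigid cluster whose signal-processing network sits at
#' its steady state, the orientation-conditioned mean velocity is
#' `<V>_c = (1/N) sum_i beta_i q_i`, with `beta_i` from the configured
#' response mode and `q_i` the CIL bias vectors. This function averages
#' `V_x` over equally spaced cluster orientations and computes the
#' chemotactic index from the orientation mixture of isotropic Gaussians
#' with per-component variance `sigma^2 tau / N` (the rigid-cluster
#' velocity fluctuation), evaluating `E|V|` by quadrature.
#'
#' @param positions Cluster configuration (e.g.
#'   [init_hexagonal_cluster()] with `angle = 0`).
#' @param params A [model_params()].
#' @param field A [signal_field()].
#' @param n_orientations Number of equally spaced orientations (default
#'   64; doubling changes results by well under 0.1%).
#' @return A one-row tibble with `N`, `mean_vx`, `mean_vy`, `ci`,
#'   `mean_speed_cond` (orientation-mean of `|<V>_c|`), carrying the
#'   per-orientation table as attribute `"orientations"`.
#' @export
rigid_steady_prediction <- function(positions, params, field,
                                    n_orientations = 64) {
  pos <- as_positions(positions)
  pos <- sweep(pos, 2, colMeans(pos))
  n <- nrow(pos)
  angles <- 2 * pi * (seq_len(n_orientations) - 1) / n_orientations
  per <- purrr::map(angles, function(a) {
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    p <- pos %*% t(rot)
    graph <- contact_graph(p, cutoff = params$D0)
    s <- signal_at(field, p)
    beta <- switch(params$response_mode,
      minimal = susceptibility_minimal(s, params$beta_bar),
      {
        ss <- legi_steady_state(s, graph, params$legi)
        susceptibility_from_response(
          ss$R, params$legi, params$beta_bar,
          mode = if (params$response_mode == "legi_switch") "switch"
                 else "linear",
          lam = params$lam)
      })
    q <- cil_bias(p, graph)
    tibble::tibble(angle = a,
                   vx = sum(beta * q$qx) / n,
                   vy = sum(beta * q$qy) / n)
  }) |> dplyr::bind_rows()
  s_noise <- params$sigma * sqrt(params$tau / n)
  e_absv <- mean(vapply(sqrt(per$vx^2 + per$vy^2),
                        rice_mean, numeric(1), s = s_noise))
  out <- tibble::tibble(
    N = n,
    mean_vx = mean(per$vx),
    mean_vy = mean(per$vy),
    ci = mean(per$vx) / e_absv,
    mean_speed_cond = mean(sqrt(per$vx^2 + per$vy^2)))
  attr(out, "orientations") <- per
  out
}
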