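#' Co-attractant gradient at each cell
#'
#' Cells secrete a chemical that diffuses and degrades quickly compared with
#' cell movement, so the secreted field is the superposition of screened 2-D
#' point sources. Its gradient at cell i is
#' `grad c(r_i) = -sum over j != i of K1(|r_i - r_j| / ell) r_hat_ij`,
#' where `K1` is the modified Bessel function of the second kind and
#' `r_hat_ij` points from j to i: each neighbour pulls the gradient toward
#' itself. The overall secretion/diffusion prefactor is taken as one; only
#' the direction of the gradient (and comparison with the tiny threshold
#' `g0`) enters the polarity dynamics, so the prefactor is absorbed into the
#' chemotaxis strength `chi`.
#'
#' @param positions N x 2 matrix or data frame with columns `x`, `y`.
#' @param ell Degradation length of the secreted field, in cell diameters
#'   (default 5).
#' @return A tibble with columns `cell`, `gx`, `gy`.
#' @export
coattract_gradient <- function(positions, ell = 5) {
  stopifnot(ell > 0)
  pos <- as_positions(positions)
  n <- nrow(pos)
  gx <- numeric(n); gy <- numeric(n)
  pd <- pair_distances(pos)
  if (length(pd$d)) {
    if (any(pd$d < 1e-12))
      rlang::abort("coattract_gradient: coincident cells (K1 diverges)")
    w <- besselK(pd$d / ell, nu = 1)
    ux <- (pos[pd$i, 1] - pos[pd$j, 1]) / pd$d
    uy <- (pos[pd$i, 2] - pos[pd$j, 2]) / pd$d
    for (k in seq_along(pd$d)) {
      gx[pd$i[k]] <- gx[pd$i[k]] - w[k] * ux[k]
      gy[pd$i[k]] <- gy[pd$i[k]] - w[k] * uy[k]
      gx[pd$j[k]] <- gx[pd$j[k]] + w[k] * ux[k]
      gy[pd$j[k]] <- gy[pd$j[k]] + w[k] * uy[k]
    }
  }
  tibble::tibble(cell = seq_len(n), gx = gx, gy = gy)
}

#' Chemotaxis bias from a co-attractant gradient
#'
#' The polarity-rate contribution of co-attraction: `chi` times the unit
#' vector along the gradient when the gradient magnitude exceeds the
#' threshold `g0`, otherwise zero. The response is a hard step in gradient
#' magnitude -- cells respond equally strongly to weak and strong gradients
#' -- and `g0` mainly guards the division by `|grad c|`.
#'
#' @param grad_c Length-2 vector, N x 2 matrix, or tibble with `gx`, `gy`.
#' @param chi Chemotaxis strength toward the secreted attractant.
#' @param g0 Gradient-magnitude threshold (default `1e-5`).
#' @return A tibble with columns `cell`, `bx`, `by`; the bias magnitude is
#'   exactly `chi` wherever it is nonzero.
#' @export
chemotaxis_bias <- function(grad_c, chi, g0 = 1e-5) {
  stopifnot(chi >= 0, g0 >= 0)
  if (is.data.frame(grad_c)) {
    g <- cbind(grad_c$gx, grad_c$gy)
  } else if (is.null(dim(grad_c))) {
    g <- matrix(grad_c, ncol = 2)
  } else g <- as.matrix(grad_c)
  if (!all(is.finite(g)))
    rlang::abort("chemotaxis_bias: gradient must be finite")
  gn <- sqrt(rowSums(g^2))
  on <- gn > g0
  bx <- ifelse(on, chi * g[, 1] / gn, 0)
  by <- ifelse(on, chi * g[, 2] / gn, 0)
  tibble::tibble(cell = seq_len(nrow(g)), bx = bx, by = by)
}

#' Co-attractant scalar field
#'
#' The secreted field itself, a sum of screened 2-D point sources
#' `K0(|r - r_j| / ell)`, scaled by `ell` so that its analytic gradient is
#' exactly the `K1` kernel sum of [coattract_gradient()] (the chain rule
#' brings down a factor `1/ell`). The overall normalization is
#' conventional — only gradient directions enter the dynamics — and the
#' field is mainly useful for visualization.
#'
#' @param positions Secreting cell positions (N x 2 matrix or data frame).
#' @param query_points Points at which to evaluate the field, same formats.
#' @param ell Degradation length in cell diameters.
#' @return A tibble with columns `x`, `y`, `c` (one row per query point).
#' @export
coattract_field <- function(positions, query_points, ell = 5) {
  stopifnot(ell > 0)
  pos <- as_positions(positions)
  q <- as_positions(query_points)
  cvals <- vapply(seq_len(nrow(q)), function(k) {
    d <- sqrt((q[k, 1] - pos[, 1])^2 + (q[k, 2] - pos[, 2])^2)
    if (any(d < 1e-12))
      rlang::abort("coattract_field: query point coincides with a cell")
    ell * sum(besselK(d / ell, nu = 0))
  }, numeric(1))
  tibble::tibble(x = q[, 1], y = q[, 2], c = cvals)
}

#' Rasterize the co-attractant field on a grid
#'
#' Evaluates [coattract_field()] on a regular grid around the cells, for
#' plotting or export as a plain-text table.
#'
#' @param positions Secreting cell positions.
#' @param ell Degradation length in cell diameters.
#' @param pad Margin around the cell bounding box, in cell diameters.
#' @param n_grid Number of grid points per axis.
#' @return A tibble with columns `x`, `y`, `c`.
#' @export
coattract_field_grid <- function(positions, ell = 5, pad = 5, n_grid = 60) {
  pos <- as_positions(positions)
  xs <- seq(min(pos[, 1]) - pad, max(pos[, 1]) + pad, length.out = n_grid)
  ys <- seq(min(pos[, 2]) - pad, max(pos[, 2]) + pad, length.out = n_grid)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  # nudge grid points that fall exactly on a cell centre
  for (i in seq_len(nrow(pos))) {
    hit <- which(abs(grid[, 1] - pos[i, 1]) < 1e-9 &
                 abs(grid[, 2] - pos[i, 2]) < 1e-9)
    if (length(hit)) grid[hit, 1] <- grid[hit, 1] + 1e-6
  }
  coattract_field(pos, grid, ell = ell)
}
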