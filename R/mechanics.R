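#' Pairwise cell-cell force
#'
#' Signed radial force between two cells at separation `d` (in cell
#' diameters): a repulsive spring `v_r (1 - d)` below the equilibrium
#' separation `d = 1`, an attractive spring `-v_a (d - 1)/(D0 - 1)` between
#' the equilibrium separation and the interaction range `D0`, and zero
#' beyond `D0`. Positive values push the cells apart.
#'
#' @param d Separation(s) between cell centres, in cell diameters. Must be
#'   positive; coincident cells are an error, not a regularized case.
#' @param v_r Repulsion strength (velocity units at full overlap).
#' @param v_a Adhesion strength; `v_a = 0` removes short-range adhesion.
#' @param D0 Interaction range in cell diameters (`> 1`).
#' @return Numeric vector of signed radial force magnitudes, one per `d`.
#' @examples
#' pair_force(0.9, v_r = 100, v_a = 0)   # repulsion, +10
#' pair_force(1.5, v_r = 0, v_a = 100, D0 = 2) # adhesion, -50
#' @export
pair_force <- function(d, v_r = 100, v_a = 0, D0 = 1.2) {
  stopifnot(D0 > 1, v_r >= 0, v_a >= 0)
  if (any(d <= 0))
    rlang::abort("pair_force: separation must be positive (cells coincide)")
  ifelse(d < 1, v_r * (1 - d),
         ifelse(d < D0, -v_a * (d - 1) / (D0 - 1), 0))
}

#' Net intercellular force on every cell
#'
#' Sums the pairwise radial forces of [pair_force()] over all pairs. The
#' force on cell i from cell j acts along the unit vector from j to i, so
#' action and reaction cancel and the total force on the cluster is zero.
#'
#' @param positions N x 2 matrix or data frame with columns `x`, `y`.
#' @inheritParams pair_force
#' @return A tibble with columns `cell`, `fx`, `fy`.
#' @export
net_forces <- function(positions, v_r = 100, v_a = 0, D0 = 1.2) {
  pos <- as_positions(positions)
  n <- nrow(pos)
  fx <- numeric(n); fy <- numeric(n)
  pd <- pair_distances(pos)
  if (length(pd$d)) {
    f <- pair_force(pd$d, v_r = v_r, v_a = v_a, D0 = D0)
    ux <- (pos[pd$i, 1] - pos[pd$j, 1]) / pd$d
    uy <- (pos[pd$i, 2] - pos[pd$j, 2]) / pd$d
    for (k in seq_along(pd$d)) {
      fx[pd$i[k]] <- fx[pd$i[k]] + f[k] * ux[k]
      fy[pd$i[k]] <- fy[pd$i[k]] + f[k] * uy[k]
      fx[pd$j[k]] <- fx[pd$j[k]] - f[k] * ux[k]
      fy[pd$j[k]] <- fy[pd$j[k]] - f[k] * uy[k]
    }
  }
  tibble::tibble(cell = seq_len(n), fx = fx, fy = fy)
}

#' Contact-neighbour graph of a cell configuration
#'
#' Two cells are in contact when their separation is below the cutoff,
#' which is also the interaction range `D0` of the pair force and the range
#' of contact inhibition of locomotion.
#'
#' @param positions N x 2 matrix or data frame with columns `x`, `y`.
#' @param cutoff Contact distance in cell diameters (default `1.2`).
#' @return An object of class `contact_graph`: a list with `adjacency`
#'   (list of neighbour index vectors), `n_contacts` (neighbour counts),
#'   `cutoff` and `n`.
#' @export
contact_graph <- function(positions, cutoff = 1.2) {
  pos <- as_positions(positions)
  n <- nrow(pos)
  adj <- rep(list(integer(0)), n)
  pd <- pair_distances(pos)
  sel <- which(pd$d < cutoff)
  for (k in sel) {
    adj[[pd$i[k]]] <- c(adj[[pd$i[k]]], pd$j[k])
    adj[[pd$j[k]]] <- c(adj[[pd$j[k]]], pd$i[k])
  }
  adj <- lapply(adj, sort)
  structure(list(adjacency = adj,
                 n_contacts = vapply(adj, length, integer(1)),
                 cutoff = cutoff, n = n),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph> ", x$n, " cells, ",
      sum(x$n_contacts) / 2, " edges, cutoff ", x$cutoff, "\n", sep = "")
  invisible(x)
}

# Edge list (i < j) of a contact graph.
graph_edges <- function(graph) {
  i <- rep(seq_len(graph$n), graph$n_contacts)
  j <- unlist(graph$adjacency)
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

# Number of connected components, by breadth-first search.
graph_components <- function(graph) {
  n <- graph$n
  if (n == 0L) return(0L)
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- graph$adjacency[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  ncomp
}

#' Contact-inhibition bias vectors
#'
#' The repolarization direction of contact inhibition of locomotion for each
#' cell: `q_i = sum over contacting j of unit vector from j to i`. Interior
#' cells of symmetric clusters have `q = 0`; edge cells point outward. The
#' vector is deliberately not normalized, so cells with more contacts on one
#' side are biased more strongly.
#'
#' @param positions N x 2 matrix or data frame with columns `x`, `y`.
#' @param graph Optional [contact_graph()] for `positions`; recomputed with
#'   cutoff `D0` when missing.
#' @param D0 Contact range used when `graph` is missing.
#' @return A tibble with columns `cell`, `qx`, `qy`, `n_contacts`.
#' @export
cil_bias <- function(positions, graph = NULL, D0 = 1.2) {
  pos <- as_positions(positions)
  if (is.null(graph)) graph <- contact_graph(pos, cutoff = D0)
  stopifnot(inherits(graph, "contact_graph"), graph$n == nrow(pos))
  n <- nrow(pos)
  qx <- numeric(n); qy <- numeric(n)
  for (i in seq_len(n)) {
    nb <- graph$adjacency[[i]]
    if (!length(nb)) next
    dx <- pos[i, 1] - pos[nb, 1]
    dy <- pos[i, 2] - pos[nb, 2]
    d <- sqrt(dx^2 + dy^2)
    qx[i] <- sum(dx / d)
    qy[i] <- sum(dy / d)
  }
  tibble::tibble(cell = seq_len(n), qx = qx, qy = qy,
                 n_contacts = graph$n_contacts)
}
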