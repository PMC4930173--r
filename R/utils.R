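#' @keywords internal
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort
#' @useDynLib coguide, .registration = TRUE
"_PACKAGE"

# Coerce a positions argument (N x 2 matrix, or data frame with x/y columns)
# to an N x 2 numeric matrix.
as_positions <- function(positions) {
  if (is.data.frame(positions)) {
    if (!all(c("x", "y") %in% names(positions)))
      rlang::abort("positions data frame must have columns `x` and `y`")
    positions <- cbind(positions$x, positions$y)
  }
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    rlang::abort("positions must have two columns (x, y)")
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions)))
    rlang::abort("positions must be finite")
  unname(positions)
}

# All pairwise distances (upper triangle as i<j index pairs).
pair_distances <- function(positions) {
  n <- nrow(positions)
  if (n < 2L)
    return(list(i = integer(0), j = integer(0), d = numeric(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- positions[idx[, 1], 1] - positions[idx[, 2], 1]
  dy <- positions[idx[, 1], 2] - positions[idx[, 2], 2]
  list(i = idx[, 1], j = idx[, 2], d = sqrt(dx^2 + dy^2))
}

#' Convert between simulation and physical units
#'
#' One simulation length unit is a typical cell-cell equilibrium separation
#' (20 micrometres) and one time unit is the polarity persistence time
#' (20 minutes), so one velocity unit is 1 micrometre per minute.
#'
#' @param x Numeric vector in simulation units.
#' @param quantity One of `"length"`, `"time"`, `"velocity"`.
#' @param unit_length Physical length per simulation length unit, in
#'   micrometres (default 20).
#' @param unit_time Physical time per simulation time unit, in minutes
#'   (default 20).
#' @return `x` converted to micrometres, minutes, or micrometres/minute.
#' @examples
#' sim_to_real(sqrt(2), "velocity") # RMS speed of an isolated cell
#' @export
sim_to_real <- function(x, quantity = c("length", "time", "velocity"),
                        unit_length = 20, unit_time = 20) {
  quantity <- match.arg(quantity)
  switch(quantity,
    length = x * unit_length,
    time = x * unit_time,
    velocity = x * unit_length / unit_time)
}

# Derive reproducible per-trajectory seeds (< 2^31) from a master seed.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}
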