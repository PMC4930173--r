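# Shared fixtures, built in code.

# Random jittered cluster that is guaranteed connected at the given cutoff:
# hexagonal packing with small positional noise.
random_connected_cluster <- function(n, jitter = 0.05, cutoff = 1.2) {
  pos <- init_hexagonal_cluster(n, angle = 0)
  repeat {
    cand <- pos + matrix(stats::rnorm(2 * n, sd = jitter), n, 2)
    g <- contact_graph(cand, cutoff = cutoff)
    if (coguide:::graph_components(g) == 1L) return(cand)
  }
}

# Relax the LEGI system to steady state by long-time integration of the
# kinetics (independent oracle for the linear-algebra solver).
legi_relax_oracle <- function(S_i, graph, rates, safety = 50) {
  n <- graph$n
  rate_scale <- min(unlist(rates)[unlist(rates) > 0])
  deriv <- function(t, y, parms) {
    st <- list(A = y[seq_len(n)], I = y[n + seq_len(n)],
               R = y[2 * n + seq_len(n)])
    d <- coguide:::legi_rhs_unchecked(st, S_i, graph, rates)
    list(c(d$dA, d$dI, d$dR))
  }
  y0 <- c(rep(1, n), rep(1, n), rep(0.5, n))
  tf <- safety / rate_scale
  sol <- deSolve::ode(y = y0, times = c(0, tf), func = deriv, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)
  yf <- sol[2, -1]
  list(A = yf[seq_len(n)], I = yf[n + seq_len(n)], R = yf[2 * n + seq_len(n)])
}
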