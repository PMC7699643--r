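# Independent oracle: the Efron partial log-likelihood written out from its
# definition, evaluated by brute force.  Used to check the model-fitting
# code; deliberately slow and literal.

efron_partial_loglik <- function(beta, x, start, stop, event) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(stop[event == 1]))) {
    deaths <- which(stop == t & event == 1)
    riskset <- which(start < t & stop >= t)
    d <- length(deaths)
    s0 <- sum(w[riskset])
    s0d <- sum(w[deaths])
    ll <- ll + sum(eta[deaths])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(s0 - (l / d) * s0d)
    }
  }
  ll
}

# brute-force 1-D maximizer of the written-out likelihood on a grid
grid_max_beta <- function(x, start, stop, event,
                          grid = seq(-4, 4, by = 5e-4)) {
  ll <- vapply(
    grid,
    function(b) efron_partial_loglik(b, x, start, stop, event),
    numeric(1)
  )
  grid[which.max(ll)]
}
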