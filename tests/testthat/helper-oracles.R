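# Dense-grid likelihood oracles: evaluate the summed Rician log-likelihood
# over a parameter grid, independently of the optimizer path; the ML fit
# must never fall below the grid best.

mono_grid_best <- function(m, te, sigma, s0_rng = c(50, 150), t2_rng = c(5, 30),
                           n = 200L) {
  s0g <- seq(s0_rng[1], s0_rng[2], length.out = n)
  t2g <- seq(t2_rng[1], t2_rng[2], length.out = n)
  best <- -Inf
  for (t2 in t2g) {
    a <- outer(exp(-te / t2), s0g)            # echo x s0
    ll <- colSums(matrix(rician_loglik(rep(m, n), as.numeric(a), sigma),
                         nrow = length(te)))
    best <- max(best, max(ll))
  }
  best
}

bi_grid_best <- function(m, te, sigma, n = 10L) {
  s0g <- seq(60, 150, length.out = n)
  fg <- seq(0.02, 0.98, length.out = n)
  t2sg <- exp(seq(log(0.1), log(2.9), length.out = n))
  t2lg <- exp(seq(log(8.5), log(55), length.out = n))
  best <- -Inf
  for (t2s in t2sg) for (t2l in t2lg) {
    e1 <- exp(-te / t2s); e2 <- exp(-te / t2l)
    shape <- outer(e1, fg) + outer(e2, 1 - fg)   # echo x f
    for (s0 in s0g) {
      ll <- colSums(matrix(rician_loglik(rep(m, n), as.numeric(s0 * shape), sigma),
                           nrow = length(te)))
      best <- max(best, max(ll))
    }
  }
  best
}
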