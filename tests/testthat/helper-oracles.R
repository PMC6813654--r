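# Independent oracles used to cross-check the package implementations.
# These deliberately use different computational routes (dense grids,
# brute-force enumeration, hand formulas) than the code they verify.

# Efron log partial likelihood evaluated over a grid of coefficients,
# for a single covariate; vectorized over the grid.
efron_loglik_grid <- function(beta_grid, x, times, events) {
  E <- exp(outer(x, beta_grid))  # n x G
  ll <- numeric(length(beta_grid))
  for (t in sort(unique(times[events == 1]))) {
    D <- which(events == 1 & times == t)
    R <- which(times >= t)
    sR <- colSums(E[R, , drop = FALSE])
    sD <- colSums(E[D, , drop = FALSE])
    d <- length(D)
    ll <- ll + sum(x[D]) * beta_grid
    for (l in seq_len(d) - 1L) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# dense grid-search maximizer of the Efron partial likelihood
grid_cox_coef <- function(x, times, events, lo = -5, hi = 5, step = 1e-4) {
  g <- seq(lo, hi, by = step)
  g[which.max(efron_loglik_grid(g, x, times, events))]
}

# O(n^2) double-loop concordance index (comparable iff t_i != t_j and the
# earlier subject had an event; risk ties count 0.5)
brute_cindex <- function(risk, times, events) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# two-sided Fisher p by full enumeration of the hypergeometric support
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  supp <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(supp, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# hand product-limit estimate S(at)
hand_km_at <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t > at) break
    s <- s * (1 - sum(times == t & events == 1) / sum(times >= t))
  }
  s
}
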