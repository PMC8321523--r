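# Shared test utilities and independent oracles.

# Independent permutation enumerator (Heap's algorithm, iterative) used as
# an oracle against the package's lexicographic recursion.
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  c_ <- rep(0L, n)
  out[1, ] <- a
  row <- 2L
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp
      }
      out[row, ] <- a
      row <- row + 1L
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# Brute-force exact two-sided Spearman p-value via Heap enumeration.
spearman_p_bruteforce <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- heap_permutations(length(x))
  rho_all <- apply(perms, 1, function(pm) stats::cor(rx, as.numeric(pm)))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# A spiked library: all designs neutral except `spike_idx` with the given
# persister and growth multipliers.
spiked_effects <- function(n_designs, spike_idx, pi_mult = 10, w_mult = 1) {
  eff <- data.frame(pi_mult = rep(1, n_designs), w_mult = rep(1, n_designs))
  eff$pi_mult[spike_idx] <- pi_mult
  eff$w_mult[spike_idx] <- w_mult
  eff
}

# Noiseless four-parameter logistic.
sigmoid_curve <- function(t, L, U, S, lam) L + (U - L) / (1 + exp(-S * (t - lam)))
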