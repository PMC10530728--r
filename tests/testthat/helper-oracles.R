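# Independent brute-force oracles used to check the statistical primitives.

# Exact two-sided Wilcoxon rank-sum p-value by enumerating all group
# assignments (tie-free data only).
oracle_wilcoxon_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(n, n1)
  us <- apply(assignments, 2L, function(s) {
    sum(r[s]) - n1 * (n1 + 1) / 2
  })
  min(2 * min(mean(us <= u_obs), mean(us >= u_obs)), 1)
}

# Direct step-up Benjamini-Hochberg: q(k) = min_{l >= k} p(l) m / l.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- vapply(seq_len(m), function(k) {
    min(c(sorted[k:m] * m / (k:m), 1))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Scalar-loop evaluation of the observed-abundance formula for tiny cases:
# p_ij  proportional to  exp(gamma_j + sum_{j' != j} theta_jj' pi_ij'
#                            + beta1_j T_i + beta2_j C_i) * pi0_ij.
oracle_observed <- function(Pi0, Pi, gamma, theta, beta1, beta2, trait,
                            conf) {
  n <- nrow(Pi0)
  J <- ncol(Pi0)
  P <- matrix(0, n, J)
  for (i in seq_len(n)) {
    w <- numeric(J)
    for (j in seq_len(J)) {
      eta <- 0
      for (jp in seq_len(J)) {
        if (jp != j) eta <- eta + theta[j, jp] * Pi[i, jp]
      }
      w[j] <- exp(gamma[j] + eta + beta1[j] * trait[i] +
                    beta2[j] * conf[i]) * Pi0[i, j]
    }
    P[i, ] <- w / sum(w)
  }
  P
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Small simulation configuration used across tests.
tiny_config <- function(...) {
  sim_config(J = 30L, n = 20L, scheme = "M2", ...)
}
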