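# Independent oracles used across the suite.

# Exact posterior marginals for a single-factor, single-policy, T = 2 model
# by brute-force enumeration of the joint state space.
enum_posterior_T2 <- function(D, A, B, o1, o2) {
  ns <- length(D)
  p <- matrix(0, ns, ns)
  for (s1 in seq_len(ns)) {
    for (s2 in seq_len(ns)) {
      p[s1, s2] <- D[s1] * A[o1, s1] * B[s2, s1] * A[o2, s2]
    }
  }
  p <- p / sum(p)
  list(t1 = rowSums(p), t2 = colSums(p))
}

# log multivariate beta via the pairwise-beta telescoping identity,
# independent of the lgamma-sum implementation under test
lbeta_oracle <- function(x) {
  out <- 0
  acc <- x[1]
  for (i in seq_along(x)[-1]) {
    out <- out + lbeta(acc, x[i])
    acc <- acc + x[i]
  }
  out
}

# scalar root of the precision fixed point by bisection
precision_oracle <- function(G, Fv, beta0, lo = 1e-3, hi = 50) {
  gap <- function(beta) {
    g <- 1 / beta
    pi0 <- exp(-g * G - max(-g * G)); pi0 <- pi0 / sum(pi0)
    pip <- exp(-Fv - g * G - max(-Fv - g * G)); pip <- pip / sum(pip)
    beta - (beta0 + sum((pip - pi0) * G))
  }
  uniroot(gap, c(lo, hi), tol = 1e-12)$root
}

# small random single-factor model for property sweeps
random_single_factor <- function(ns = 3, no = 4) {
  A <- matrix(rexp(no * ns), no, ns)
  A <- sweep(A, 2, colSums(A), "/")
  B <- array(rexp(ns * ns), c(ns, ns, 1))
  for (j in seq_len(ns)) B[, j, 1] <- B[, j, 1] / sum(B[, j, 1])
  D <- rexp(ns); D <- D / sum(D)
  generative_model(A = list(array(A, c(no, ns))), B = list(B),
                   C = list(rep(0, no)), D = list(D),
                   policies = array(1L, c(1, 1, 1)), T = 2L)
}
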