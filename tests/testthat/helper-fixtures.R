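# Small fixtures shared across test files. Everything is generated in
# code; seeds are fixed so tests are deterministic.

toy_alignment <- function() {
  alignment(c("ACGTACGTAC",
              "ACGTACGTAC",
              "ACGTACGAAC",
              "ATGTACGAAC"),
            id = sprintf("t%d", 1:4),
            population = c("P1", "P1", "P2", "P2"),
            year = 2000L)
}

two_deme_alignment <- function(theta = 10, M = 1, T_split = 1, n = 8,
                               seed = 3) {
  sc <- scenario("isolation_with_migration", theta = theta, M = M,
                 T_split = T_split, n = c(n, n))
  simulate_sample(sc, seed = seed)$alignment
}

expansion_alignment <- function(tau = 10, theta0 = 1, theta1 = 500,
                                n = 30, seed = 7) {
  sc <- scenario("sudden_expansion", tau = tau, theta0 = theta0,
                 theta1 = theta1, n = n)
  simulate_sample(sc, seed = seed)$alignment
}

# expected-curve histogram with (effectively) no sampling noise
curve_histogram <- function(probs, n = 50) {
  counts <- round(probs * 1e6)
  structure(list(counts = setNames(counts, seq_along(probs) - 1L),
                 n_pairs = sum(counts), n = n),
            class = "phd_mismatch")
}

# independent Chinese-restaurant-process oracle for the Ewens
# distribution of the number of distinct haplotypes
crp_k_distribution <- function(n, theta) {
  p <- 1
  for (m in 2:n) {
    pn <- numeric(m)
    pnew <- theta / (theta + m - 1)
    pn[2:m] <- p * pnew
    pn[1:(m - 1)] <- pn[1:(m - 1)] + p * (1 - pnew)
    p <- pn
  }
  p
}
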