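# Brute-force mean squares: literal double-loop transcription of the
# defining sums, independent of the vectorized implementation.
brute_mean_squares <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  gm <- mean(y)
  ri <- rowMeans(y)
  cj <- colMeans(y)
  mss <- 0
  for (i in 1:n) mss <- mss + (ri[i] - gm)^2
  mss <- k * mss / (n - 1)
  msr <- 0
  for (j in 1:k) msr <- msr + (cj[j] - gm)^2
  msr <- n * msr / (k - 1)
  mse <- 0
  for (i in 1:n) for (j in 1:k) mse <- mse + (y[i, j] - ri[i] - cj[j] + gm)^2
  mse <- mse / ((n - 1) * (k - 1))
  list(mss = unname(mss), msr = unname(msr), mse = unname(mse))
}

random_table <- function(n, k, rho = 0.7, R = 0.5) {
  simulate_dataset(simulation_config(n, k, rho, R))
}

# agreement estimator in matrix form, assembled only from matrix summaries
eq_matrix_rho <- function(data) {
  sm <- matrix_summaries(data)
  n <- sm$n
  k <- sm$k
  (sm$one_S_one - sm$trace_S) /
    (sm$one_S_one / n + (n * k - n - k) * sm$trace_S / n + k * sm$yd_sq)
}
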