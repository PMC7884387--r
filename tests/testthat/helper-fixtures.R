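# shared helpers for the test suite; all fixtures are built in code

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^3) / stats::sd(x)^3
}

# random rigid motion (+ optional scaling) applied to a K x 3 config
apply_rigid <- function(coords, scale = 1) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  scale * coords %*% q +
    matrix(stats::runif(3, -5, 5), nrow(coords), 3, byrow = TRUE)
}

# two-group Gaussian score data with known mean offset along dim 1
two_group_scores <- function(n_per_group, p, offset, sd = 1) {
  x <- matrix(stats::rnorm(2 * n_per_group * p, sd = sd),
              2 * n_per_group, p)
  x[seq_len(n_per_group), 1] <- x[seq_len(n_per_group), 1] + offset
  list(x = x, labels = rep(c("A", "B"), each = n_per_group))
}
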