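# Independent oracles, deliberately written with different primitives than
# the package implementation (naive loops and explicit sum-of-squares
# decompositions rather than cumulative sums / aov).

# brute-force minimiser of the two-segment variance cost
oracle_changepoint <- function(y, min_seg = 3) {
  n <- length(y)
  seg_cost <- function(z) {
    m <- sum(z) / length(z)
    v <- sum((z - m)^2) / length(z)
    length(z) * log(max(v, 1e-12))
  }
  best_k <- NA_integer_
  best_cost <- Inf
  for (k in (min_seg + 1):(n - min_seg + 1)) {
    cost <- seg_cost(y[1:(k - 1)]) + seg_cost(y[k:n])
    if (cost < best_cost) {
      best_cost <- cost
      best_k <- k
    }
  }
  best_k
}

# explicit two-way ANOVA decomposition + ICC(A,1) closed form
oracle_icc_a1 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# pooled-variance and paired t statistics from first principles
oracle_t_pooled <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  c(statistic = tt, df = df, p = 2 * pt(-abs(tt), df))
}

oracle_t_paired <- function(x, y) {
  d <- x - y
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  c(statistic = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1))
}

# two one-sided p values from first principles
oracle_tost <- function(d, bound) {
  n <- length(d)
  se <- sd(d) / sqrt(n)
  p_lo <- 1 - pt((mean(d) + bound) / se, n - 1)
  p_hi <- pt((mean(d) - bound) / se, n - 1)
  max(p_lo, p_hi)
}

# a valid series on the 10-s grid from raw channel vectors
make_series <- function(vo2, vco2 = NULL, ve = NULL, ...) {
  n <- length(vo2)
  if (is.null(vco2)) vco2 <- 0.9 * vo2
  if (is.null(ve)) ve <- 25 * vco2
  cpet_series(time = seq(10, by = 10, length.out = n),
              vo2 = vo2, vco2 = vco2, ve = ve, ...)
}

# random sequences with a planted mean and/or variance break
random_break_sequence <- function() {
  n <- sample(20:200, 1)
  k <- sample(seq(4, n - 3), 1)
  mu2 <- rnorm(1, sample(c(-3, 0, 3), 1), 1)
  sd2 <- sample(c(0.5, 1, 2, 4), 1)
  c(rnorm(k - 1, 0, 1), rnorm(n - k + 1, mu2, sd2))
}
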