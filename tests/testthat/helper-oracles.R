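## Independent closed-form / brute-force oracles used to cross-check the
## package's statistics. These deliberately avoid the code paths they
## verify (t.test, p.adjust, phyper, kde2d).

oracle_f_p <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  p <- if (va >= vb) {
    2 * pf(va / vb, length(a) - 1, length(b) - 1, lower.tail = FALSE)
  } else {
    2 * pf(vb / va, length(b) - 1, length(a) - 1, lower.tail = FALSE)
  }
  min(1, p)
}

oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sa <- sum((a - mean(a))^2) / (na - 1) / na
  sb <- sum((b - mean(b))^2) / (nb - 1) / nb
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Step-up BH adjustment written from the defining formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Upper-tail hypergeometric probability from binomial coefficients.
oracle_hyper_upper <- function(k, K, N, n) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## Exhaustive enumeration of all C(N, n) draws.
oracle_hyper_enum <- function(k, K, N, n) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

## Direct double-loop Gaussian KDE evaluation (density at grid points).
oracle_kde_grid <- function(x, y, gx, gy, bw) {
  z <- matrix(0, length(gx), length(gy))
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      z[i, j] <- mean(dnorm(gx[i] - x, sd = bw) * dnorm(gy[j] - y, sd = bw))
    }
  }
  z
}

angle_deg <- function(axis) atan2(axis$direction[2], axis$direction[1]) * 180 / pi

## Unsigned angle between two axis directions, in [0, 90].
axis_angle_error <- function(a, b) {
  abs(((angle_deg(a) - angle_deg(b)) + 90) %% 180 - 90)
}
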