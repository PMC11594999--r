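# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# --- naive LBP riu2, plain double loop, textbook formulas -------------------

oracle_bilinear <- function(m, x, y) {
  # x, y are 0-based continuous coordinates (x = column, y = row)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, ncol(m) - 1); y1 <- min(y0 + 1, nrow(m) - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- m[y0 + 1, x0 + 1]; v01 <- m[y0 + 1, x1 + 1]
  v10 <- m[y1 + 1, x0 + 1]; v11 <- m[y1 + 1, x1 + 1]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

oracle_lbp_codes <- function(m, P, R) {
  P <- as.integer(P)
  b <- ceiling(R)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_integer_, h - 2 * b, w - 2 * b)
  for (cy in b:(h - 1 - b)) {
    for (cx in b:(w - 1 - b)) {
      gc <- m[cy + 1, cx + 1]
      bits <- integer(P)
      for (i in 0:(P - 1)) {
        ang <- 2 * pi * i / P
        sx <- cx + R * cos(ang)
        sy <- cy - R * sin(ang)
        # snap to grid like any careful implementation must
        if (abs(sx - round(sx)) < 1e-9) sx <- round(sx)
        if (abs(sy - round(sy)) < 1e-9) sy <- round(sy)
        gi <- oracle_bilinear(m, sx, sy)
        bits[i + 1] <- as.integer(gi >= gc)
      }
      u <- abs(bits[P] - bits[1]) +
        sum(abs(bits[-1] - bits[-P]))
      out[cy - b + 1, cx - b + 1] <-
        if (u <= 2) sum(bits) else P + 1L
    }
  }
  out
}

# --- exact Mann-Whitney p by full enumeration of group assignments ----------

oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  # two-sided: patterns at least as extreme (by distance from the mean)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# --- exact Wilcoxon signed-rank p by enumeration of sign patterns -----------

oracle_wsr_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# --- misc helpers -----------------------------------------------------------

rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]  # counter-clockwise

random_roi <- function(n = 16, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n, 100, 400), n, n)
}
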