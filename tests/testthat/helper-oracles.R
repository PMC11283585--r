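# Independent brute-force oracles, kept deliberately naive.

# step-up BH from the definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact two-sided rank-sum p by enumerating all choose(n1+n2, n1) assignments
wilcox_enum_p <- function(xs, ys) {
  pooled <- c(xs, ys)
  n1 <- length(xs)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  ws <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# hand product-limit estimator evaluated at each requested time
km_hand <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv_at <- function(t0) {
    s <- 1
    for (u in ut[ut <= t0]) {
      d <- sum(time == u & event == 1)
      n <- sum(time >= u)
      s <- s * (1 - d / n)
    }
    s
  }
  vapply(at, surv_at, numeric(1))
}

# hand log-rank O-E / variance accumulation (two groups)
logrank_hand_chi2 <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o1 <- 0; exp1 <- 0; v <- 0
  for (u in times) {
    n1 <- sum(t1 >= u); n2 <- sum(t2 >= u); n <- n1 + n2
    d1 <- sum(t1 == u & e1 == 1); d2 <- sum(t2 == u & e2 == 1); d <- d1 + d2
    o1 <- o1 + d1
    exp1 <- exp1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o1 - exp1)^2 / v
}

# linear-interpolation percentile on the sorted vector (quantile type 7)
percentile_hand <- function(x, prob) {
  xs <- sort(x)
  h <- (length(xs) - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
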