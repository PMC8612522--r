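# Independent oracles used across the suite. These deliberately use naive
# algorithms (flood fill, full enumeration, direct formulas) so they stay
# independent of the implementation paths they check.

# count connected foreground components by iterative flood fill (4-connectivity)
flood_fill_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    ncomp <- ncomp + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      if (!mask[p[1], p[2]] || seen[p[1], p[2]]) next
      seen[p[1], p[2]] <- TRUE
      stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                             c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
    }
  }
  ncomp
}

# brute-force two-sided rank-sum p by enumerating all group assignments
enumerate_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  combs <- combn(n, length(x))
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# textbook Welch statistic and Welch-Satterthwaite df
welch_formula <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

# dense brute-force local linear fit with tricube weights at given points
brute_loess_degree1 <- function(x, y, at, span) {
  k <- max(2, ceiling(span * length(x)))
  vapply(at, function(x0) {
    d <- abs(x - x0)
    dk <- sort(d)[k]
    w <- (1 - pmin(1, d / dk)^3)^3
    fit <- lm(y ~ x, weights = w)
    unname(predict(fit, newdata = data.frame(x = x0)))
  }, numeric(1))
}
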