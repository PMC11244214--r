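# Shared fixtures, built in code.

# small feature table with a known linear signal in the first `k_active`
# columns and pure-noise columns after them
make_linear_table <- function(n = 150, p = 5, k_active = 1,
                              betas = c(3, -2, 1.5), noise = 0.05,
                              seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p)
  colnames(x) <- paste0("X", seq_len(p))
  b <- rep(0, p)
  b[seq_len(k_active)] <- betas[seq_len(k_active)]
  tab <- data.frame(target = as.vector(x %*% b) + rnorm(n, 0, noise), x)
  class(tab) <- c("lur_features", "data.frame")
  tab
}

# independent type-7 quantile oracle (manual linear interpolation on the
# sorted sample), used to cross-check every quantile-based operation
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force scan of grid cells within `radius` of (cx, cy)
buffer_cells_oracle <- function(g, cx, cy, radius) {
  nx <- ncol(g$values); ny <- nrow(g$values)
  xs <- g$xmin + (seq_len(nx) - 0.5) * g$res
  ys <- g$ymin + (seq_len(ny) - 0.5) * g$res
  d2 <- outer(ys, xs, function(Y, X) (X - cx)^2 + (Y - cy)^2)
  g$values[d2 <= radius^2]
}

# naive loop implementation of the Saltelli/Jansen estimators, kept
# deliberately independent of the package's vectorised path
indices_oracle <- function(y, D, N) {
  fa <- y[1:N]
  fb <- y[(D + 1) * N + 1:N]
  v <- var(c(fa, fb))
  fos <- tos <- numeric(D)
  for (i in 1:D) {
    s1 <- 0; st <- 0
    for (j in 1:N) {
      fab <- y[i * N + j]
      s1 <- s1 + fb[j] * (fab - fa[j])
      st <- st + (fa[j] - fab)^2
    }
    fos[i] <- (s1 / N) / v
    tos[i] <- (st / N) / (2 * v)
  }
  list(fos = fos, tos = tos)
}

# analytic parameter space over [lo, hi]^d for test functions
unit_space <- function(d, lo = 0, hi = 1) {
  structure(list(names = paste0("x", seq_len(d)),
                 bounds = rbind(lo = rep(lo, d), hi = rep(hi, d)),
                 kind = rep("continuous", d),
                 codes = vector("list", d),
                 dropped = character(0),
                 constants = numeric(0),
                 D = as.integer(d)),
            class = "parameter_space")
}

base_layer_of <- function(cols) {
  sub("_(max|min|mean|cat_max|cat_min)_[0-9]+$", "", cols)
}
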