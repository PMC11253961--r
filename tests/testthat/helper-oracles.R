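# Independent brute-force oracles used to pin expected values.  These
# deliberately use direct loops / first-principles formulas rather than
# the package's implementation paths.

# replicate padding identical in contract to the package's boundary rule
pad_rep <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(rep(1, p), seq_len(nr), rep(nr, p)),
    c(rep(1, p), seq_len(nc), rep(nc, p))]
}

# white top-hat by direct min-then-max filtering over a centred square
# window, on a once-replicate-padded image (the package's boundary
# contract), evaluated with plain loops
brute_tophat <- function(m, se) {
  nr <- nrow(m); nc <- ncol(m)
  p <- se
  pm <- pad_rep(m, p)
  h <- (se - 1) %/% 2
  lo <- -h; hi <- se - 1 - h
  # erosion over a band wide enough to feed the dilation of the crop
  er <- pm
  for (i in seq(p + 1 - h, p + nr + h)) {
    for (j in seq(p + 1 - h, p + nc + h)) {
      er[i, j] <- min(pm[(i + lo):(i + hi), (j + lo):(j + hi)])
    }
  }
  op <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      op[i, j] <- max(er[(p + i + lo):(p + i + hi),
                         (p + j + lo):(p + j + hi)])
    }
  }
  pmax(m - op, 0)
}

# normalized sampled Gaussian kernel as used for smoothing (truncated at
# ceiling(3 sigma))
gauss_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

# exhaustive Otsu: try every distinct value as threshold, compute the
# between-class variance from first principles
brute_otsu <- function(v) {
  v <- as.numeric(v)
  u <- sort(unique(v))
  cand <- u[-length(u)]
  bcv <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  mean(cand[abs(bcv - max(bcv)) < 1e-10 * max(bcv)])
}

# type-7 quantile from the textbook formula
quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# binary erosion with a 3x3 window (all 9 in-window pixels must be TRUE),
# replicate boundary
brute_binary_erode <- function(mask) {
  p <- pad_rep(mask * 1, 1)
  out <- mask
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- all(p[i:(i + 2), j:(j + 2)] > 0.5)
    }
  }
  out
}
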