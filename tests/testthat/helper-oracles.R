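# Independent oracles, deliberately coded from the definitions rather than
# by calling package internals.

# The eight coefficient statistics, straight transcription of the formulas.
oracle_metrics <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  skew <- if (s == 0) 0 else sum(((x - mu) / s)^3) / n
  energy <- x^2
  tot <- sum(energy)
  ent <- if (tot == 0) {
    0
  } else {
    p <- energy / tot
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  c(
    max = max(x), min = min(x), mean = mu, std = s, var = v,
    skewness = skew, shannon_entropy = ent, avg_power = sum(x^2) / n
  )
}

# Pairwise-concordance AUC estimator, O(n^2), ties counted 1/2.
oracle_auc <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Fraction of periodogram power inside [lo, hi] Hz.
oracle_band_power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  pw <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  sum(pw[f >= lo & f <= hi]) / sum(pw)
}

# Chi-squared feature-selection statistic evaluated feature by feature.
oracle_chi2 <- function(x, y) {
  apply(x, 2, function(col) {
    lo <- min(col)
    span <- max(col) - lo
    scaled <- if (span > 0) (col - lo) / span else rep(0, length(col))
    tot <- sum(scaled)
    stat <- 0
    for (cls in unique(y)) {
      obs <- sum(scaled[y == cls])
      exp <- tot * mean(y == cls)
      if (exp > 0) stat <- stat + (obs - exp)^2 / exp
    }
    stat
  })
}

# Brute-force confusion tally.
oracle_confusion <- function(y_true, y_pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}
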