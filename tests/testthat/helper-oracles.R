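# Independent oracles used across the suite.  These deliberately use
# plain loops / closed forms, not the package's code paths.

# direct double-sum short-time energy: E_n = sum_{m=n-N+1}^{n} [x(m) w(n-m)]^2
ste_oracle <- function(x, N, w = rep(1, N)) {
  Tn <- length(x)
  E <- numeric(Tn)
  for (n in seq_len(Tn)) {
    s <- 0
    for (m in max(1L, n - N + 1L):n) {
      s <- s + (x[m] * w[n - m + 1L])^2
    }
    E[n] <- s
  }
  E
}

# exhaustive three-criterion peak finder: enumerate strict local maxima,
# filter by height and topographic prominence, then greedily keep the
# highest (tie -> earlier index) subject to the separation constraint.
peak_oracle <- function(x, min_sep, min_height, min_prom) {
  n <- length(x)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i > 1L && i < n && x[i] > x[i - 1L] && x[i] > x[i + 1L])
      cand <- c(cand, i)
  }
  cand <- cand[x[cand] >= min_height]
  proms <- vapply(cand, function(i) prominence_oracle(x, i), numeric(1))
  cand <- cand[proms >= min_prom]
  if (length(cand) <= 1L) return(cand)
  remaining <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in remaining) {
    if (all(abs(i - kept) >= min_sep) || !length(kept)) kept <- c(kept, i)
  }
  sort(kept)
}

prominence_oracle <- function(x, i) {
  n <- length(x)
  left <- i; right <- i
  while (left > 1L && x[left - 1L] <= x[i]) left <- left - 1L
  while (right < n && x[right + 1L] <= x[i]) right <- right + 1L
  x[i] - max(min(x[left:i]), min(x[i:right]))
}

# closed-form OLS via normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2); ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}

# small random CSI recording (complex Gaussian), S a multiple of 30
random_recording <- function(Tn = 50L, S = 60L, fs = 1000, seed = 1L) {
  set.seed(seed)
  samples <- matrix(complex(real = rnorm(Tn * S), imaginary = rnorm(Tn * S)),
                    Tn, S)
  csi_recording(samples, fs = fs)
}

pop_sd <- function(x) sqrt(mean(x^2) - mean(x)^2)
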