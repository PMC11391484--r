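# Independent brute-force oracles, kept deliberately naive.

# Weighted Gini as the pairwise mean difference of per-capita rates:
#   G = sum_ij w_i w_j |r_i - r_j| / (2 (sum w)^2 rbar),  r_i = v_i / w_i.
# Exact for grouped data with homogeneous groups.
gini_pairwise <- function(values, weights) {
  r <- values / weights
  W <- sum(weights)
  rbar <- sum(values) / W
  num <- 0
  for (i in seq_along(r)) {
    for (j in seq_along(r)) {
      num <- num + weights[i] * weights[j] * abs(r[i] - r[j])
    }
  }
  num / (2 * W^2 * rbar)
}

# Direct entropy sum over weight shares xi and resource shares eta.
theil_direct <- function(values, weights) {
  xi <- weights / sum(weights)
  eta <- values / sum(values)
  sum(xi * log(xi / eta))
}

# Random weighted allocation instance (some mass concentration, no zeros
# unless asked for).
random_instance <- function(n, zero_prob = 0) {
  values <- stats::rgamma(n, shape = 0.8, rate = 1) + 1e-3
  if (zero_prob > 0) {
    z <- stats::runif(n) < zero_prob
    if (all(z)) z[1] <- FALSE
    values[z] <- 0
  }
  list(values = values,
       weights = stats::rgamma(n, shape = 2, rate = 1) + 1e-3)
}
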