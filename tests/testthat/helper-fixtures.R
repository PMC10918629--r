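# shared fixtures and independent reference implementations

# random positive intensity matrix with a random mask; every column is
# guaranteed at least `min_obs` observed cells
rand_im <- function(n = 10, p = 6, miss_frac = 0.2, seed = 1, min_obs = 4L,
                    meanlog = 3, sdlog = 0.6) {
  withr::with_seed(seed, {
    v <- matrix(rlnorm(n * p, meanlog, sdlog), n, p)
    mask <- matrix(runif(n * p) < miss_frac, n, p)
    for (j in seq_len(p)) {
      obs <- which(!mask[, j])
      if (length(obs) < min_obs) {
        mask[sample(which(mask[, j]), min_obs - length(obs)), j] <- FALSE
      }
    }
    intensity_matrix(v, mask = mask)
  })
}

# naive double-loop NRMSE reference (kept independent of the package's
# vectorized implementation)
nrmse_reference <- function(truth, completed, mask) {
  total <- 0
  count <- 0
  for (j in seq_len(ncol(truth))) {
    if (!any(mask[, j])) next
    vj <- var(truth[, j])
    for (i in seq_len(nrow(truth))) {
      if (mask[i, j]) {
        total <- total + (completed[i, j] - truth[i, j])^2 / vj
        count <- count + 1
      }
    }
  }
  sqrt(total / count)
}

# exhaustive KNN reference following the written method definition,
# on the raw scale (log_transform = FALSE)
knn_reference <- function(x, k) {
  v <- x$values
  mask <- x$mask
  n <- nrow(v)
  out <- v
  for (j in seq_len(ncol(v))) {
    for (i in which(mask[, j])) {
      d <- rep(Inf, n)
      for (b in seq_len(n)) {
        if (b == i) next
        shared <- !mask[i, ] & !mask[b, ]
        if (any(shared)) {
          d[b] <- sum((v[i, shared] - v[b, shared])^2) / sum(shared)
        }
      }
      cand <- which(!mask[, j] & is.finite(d))
      if (length(cand) == 0) {
        out[i, j] <- mean(v[!mask[, j], j])
        next
      }
      cand <- cand[order(d[cand], cand)]
      nb <- cand[seq_len(min(k, length(cand)))]
      out[i, j] <- mean(v[nb, j])
    }
  }
  out
}
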