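# Brute-force single-scale SSIM straight from the definition: loop over all
# window positions, compute Gaussian-weighted means/variances/covariance,
# average the per-window scores.
brute_ssim <- function(a, b, w, sd, c1, c2) {
  k1 <- exp(-((seq_len(w) - (w + 1) / 2)^2) / (2 * sd^2))
  k1 <- k1 / sum(k1)
  W3 <- outer(outer(k1, k1), k1)
  d <- dim(a)
  scores <- c()
  for (i in seq_len(d[1] - w + 1)) for (j in seq_len(d[2] - w + 1))
    for (k in seq_len(d[3] - w + 1)) {
      wa <- a[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)]
      wb <- b[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)]
      mu_a <- sum(W3 * wa); mu_b <- sum(W3 * wb)
      va <- sum(W3 * wa^2) - mu_a^2; vb <- sum(W3 * wb^2) - mu_b^2
      cab <- sum(W3 * wa * wb) - mu_a * mu_b
      scores <- c(scores, (2 * mu_a * mu_b + c1) * (2 * cab + c2) /
                            ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
    }
  mean(scores)
}

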