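# independent oracle: exhaustive path enumeration of the HMM likelihood,
# built from the explicit transition matrix rather than the forward
# recursion
brute_force_loglik <- function(x, chroms, t, phi, sigma, params) {
  states <- 0:params$max_cn
  K <- length(states)
  pi_k <- exp(-params$state_prior_decay * abs(states - 2))
  pi_k <- pi_k / sum(pi_k)
  trans <- matrix(rep(pi_k, each = K) * (1 - params$e), K, K)
  diag(trans) <- diag(trans) + params$e
  mu <- expected_log_ratio(states, t, phi)
  dens <- function(b, k) {
    if (is.finite(params$df))
      stats::dt((x[b] - mu[k]) / sigma, params$df) / sigma
    else stats::dnorm(x[b], mu[k], sigma)
  }
  total <- 0
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    B <- length(idx)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), B)))
    lik <- 0
    for (p in seq_len(nrow(paths))) {
      s <- paths[p, ]
      w <- pi_k[s[1]] * dens(idx[1], s[1])
      if (B > 1) for (b in 2:B)
        w <- w * trans[s[b - 1], s[b]] * dens(idx[b], s[b])
      lik <- lik + w
    }
    total <- total + log(lik)
  }
  total
}

make_profile <- function(x, chroms, masked = rep(FALSE, length(x))) {
  structure(data.frame(chrom = chroms, start = seq_along(x) * 1e6 - 1e6,
                       end = seq_along(x) * 1e6, log2ratio = x,
                       masked = masked, stringsAsFactors = FALSE),
            class = c("log2_profile", "data.frame"))
}

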