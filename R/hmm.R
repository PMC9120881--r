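#' Expected log2 copy ratio of a tumour/normal mixture
#'
#' For a bin with tumour copy number `c`, tumour fraction `t` and tumour
#' ploidy `phi`, the expected log2 ratio against a diploid reference is
#' `log2(((1 - t) * 2 + t * c) / ((1 - t) * 2 + t * phi))`; the denominator
#' normalizes to the sample's average copy content so that `c = phi` maps
#' to 0.
#'
#' @param c Integer copy number(s), `>= 0`.
#' @param t Tumour fraction in `[0, 1)`.
#' @param phi Tumour ploidy (`> 0`).
#' @return Numeric vector of expected log2 ratios.
#' @examples
#' expected_log_ratio(3, 0.5, 2)  # log2(2.5 / 2) = 0.3219
#' @export
expected_log_ratio <- function(c, t, phi = 2) {
  if (any(c < 0)) stop("`c` must be >= 0")
  if (t < 0 || t >= 1) stop("`t` must lie in [0, 1)")
  if (phi <= 0) stop("`phi` must be positive")
  denom <- (1 - t) * 2 + t * phi
  if (denom <= 0) stop("non-positive mixture denominator")  # unreachable for valid inputs
  log2(((1 - t) * 2 + t * c) / denom)
}

#' HMM hyper-parameters for tumour-fraction estimation
#'
#' @param max_cn Largest modelled copy number; states are `0:max_cn`.
#' @param ploidy Candidate tumour ploidies tried at fit time.
#' @param n_init Normal-fraction initializations of the EM grid; each is
#'   combined with each ploidy candidate.
#' @param e Self-transition probability shared by all states; off-diagonal
#'   transition mass is uniform. Controls segment persistence: larger values
#'   suppress short spurious segments at the cost of sensitivity to subtle
#'   arm-level shifts.
#' @param df Degrees of freedom of the Student-t emission distribution
#'   (default 4, matching the heavy-tailed log2 ratios of low-count bins;
#'   `Inf` gives Gaussian emissions).
#' @param state_prior_decay Decay rate `lambda` of the copy-number state
#'   prior `pi_k` proportional to `exp(-lambda * |k - 2|)`. The prior enters
#'   the initial distribution and the off-diagonal transition mass; it breaks
#'   the exact likelihood degeneracy between e.g. a single-copy gain at
#'   tumour fraction `t` and a two-copy gain at `t/2` in favour of the
#'   parsimonious (near-diploid) interpretation. `0` gives a uniform prior.
#' @param null_margin Detection margin in log-likelihood units (nats): the
#'   fitted model must beat the tumour-free null (`t = 0`) by more than this
#'   before a non-zero tumour fraction is reported; otherwise the fit
#'   collapses to the null. Guards against the scale-free tail-fitting gains
#'   a flexible mixture extracts from any noisy profile (an AIC-style
#'   parsimony rule).
#' @param tol EM stops when the log-likelihood gain falls below `tol`.
#' @param max_iter Maximum EM iterations per initialization.
#' @param t_max Upper bound of the tumour-fraction search.
#' @param estimate_sigma Re-estimate the emission scale inside EM. The
#'   default `FALSE` fixes it at a robust bin-to-bin difference estimate of
#'   the profile noise (`mad(diff(x)) / sqrt(2)`), which is insensitive to
#'   the segment structure and prevents the scale from absorbing genuine
#'   copy-number signal.
#' @param sigma_min Lower bound on the emission standard deviation.
#' @param tie_tol Log-likelihood margin within which competing
#'   (ploidy, initialization) fits are treated as tied; ties resolve toward
#'   lower ploidy, then higher normal fraction (the more conservative tumour
#'   call).
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(max_cn = 5L, ploidy = c(2, 3),
                       n_init = c(0.5, 0.75, 0.9, 0.95, 0.99),
                       e = 0.995, df = 4, state_prior_decay = 3,
                       null_margin = 2.5, tol = 1e-3, max_iter = 50L,
                       t_max = 0.95, estimate_sigma = FALSE,
                       sigma_min = 0.02, tie_tol = 0.05) {
  stopifnot(max_cn >= 2, all(ploidy > 0), all(n_init > 0 & n_init < 1),
            e > 0, e < 1, df > 0, state_prior_decay >= 0, null_margin >= 0,
            tol > 0, max_iter >= 1, sigma_min > 0)
  structure(list(max_cn = as.integer(max_cn), ploidy = ploidy,
                 n_init = n_init, e = e, df = df,
                 state_prior_decay = state_prior_decay,
                 null_margin = null_margin, tol = tol,
                 max_iter = as.integer(max_iter), t_max = t_max,
                 estimate_sigma = estimate_sigma,
                 sigma_min = sigma_min, tie_tol = tie_tol),
            class = "hmm_params")
}

#' Constrained parameters for the low tumour-fraction re-fit
#'
#' The second estimation pass, applied to samples whose first-pass tumour
#' fraction falls below 5%: normal-fraction initializations 0.95, 0.99,
#' 0.995, 0.999, initial ploidy fixed at 2, copy-number states capped at 3,
#' and no subclonal modelling, restricting the fit to the regime where only
#' clonal single-copy events at low mixture fractions are identifiable.
#'
#' @param ... Overrides passed on to [hmm_params()].
#' @return List of class `hmm_params`.
#' @export
hmm_params_low_tfx <- function(...) {
  defaults <- list(max_cn = 3L, ploidy = 2,
                   n_init = c(0.95, 0.99, 0.995, 0.999))
  args <- utils::modifyList(defaults, list(...))
  do.call(hmm_params, args)
}

# copy-number state prior, concentrated at diploid
.state_prior <- function(params) {
  p <- exp(-params$state_prior_decay * abs(0:params$max_cn - 2))
  p / sum(p)
}

# MAD-consistent emission scale for the configured df, from bin-to-bin
# differences (insensitive to segment-level structure)
.diff_sigma <- function(x, params) {
  s <- stats::mad(diff(x)) / sqrt(2)
  if (is.finite(params$df))
    s <- s * stats::qnorm(0.75) / stats::qt(0.75, params$df)
  max(s, params$sigma_min)
}

# usable observation vector and chain-start flags of a profile
.profile_obs <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("chrom", "log2ratio") %in% names(profile)))
  usable <- !profile$masked & is.finite(profile$log2ratio)
  if (!any(usable)) stop("profile has no usable bins")
  chrom <- profile$chrom[usable]
  starts <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  list(x = profile$log2ratio[usable], starts = starts, usable = usable)
}

.log_emissions <- function(x, states, t, phi, sigma, df = Inf) {
  mu <- expected_log_ratio(states, t, phi)
  out <- if (is.finite(df))
    vapply(mu, function(m) stats::dt((x - m) / sigma, df, log = TRUE) -
             log(sigma), numeric(length(x)))
  else
    vapply(mu, function(m) stats::dnorm(x, m, sigma, log = TRUE),
           numeric(length(x)))
  matrix(out, nrow = length(x))
}

#' Forward-algorithm log-likelihood of a log2-ratio profile
#'
#' Exact HMM log-likelihood under Gaussian emissions centred at
#' [expected_log_ratio()], with chromosomes treated as independent chains and
#' masked bins skipped without breaking chain adjacency.
#'
#' @param profile A `log2_profile` (or data.frame with `chrom`, `log2ratio`,
#'   `masked`).
#' @param t Tumour fraction.
#' @param phi Tumour ploidy.
#' @param sigma Emission standard deviation.
#' @param params An [hmm_params()] supplying states and transition structure.
#' @return The log-likelihood (scalar).
#' @export
forward_loglik <- function(profile, t, phi = 2, sigma = 0.1,
                           params = hmm_params()) {
  obs <- .profile_obs(profile)
  states <- 0:params$max_cn
  logE <- .log_emissions(obs$x, states, t, phi, sigma, params$df)
  .fb_cpp(logE, obs$starts, params$e, .state_prior(params))$loglik
}

# single EM run from one (ploidy, normal-fraction) initialization.
# The M-step exploits that Q(t) depends on the data only through the
# per-state posterior moments S_k, M_k, so the 1-D search over t is O(K).
.em_single <- function(x, starts, params, phi, n0) {
  K <- params$max_cn + 1L
  states <- 0:params$max_cn
  init <- .state_prior(params)
  t <- 1 - n0
  sigma <- if (params$estimate_sigma)
    max(stats::mad(x), params$sigma_min)
  else .diff_sigma(x, params)
  B <- length(x)
  nu <- params$df
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  gamma <- NULL
  for (iter in seq_len(params$max_iter)) {
    mu <- expected_log_ratio(states, t, phi)
    logE <- .log_emissions(x, states, t, phi, sigma, nu)
    fb <- .fb_cpp(logE, starts, params$e, init)
    gamma <- fb$gamma
    ll <- fb$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < params$tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    ## Student-t emissions: latent scale weights of the usual t-EM; with
    ## df = Inf the weights are 1 and this is exact Gaussian EM.
    resid2 <- (x - matrix(mu, B, length(states), byrow = TRUE))^2
    U <- if (is.finite(nu)) (nu + 1) / (nu + resid2 / sigma^2) else
      matrix(1, B, length(states))
    W <- gamma * U
    S <- colSums(W)
    M <- colSums(W * x)
    SSxW <- sum(W * x^2)
    score <- function(tt) {
      mu <- expected_log_ratio(states, tt, phi)
      sum(2 * mu * M - mu^2 * S)
    }
    cand <- stats::optimize(score, c(0, params$t_max), maximum = TRUE,
                            tol = 1e-5)$maximum
    ts <- c(cand, t, 0)
    t <- ts[which.max(vapply(ts, score, 0))]
    if (params$estimate_sigma) {
      mu <- expected_log_ratio(states, t, phi)
      sigma <- max(sqrt(max(SSxW - sum(2 * mu * M) + sum(mu^2 * S), 0) / B),
                   params$sigma_min)
    }
  }
  list(t = t, phi = phi, sigma = sigma, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, converged = converged,
       n_iter = length(ll_trace), n_init = n0)
}

#' Fit the copy-number HMM by expectation-maximization
#'
#' Runs EM from every (ploidy, normal-fraction) initialization of the grid in
#' `params`. Each E-step computes posteriors by forward-backward; each M-step
#' re-estimates the tumour fraction by bounded 1-D maximization of the
#' expected complete-data log-likelihood (state means are tied through
#' [expected_log_ratio()], so no closed form exists) and the shared emission
#' standard deviation in closed form. The fit with the highest final
#' log-likelihood wins; fits within `tie_tol` of the best are tie-broken
#' toward lower ploidy, then higher normal fraction.
#'
#' @param profile A `log2_profile`.
#' @param params An [hmm_params()].
#' @return An object of class `tfx_fit`; see [estimate_tumor_fraction()].
#' @export
fit_em <- function(profile, params = hmm_params()) {
  obs <- .profile_obs(profile)
  runs <- list()
  for (phi in params$ploidy)
    for (n0 in params$n_init)
      runs[[length(runs) + 1]] <- .em_single(obs$x, obs$starts, params, phi, n0)
  ll <- vapply(runs, `[[`, 0, "loglik")
  near <- which(ll >= max(ll) - params$tie_tol)
  ord <- order(vapply(runs[near], `[[`, 0, "phi"),
               vapply(runs[near], `[[`, 0, "t"))
  best <- runs[[near[ord[1]]]]

  ## tumour-free null: all state means collapse to 0, so the forward
  ## likelihood is the plain iid emission likelihood
  sigma0 <- .diff_sigma(obs$x, params)
  ll0 <- if (is.finite(params$df))
    sum(stats::dt(obs$x / sigma0, params$df, log = TRUE) - log(sigma0))
  else sum(stats::dnorm(obs$x, 0, sigma0, log = TRUE))
  detection_gain <- best$loglik - ll0
  if (detection_gain < params$null_margin)
    best <- list(t = 0, phi = min(params$ploidy), sigma = sigma0,
                 loglik = ll0, loglik_trace = best$loglik_trace,
                 converged = TRUE, n_iter = best$n_iter,
                 n_init = best$n_init)

  states <- 0:params$max_cn
  logE <- .log_emissions(obs$x, states, best$t, best$phi, best$sigma,
                         params$df)
  prior <- .state_prior(params)
  fb <- .fb_cpp(logE, obs$starts, params$e, prior)
  vit <- .viterbi_cpp(logE, obs$starts, params$e, prior)
  fit <- structure(list(
    tfx = best$t, ploidy = best$phi, sigma = best$sigma,
    loglik = fb$loglik, loglik_trace = best$loglik_trace,
    converged = best$converged, n_iter = best$n_iter,
    null_loglik = ll0, detection_gain = detection_gain,
    pass_index = 1L, params = params,
    posterior = fb$gamma, states = states[vit + 1L],
    usable = obs$usable, profile = profile,
    all_inits = data.frame(
      phi = vapply(runs, `[[`, 0, "phi"),
      n_init = vapply(runs, `[[`, 0, "n_init"),
      tfx = vapply(runs, `[[`, 0, "t"),
      loglik = ll)),
    class = "tfx_fit")
  fit$segments <- viterbi_segments(fit)
  fit
}

#' Segment the genome from the fitted MAP state path
#'
#' Merges maximal same-state runs of the Viterbi path into segments, one set
#' per chromosome. Calls are relative to diploid: copy number < 2 is
#' `deletion`, 2 `neutral`, 3 `gain`, > 3 `amplification`.
#'
#' @param fit A `tfx_fit`.
#' @param profile Profile to segment (defaults to the one stored in `fit`).
#' @return Data.frame with `chrom`, `start`, `end`, `n_bins`, `seg_mean`,
#'   `copy`, `call`.
#' @export
viterbi_segments <- function(fit, profile = fit$profile) {
  stopifnot(inherits(fit, "tfx_fit"))
  usable <- fit$usable
  df <- profile[usable, , drop = FALSE]
  df$state <- fit$states
  run_id <- cumsum(c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                       df$state[-1] != df$state[-nrow(df)]))
  segs <- do.call(rbind, lapply(split(seq_len(nrow(df)), run_id), function(i) {
    data.frame(chrom = df$chrom[i[1]], start = df$start[i[1]],
               end = df$end[i[length(i)]], n_bins = length(i),
               seg_mean = mean(df$log2ratio[i]), copy = df$state[i[1]],
               stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  segs$call <- cut(segs$copy, c(-Inf, 1, 2, 3, Inf),
                   labels = c("deletion", "neutral", "gain", "amplification"))
  segs$call <- as.character(segs$call)
  segs
}

#' Estimate tumour fraction with the two-pass procedure
#'
#' Pass 1 fits the HMM with default parameters. When the estimated tumour
#' fraction falls below `low_tfx_threshold` (5%), the sample is re-fitted
#' with the constrained low-TFx parameters ([hmm_params_low_tfx()]) and the
#' second-pass result is returned with `pass_index = 2`; otherwise the
#' first-pass fit is returned unchanged.
#'
#' @param profile A `log2_profile`.
#' @param params Pass-1 parameters.
#' @param low_params Pass-2 parameters.
#' @param low_tfx_threshold Re-fit trigger on the pass-1 tumour fraction.
#' @return A `tfx_fit`: tumour fraction `tfx`, `ploidy`, emission `sigma`,
#'   `loglik`, per-bin `posterior` and Viterbi `states`, `segments`,
#'   `pass_index`, and (when pass 2 ran) the pass-1 fit under `$pass1`.
#' @export
estimate_tumor_fraction <- function(profile, params = hmm_params(),
                                    low_params = hmm_params_low_tfx(),
                                    low_tfx_threshold = 0.05) {
  fit1 <- fit_em(profile, params)
  if (fit1$tfx < low_tfx_threshold) {
    fit2 <- fit_em(profile, low_params)
    fit2$pass_index <- 2L
    fit2$pass1 <- fit1
    return(fit2)
  }
  fit1
}

#' @export
print.tfx_fit <- function(x, ...) {
  cat(sprintf("tfx_fit: tumour fraction %.4f (ploidy %g, pass %d)\n",
              x$tfx, x$ploidy, x$pass_index))
  cat(sprintf("  loglik %.2f | sigma %.3f | %d EM iterations%s\n",
              x$loglik, x$sigma, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  nonneutral <- sum(x$segments$call != "neutral")
  cat(sprintf("  %d segments (%d non-neutral)\n", nrow(x$segments), nonneutral))
  invisible(x)
}

#' @export
summary.tfx_fit <- function(object, ...) {
  seg <- object$segments
  out <- list(tfx = object$tfx, ploidy = object$ploidy,
              sigma = object$sigma, loglik = object$loglik,
              pass_index = object$pass_index, converged = object$converged,
              n_segments = nrow(seg),
              burden = total_altered_mb(seg),
              sample_id = attr(object$profile, "sample_id"))
  class(out) <- "summary.tfx_fit"
  out
}

#' @export
print.summary.tfx_fit <- function(x, ...) {
  cat("Tumour-fraction HMM fit", if (!is.null(x$sample_id))
    paste0("for ", x$sample_id) else "", "\n")
  cat(sprintf("  tumour fraction: %.4f   ploidy: %g   pass: %d\n",
              x$tfx, x$ploidy, x$pass_index))
  cat(sprintf("  emission sd: %.3f   loglik: %.2f   converged: %s\n",
              x$sigma, x$loglik, x$converged))
  cat(sprintf("  segments: %d   amplified: %.0f Mb   deleted: %.0f Mb\n",
              x$n_segments, x$burden$amplified_mb, x$burden$deleted_mb))
  invisible(x)
}

#' @export
coef.tfx_fit <- function(object, ...) {
  c(tumour_fraction = object$tfx, ploidy = object$ploidy,
    sigma = object$sigma)
}

#' @export
fitted.tfx_fit <- function(object, ...) {
  out <- rep(NA_real_, nrow(object$profile))
  out[object$usable] <- expected_log_ratio(object$states, object$tfx,
                                           object$ploidy)
  out
}

#' @export
residuals.tfx_fit <- function(object, ...) {
  object$profile$log2ratio - fitted(object)
}

#' Plot a fitted copy-number profile
#'
#' Genome-wide scatter of the per-bin log2 ratios coloured by Viterbi call,
#' with segment means overdrawn and chromosome boundaries marked.
#'
#' @param x A `tfx_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tfx_fit <- function(x, ...) {
  prof <- x$profile
  idx <- seq_len(nrow(prof))
  cols <- c(deletion = "#1b7837", neutral = "#888888", gain = "#d6604d",
            amplification = "#b2182b")
  call_per_bin <- rep("neutral", nrow(prof))
  call_per_bin[x$usable] <- as.character(
    cut(x$states, c(-Inf, 1, 2, 3, Inf),
        labels = c("deletion", "neutral", "gain", "amplification")))
  graphics::plot(idx, prof$log2ratio, pch = 16, cex = 0.3,
                 col = cols[call_per_bin],
                 xlab = "bin index (genome order)", ylab = "log2 ratio",
                 main = sprintf("TFx = %.3f (pass %d)", x$tfx, x$pass_index),
                 ...)
  bounds <- which(prof$chrom[-1] != prof$chrom[-nrow(prof)])
  graphics::abline(v = bounds + 0.5, col = "#dddddd")
  seg <- x$segments
  for (i in seq_len(nrow(seg))) {
    b <- which(prof$chrom == seg$chrom[i] & prof$start >= seg$start[i] &
                 prof$end <= seg$end[i])
    graphics::segments(min(b), seg$seg_mean[i], max(b), seg$seg_mean[i],
                       col = "black", lwd = 2)
  }
  invisible(x)
}
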