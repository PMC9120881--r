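#' Simulate per-bin GC content and mappability
#'
#' Produces a deterministic, smoothly varying GC track (waves plus small
#' bin-to-bin jitter; wave periods scale with the genome so GC is not
#' confounded with chromosome arms), a mappability track in which most bins
#' are near 1 with a small minority of poorly mappable bins, and a fixed
#' multiplicative per-bin `artifact` shared by every sample sequenced on the
#' same layout -- the recurrent technical structure (mapping artefacts,
#' fragile sites) that a panel of normals exists to remove. The count
#' simulator applies the artifact; the bias corrector never sees it.
#'
#' @param layout A `genome_layout`.
#' @param seed Integer seed for the annotation stream.
#' @param artifact_sd Log-scale standard deviation of the shared per-bin
#'   technical artifact (default 0.05; 0 disables it).
#' @return A data.frame with columns `gc`, `mappability` and `artifact`, one
#'   row per bin.
#' @export
simulate_annotation <- function(layout, seed = 1L, artifact_sd = 0.05) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- nrow(layout$bins)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.substream_seed(seed, "annotation"))
  i <- seq_len(n)
  gc <- 0.44 + 0.07 * sin(2 * pi * i / max(30, round(n / 9))) +
    0.04 * sin(2 * pi * i / max(12, round(n / 54))) +
    stats::rnorm(n, 0, 0.015)
  gc <- pmin(pmax(gc, 0.25), 0.70)
  mapp <- 1 - stats::rbeta(n, 0.3, 18)
  data.frame(gc = gc, mappability = pmin(pmax(mapp, 0.05), 1),
             artifact = exp(stats::rnorm(n, 0, artifact_sd)))
}

# save/restore the global RNG state so simulators are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Default chromosome-arm event menu
#'
#' Arm-level copy-number events typical of hepatocellular carcinoma, with
#' per-patient occurrence probabilities in the range reported for HCC cohorts:
#' gains of 1q, 6p, 8q, 20p and 20q, and losses of 4q, 13q, 8p, 16q and 17p.
#'
#' @return A data.frame with columns `arm`, `type` (`"gain"`/`"loss"`) and
#'   `prob`.
#' @export
default_event_menu <- function() {
  data.frame(
    arm  = c("1q", "6p", "8q", "20p", "20q", "4q", "13q", "8p", "16q", "17p"),
    type = rep(c("gain", "loss"), each = 5),
    prob = c(0.50, 0.35, 0.55, 0.25, 0.30, 0.45, 0.40, 0.40, 0.35, 0.40),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic cfDNA cohort
#'
#' Bundles every knob of the generator: cohort sizes, the arm-event menu, the
#' count-noise model, the sampling timeline and the outcome model linking
#' tumour-fraction (TFx) dynamics to survival and lipiodol deposition. The
#' defaults emulate the monitored HCC study design: 89 non-cancer controls
#' (32 healthy + 57 liver cirrhosis), 64 treated patients with pre/post/
#' follow-up plasma sampling, TFx spanning 0-0.65, and ~45 expected reads per
#' 1-Mb bin with negative-binomial overdispersion 0.02.
#'
#' @param n_controls,n_patients Cohort sizes.
#' @param depth Expected reads per bin before bias (LD-WGS coverage knob).
#' @param dispersion Negative-binomial overdispersion `a` in
#'   `Var = mu + a * mu^2`; `0` gives Poisson counts.
#' @param gc_bias_amplitude Amplitude of the unimodal quadratic GC bias.
#' @param event_menu Arm event menu; see [default_event_menu()].
#' @param tfx_grid Optional vector of baseline TFx values to draw from instead
#'   of the per-group continuous defaults.
#' @param group_probs Probabilities of the decline/stable/increase TFx-change
#'   groups at the first treatment session (defaults 14/64, 43/64, 7/64).
#' @param timeline_design List with `n_sessions`, `session_gap_days`,
#'   `post_day`, `followup_day`.
#' @param outcome_model List of outcome-link parameters: `median_pfs_days`,
#'   `hr_increase` (PFS hazard ratio of the TFx-increase group),
#'   `median_os_days`, `hr_high_tfx` (OS hazard ratio of baseline TFx >= 0.1),
#'   `censor_pfs_days`, `censor_os_days`, `lipiodol_alpha`,
#'   `lipiodol_beta_per_mb`, `lipiodol_noise_sd`.
#' @param seed Master seed (mandatory); all child streams are derived from it
#'   by named substream.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 89L, n_patients = 64L,
                          depth = 45, dispersion = 0.02,
                          gc_bias_amplitude = 0.3,
                          event_menu = default_event_menu(),
                          tfx_grid = NULL,
                          group_probs = c(decline = 14 / 64, stable = 43 / 64,
                                          increase = 7 / 64),
                          timeline_design = list(n_sessions = 1L,
                                                 session_gap_days = 120L,
                                                 post_day = 35L,
                                                 followup_day = 90L),
                          outcome_model = list(median_pfs_days = 163,
                                               hr_increase = 3,
                                               median_os_days = 630,
                                               hr_high_tfx = 2.6,
                                               censor_pfs_days = 600,
                                               censor_os_days = 900,
                                               lipiodol_alpha = 1.2,
                                               lipiodol_beta_per_mb = 0.008,
                                               lipiodol_noise_sd = 0.5),
                          seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory in a cohort config")
  if (any(event_menu$prob < 0 | event_menu$prob > 1))
    stop("event probabilities must be in [0, 1]")
  if (!is.null(tfx_grid) && any(tfx_grid < 0 | tfx_grid >= 1))
    stop("tfx_grid values must be in [0, 1)")
  if (abs(sum(group_probs) - 1) > 1e-8) stop("group_probs must sum to 1")
  if (depth <= 0) stop("`depth` must be positive")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 depth = depth, dispersion = dispersion,
                 gc_bias_amplitude = gc_bias_amplitude,
                 event_menu = event_menu, tfx_grid = tfx_grid,
                 group_probs = group_probs,
                 timeline_design = timeline_design,
                 outcome_model = outcome_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw a latent copy-number truth from an arm event menu
#'
#' Each menu row is an independent Bernoulli draw; a drawn event covers the
#' whole arm (or, when the menu has a `span` column < 1, a random contiguous
#' sub-arm span of that fraction) with copy number 3 for gains and 1 for
#' losses on a diploid background.
#'
#' @param layout A `genome_layout`.
#' @param event_menu Data.frame with `arm`, `type`, `prob` (optional `span`).
#' @param seed Integer seed.
#' @return A data.frame of class `cn_truth` with columns `chrom`, `start`,
#'   `end`, `copy` (only non-diploid segments; empty for a flat genome).
#' @export
simulate_truth <- function(layout, event_menu = default_event_menu(), seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(event_menu) > 0 && any(event_menu$prob < 0 | event_menu$prob > 1))
    stop("event probabilities must be in [0, 1]")
  arms <- arm_table(layout)
  if (nrow(event_menu) > 0 && !all(event_menu$arm %in% arms$arm))
    stop("event menu names arms absent from the layout: ",
         paste(setdiff(event_menu$arm, arms$arm), collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.substream_seed(seed, "truth"))
  segs <- list()
  for (i in seq_len(nrow(event_menu))) {
    if (stats::runif(1) >= event_menu$prob[i]) next
    a <- arms[arms$arm == event_menu$arm[i], ]
    span <- if ("span" %in% names(event_menu)) event_menu$span[i] else 1
    s <- a$start; e <- a$end
    if (span < 1) {
      w <- round((a$end - a$start) * span)
      s <- a$start + floor(stats::runif(1, 0, a$end - a$start - w))
      e <- s + w
    }
    segs[[length(segs) + 1]] <- data.frame(
      chrom = a$chrom, start = s, end = e,
      copy = if (event_menu$type[i] == "gain") 3L else 1L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               copy = integer(), stringsAsFactors = FALSE)
  class(out) <- c("cn_truth", "data.frame")
  out
}

#' Per-bin integer copy number implied by a truth table
#'
#' @param truth A `cn_truth` (or any data.frame with `chrom`,`start`,`end`,`copy`).
#' @param layout A `genome_layout`.
#' @return Integer vector, one copy number per bin (2 outside truth segments).
#' @export
truth_copy_per_bin <- function(truth, layout) {
  bins <- layout$bins
  copy <- rep(2L, nrow(bins))
  for (i in seq_len(nrow(truth))) {
    hit <- bins$chrom == truth$chrom[i] &
      bins$start < truth$end[i] & bins$end > truth$start[i]
    copy[hit] <- truth$copy[i]
  }
  copy
}

# unimodal quadratic GC bias curve, centred at gc = 0.45
.gc_bias_curve <- function(gc, amplitude) {
  pmax(1 - amplitude * ((gc - 0.45) / 0.2)^2, 0.2)
}

#' Simulate binned read counts for one plasma sample
#'
#' Forward model of a tumour/normal cfDNA mixture: the expected count in bin
#' `b` is `depth * m_b * g(gc_b) * ((1 - tfx) * 2 + tfx * c_b) / 2`, where
#' `c_b` is the latent copy number, `g` a unimodal quadratic GC bias and `m`
#' mappability; counts are negative-binomial with `Var = mu + dispersion*mu^2`
#' (Poisson when `dispersion = 0`).
#'
#' @param truth A `cn_truth` table (may be empty for a diploid genome).
#' @param tfx Tumour fraction in `[0, 1)`.
#' @param layout A `genome_layout`.
#' @param annotation Data.frame with `gc` and `mappability` per bin.
#' @param depth Expected reads per bin before bias.
#' @param dispersion Negative-binomial overdispersion (see [cohort_config()]).
#' @param gc_bias_amplitude Amplitude of the GC bias curve.
#' @param seed Integer seed; identical seeds give identical counts.
#' @param sample_id Identifier stored on the result.
#' @return Integer vector of per-bin counts with attributes `sample_id`,
#'   `tfx`, `depth` and `seed`.
#' @export
simulate_sample_counts <- function(truth, tfx, layout, annotation,
                                   depth = 45, dispersion = 0.02,
                                   gc_bias_amplitude = 0.3, seed = 1L,
                                   sample_id = "sample") {
  if (tfx < 0 || tfx >= 1) stop("`tfx` must lie in [0, 1)")
  if (depth <= 0) stop("`depth` must be positive")
  stopifnot(nrow(annotation) == nrow(layout$bins))
  copy <- truth_copy_per_bin(truth, layout)
  artifact <- if ("artifact" %in% names(annotation)) annotation$artifact else 1
  mu <- depth * annotation$mappability * artifact *
    .gc_bias_curve(annotation$gc, gc_bias_amplitude) *
    ((1 - tfx) * 2 + tfx * copy) / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.substream_seed(seed, paste0("counts/", sample_id)))
  counts <- if (dispersion > 0)
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else stats::rpois(length(mu), mu)
  structure(as.integer(counts), sample_id = sample_id, tfx = tfx,
            depth = depth, seed = seed)
}

# draw (pre, post) TFx for one session given a change group label
.draw_tfx_pair <- function(group, pre = NULL, tfx_grid = NULL) {
  if (is.null(pre)) {
    pre <- switch(group,
      decline  = stats::runif(1, 0.12, 0.55),
      stable   = stats::rbeta(1, 1.6, 8) * 0.65,
      increase = stats::runif(1, 0, 0.10))
    if (!is.null(tfx_grid)) {
      ok <- switch(group, decline = tfx_grid >= 0.12,
                   stable = rep(TRUE, length(tfx_grid)),
                   increase = tfx_grid <= 0.10)
      if (any(ok)) pre <- sample(rep(tfx_grid[ok], 2), 1)
    }
  }
  post <- switch(group,
    decline  = pre * stats::runif(1, 0.08, 0.45),
    stable   = pmin(pmax(pre + stats::runif(1, -0.025, 0.025), 0), 0.99),
    increase = pre + stats::runif(1, 0.06, 0.30))
  c(pre = pre, post = min(post, 0.95))
}

#' Simulate a full synthetic cfDNA cohort
#'
#' Generates, from one master seed, a download-free cohort with the structure
#' the downstream analysis assumes: control and serial patient bin counts, the
#' latent copy-number truth and true TFx trajectory of every patient, a
#' clinical table (lesion diameter sums, mRECIST, AFP, lipiodol deposition)
#' and an outcome table (PFS/OS with event flags and covariates). Outcomes are
#' linked to the truth: PFS hazard is proportional to the first-session
#' TFx-change group (`hr_increase`), OS hazard to baseline TFx >= 0.1, and the
#' lipiodol deposition rate decreases with the true amplified-Mb burden.
#'
#' @param config A [cohort_config()].
#' @param layout A `genome_layout` (defaults to the packaged hg19 1-Mb tiling).
#' @param counts Logical; set `FALSE` to skip read-count generation when only
#'   clinical/outcome structure is needed (much faster).
#' @return A list of class `synthetic_cohort` with elements `layout`,
#'   `annotation`, `samples` (sample sheet), `counts` (bins x samples integer
#'   matrix), `truth` (per-patient truth tables), `clinical`, `outcomes` and
#'   `config`.
#' @export
simulate_cohort <- function(config, layout = make_layout(), counts = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$seed
  annotation <- simulate_annotation(layout, seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  td <- config$timeline_design
  om <- config$outcome_model
  npat <- config$n_patients

  ## --- patient truth and TFx trajectories ---------------------------------
  truth <- lapply(seq_len(npat), function(i)
    simulate_truth(layout, config$event_menu,
                   seed = .substream_seed(seed, paste0("patient-truth/", i))))
  amp_mb <- vapply(truth, function(tr)
    sum((tr$end - tr$start)[tr$copy > 2]) / 1e6, 0)
  del_mb <- vapply(truth, function(tr)
    sum((tr$end - tr$start)[tr$copy < 2]) / 1e6, 0)

  set.seed(.substream_seed(seed, "tfx-trajectories"))
  groups <- sample(names(config$group_probs), npat, replace = TRUE,
                   prob = config$group_probs)
  later_probs <- c(decline = 0.2, stable = 0.65, increase = 0.15)
  traj <- vector("list", npat)
  for (i in seq_len(npat)) {
    ns <- td$n_sessions
    g <- character(ns); pre <- numeric(ns); post <- numeric(ns)
    g[1] <- groups[i]
    pp <- .draw_tfx_pair(g[1], tfx_grid = config$tfx_grid)
    pre[1] <- pp["pre"]; post[1] <- pp["post"]
    if (ns > 1) for (s in 2:ns) {
      g[s] <- sample(names(later_probs), 1, prob = later_probs)
      carry <- pmin(pmax(post[s - 1] + stats::runif(1, -0.01, 0.01), 0), 0.9)
      if (g[s] == "decline" && carry < 0.08) carry <- carry + 0.1
      pp <- .draw_tfx_pair(g[s], pre = carry)
      pre[s] <- pp["pre"]; post[s] <- pp["post"]
    }
    traj[[i]] <- data.frame(session = seq_len(ns), group = g,
                            pre_tfx = pre, post_tfx = post)
  }

  ## --- sample sheet --------------------------------------------------------
  rows <- list()
  for (i in seq_len(config$n_controls)) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("CTRL%03d", i), patient_id = NA_character_,
      role = if (i <= 32) "healthy" else "cirrhosis",
      session = NA_integer_, phase = "control", day = NA_integer_,
      true_tfx = 0, stringsAsFactors = FALSE)
  }
  for (i in seq_len(npat)) {
    pid <- sprintf("P%02d", i)
    tr <- traj[[i]]
    for (s in seq_len(nrow(tr))) {
      d0 <- (s - 1) * td$session_gap_days
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s_S%d_pre", pid, s), patient_id = pid,
        role = "patient", session = s, phase = "pre", day = d0,
        true_tfx = tr$pre_tfx[s], stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s_S%d_post", pid, s), patient_id = pid,
        role = "patient", session = s, phase = "post", day = d0 + td$post_day,
        true_tfx = tr$post_tfx[s], stringsAsFactors = FALSE)
    }
    ## long-term follow-up after the final session
    set.seed(.substream_seed(seed, paste0("followup/", i)))
    fu_tfx <- pmin(pmax(tr$post_tfx[nrow(tr)] + stats::runif(1, -0.02, 0.02), 0), 0.95)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("%s_FU", pid), patient_id = pid, role = "patient",
      session = nrow(tr), phase = "follow-up",
      day = (nrow(tr) - 1) * td$session_gap_days + td$followup_day,
      true_tfx = fu_tfx, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  samples$seed <- seed
  rownames(samples) <- NULL

  ## --- read counts ---------------------------------------------------------
  count_mat <- NULL
  if (counts) {
    empty <- simulate_truth(layout, config$event_menu[0, ], seed = seed)
    count_mat <- matrix(0L, nrow(layout$bins), nrow(samples),
                        dimnames = list(NULL, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      tr <- if (samples$role[j] %in% c("healthy", "cirrhosis")) empty else
        truth[[match(samples$patient_id[j], sprintf("P%02d", seq_len(npat)))]]
      count_mat[, j] <- simulate_sample_counts(
        tr, samples$true_tfx[j], layout, annotation,
        depth = config$depth, dispersion = config$dispersion,
        gc_bias_amplitude = config$gc_bias_amplitude,
        seed = seed, sample_id = samples$sample_id[j])
    }
  }

  ## --- clinical table ------------------------------------------------------
  set.seed(.substream_seed(seed, "clinical"))
  pre1 <- vapply(traj, function(t) t$pre_tfx[1], 0)
  post1 <- vapply(traj, function(t) t$post_tfx[1], 0)
  size_cm <- pmax(1, 3 + 14 * pre1 + stats::rnorm(npat, 0, 2))
  baseline_sum <- size_cm
  mult <- vapply(seq_len(npat), function(i) switch(groups[i],
    decline = stats::runif(1, 0.35, 0.78),
    stable = stats::runif(1, 0.75, 1.25),
    increase = stats::runif(1, 1.10, 1.80)), 0)
  all_gone <- groups == "decline" & post1 < 0.01 & stats::runif(npat) < 0.3
  followup_sum <- ifelse(all_gone, 0, baseline_sum * mult)
  afp_pre <- 10^(1.0 + 3.5 * pre1 + stats::rnorm(npat, 0, 0.45))
  afp_post <- 10^(1.0 + 3.5 * post1 + stats::rnorm(npat, 0, 0.45))
  lip_lin <- om$lipiodol_alpha - om$lipiodol_beta_per_mb * amp_mb +
    stats::rnorm(npat, 0, om$lipiodol_noise_sd)
  lipiodol <- pmin(pmax(stats::plogis(lip_lin), 0.01), 0.99)
  pvtt <- stats::rbinom(npat, 1, stats::plogis(-1.5 + 6 * pre1))
  hbv <- stats::rbinom(npat, 1, stats::plogis(-1.0 + 5 * pre1))
  tumour_number <- 1L + stats::rpois(npat, 1 + 3 * pre1)
  bclc <- ifelse(stats::runif(npat) < stats::plogis(-0.5 + 4 * pre1), "C", "B")

  clinical <- data.frame(
    patient_id = sprintf("P%02d", seq_len(npat)),
    n_sessions = td$n_sessions,
    pre_tfx = pre1, post_tfx = post1, change_group = groups,
    baseline_sum_cm = baseline_sum, followup_sum_cm = followup_sum,
    all_lesions_gone = all_gone,
    mrecist = vapply(seq_len(npat), function(i)
      mrecist_category(baseline_sum[i], followup_sum[i], all_gone[i]), ""),
    afp_pre = afp_pre, afp_post = afp_post,
    tumour_size_cm = size_cm, tumour_number = tumour_number,
    pvtt = pvtt, hbv_dna_high = hbv, bclc = bclc,
    lipiodol_rate = lipiodol,
    amplified_mb_true = amp_mb, deleted_mb_true = del_mb,
    seed = seed, stringsAsFactors = FALSE)

  ## --- outcomes ------------------------------------------------------------
  set.seed(.substream_seed(seed, "outcomes"))
  pfs <- .simulate_survival(npat, om$median_pfs_days,
                            om$hr_increase, groups == "increase",
                            om$censor_pfs_days)
  os <- .simulate_survival(npat, om$median_os_days,
                           om$hr_high_tfx, pre1 >= 0.1, om$censor_os_days)
  outcomes <- data.frame(
    patient_id = clinical$patient_id,
    pfs_days = pfs$time, pfs_event = pfs$event,
    os_days = os$time, os_event = os$event,
    change_group = groups, pre_tfx_high = pre1 >= 0.1,
    pvtt = pvtt, hbv_dna_high = hbv, bclc = bclc,
    tumour_size_cm = size_cm, tumour_number = tumour_number,
    afp_abnormal = afp_pre > 20, seed = seed, stringsAsFactors = FALSE)

  structure(list(layout = layout, annotation = annotation, samples = samples,
                 counts = count_mat, truth = truth,
                 tfx_trajectories = traj, clinical = clinical,
                 outcomes = outcomes, config = config),
            class = "synthetic_cohort")
}

# exponential survival with a binary proportional-hazards covariate and
# administrative censoring; median is the baseline-group median in days
.simulate_survival <- function(n, median_days, hr, exposed, censor_days) {
  rate <- log(2) / median_days * ifelse(exposed, hr, 1)
  t <- stats::rexp(n, rate)
  event <- as.integer(t <= censor_days)
  list(time = round(pmin(t, censor_days)) + 1, event = event)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$config$n_controls, "controls,",
      x$config$n_patients, "patients,",
      if (is.null(x$counts)) "no counts" else
        paste(ncol(x$counts), "count profiles"),
      "| seed", x$config$seed, "\n")
  invisible(x)
}
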