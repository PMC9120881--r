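#' Response/outcome thresholds
#'
#' All clinical thresholds of the response layer in one place. Defaults are
#' the study values: 50% relative and 0.03 absolute tumour-fraction change,
#' detectability cut-off 0.016245, prognostic TFx split 0.1, lipiodol
#' deposition split 50%, arm-call coverage 0.5, AFP abnormality 20 ng/mL.
#'
#' @param rel_change,abs_change TFx-change classification thresholds.
#' @param detect_cutoff Detectability cut-off on TFx.
#' @param tfx_prognostic Prognostic split on baseline/post TFx (>= is high).
#' @param lipiodol_cutoff High/low lipiodol deposition split.
#' @param arm_min_fraction Minimum arm coverage for an arm-level call.
#' @param afp_cutoff AFP abnormality threshold in ng/mL.
#' @return A named list.
#' @export
response_thresholds <- function(rel_change = 0.5, abs_change = 0.03,
                                detect_cutoff = 0.016245,
                                tfx_prognostic = 0.1,
                                lipiodol_cutoff = 0.5,
                                arm_min_fraction = 0.5,
                                afp_cutoff = 20) {
  list(rel_change = rel_change, abs_change = abs_change,
       detect_cutoff = detect_cutoff, tfx_prognostic = tfx_prognostic,
       lipiodol_cutoff = lipiodol_cutoff,
       arm_min_fraction = arm_min_fraction, afp_cutoff = afp_cutoff)
}

#' Patient-level response classification and cohort statistics
#'
#' Applies the response layer to a cohort: per patient, the first-session
#' TFx-change group (dual-threshold and absolute-only), detectability of the
#' pre/post samples, the lipiodol group, and (when >= 2 sessions are present)
#' the longitudinal class; then runs the outcome battery -- Kaplan-Meier with
#' log-rank for PFS by TFx-change (increase vs non-increase) and for OS by
#' baseline TFx split, univariate Cox for the TFx-increase group,
#' PD-vs-increase enrichment (Fisher), Pearson correlation of TFx with tumour
#' size, and the amplified-Mb comparison between lipiodol groups (Student's
#' t). No multiple-testing correction is applied.
#'
#' @param tfx_table Data.frame with columns `patient_id`, `session`,
#'   `pre_tfx`, `post_tfx` (one row per session, estimated or true TFx).
#' @param clinical Clinical table (columns as in [simulate_cohort()]'s
#'   `clinical`: `mrecist`, `lipiodol_rate`, `tumour_size_cm`, and an
#'   amplified-Mb column named `amplified_mb`).
#' @param outcomes Outcome table (`pfs_days`, `pfs_event`, `os_days`,
#'   `os_event`).
#' @param thresholds A [response_thresholds()] list.
#' @return List with `patients` (per-patient classification table) and
#'   `stats` (named list of test results).
#' @export
analyze_cohort_response <- function(tfx_table, clinical, outcomes,
                                    thresholds = response_thresholds()) {
  th <- thresholds
  ids <- unique(tfx_table$patient_id)
  rows <- lapply(ids, function(pid) {
    tt <- tfx_table[tfx_table$patient_id == pid, , drop = FALSE]
    tt <- tt[order(tt$session), , drop = FALSE]
    cc <- classify_tfx_change(tt$pre_tfx[1], tt$post_tfx[1],
                              rel = th$rel_change, abs = th$abs_change)
    lc <- if (nrow(tt) >= 2)
      longitudinal_class(tt, rel = th$rel_change, abs = th$abs_change)$class
    else NA_character_
    data.frame(
      patient_id = pid,
      pre_tfx = tt$pre_tfx[1], post_tfx = tt$post_tfx[1],
      change_group = cc$group,
      change_group_abs = classify_tfx_change_abs(tt$pre_tfx[1],
                                                 tt$post_tfx[1],
                                                 abs = th$abs_change),
      pre_detectable = detectable(tt$pre_tfx[1], th$detect_cutoff),
      post_detectable = detectable(tt$post_tfx[1], th$detect_cutoff),
      pre_tfx_high = tt$pre_tfx[1] >= th$tfx_prognostic,
      longitudinal_class = lc,
      stringsAsFactors = FALSE)
  })
  patients <- do.call(rbind, rows)

  cl <- clinical[match(patients$patient_id, clinical$patient_id), ]
  oc <- outcomes[match(patients$patient_id, outcomes$patient_id), ]
  patients$mrecist <- cl$mrecist
  lip <- lapply(cl$lipiodol_rate, function(r)
    lipiodol_group(r, 1, cutoff = th$lipiodol_cutoff))
  patients$lipiodol_group <- vapply(lip, `[[`, "", "group")

  increase <- patients$change_group == "increase"
  stats <- list()
  stats$group_counts <- table(factor(patients$change_group,
                                     c("decline", "stable", "increase")))
  stats$km_pfs_change <- try_stat(km_logrank(
    oc$pfs_days, oc$pfs_event,
    ifelse(increase, "increase", "non-increase")))
  stats$km_os_tfx <- try_stat(km_logrank(
    oc$os_days, oc$os_event,
    ifelse(patients$pre_tfx_high, "high", "low")))
  stats$cox_pfs_increase <- try_stat(cox_univariate(
    oc$pfs_days, oc$pfs_event, as.integer(increase)))
  stats$fisher_pd_increase <- try_stat(association_tests(
    table(factor(patients$mrecist == "PD", c(FALSE, TRUE)),
          factor(increase, c(FALSE, TRUE))), kind = "fisher"))
  stats$pearson_tfx_size <- try_stat(association_tests(
    patients$pre_tfx, cl$tumour_size_cm, kind = "pearson"))
  if ("amplified_mb" %in% names(cl))
    stats$ttest_amp_lipiodol <- try_stat(association_tests(
      cl$amplified_mb, patients$lipiodol_group, kind = "ttest"))
  list(patients = patients, stats = stats)
}

# run a statistic, returning the error message instead of failing the cohort
try_stat <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Run the full analysis pipeline on a cohort directory
#'
#' End-to-end orchestration over a directory in [write_cohort()] layout:
#' (1) GC/mappability-correct all control samples and build the panel of
#' normals; (2) correct, normalize and fit every patient sample with the
#' two-pass HMM, writing per-sample SEG files and a TFx summary table;
#' (3) call arm-level events and the cohort frequency profile;
#' (4) classify treatment response and run the outcome statistics. A manifest
#' with MD5 checksums of every artifact is written last; re-running with the
#' same inputs reproduces identical outputs.
#'
#' @param input_dir Cohort directory ([write_cohort()] layout).
#' @param out_dir Output directory.
#' @param params,low_params HMM parameter sets for the two passes.
#' @param thresholds A [response_thresholds()] list.
#' @param estimate_controls Also estimate TFx for control samples (needed for
#'   the detectability ROC benchmark; roughly doubles runtime).
#' @param overwrite Allow writing into a non-empty output directory.
#' @return The manifest, invisibly: a list with per-stage outputs and file
#'   checksums.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         params = hmm_params(),
                         low_params = hmm_params_low_tfx(),
                         thresholds = response_thresholds(),
                         estimate_controls = FALSE,
                         overwrite = FALSE) {
  t0 <- Sys.time()
  for (f in c("samples.tsv", "annotation.tsv", "clinical.tsv", "outcomes.tsv"))
    if (!file.exists(file.path(input_dir, f)))
      stop("[input] missing ", f, " in ", input_dir)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("[output] directory not empty (use overwrite = TRUE): ", out_dir)
  dir.create(file.path(out_dir, "seg"), recursive = TRUE,
             showWarnings = FALSE)

  layout <- make_layout()
  ann <- utils::read.delim(file.path(input_dir, "annotation.tsv"))
  if (nrow(ann) != nrow(layout$bins))
    stop("[input] annotation does not match the 1-Mb hg19 layout")
  samples <- utils::read.delim(file.path(input_dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  clinical <- utils::read.delim(file.path(input_dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  outcomes <- utils::read.delim(file.path(input_dir, "outcomes.tsv"),
                                stringsAsFactors = FALSE)

  read_counts <- function(sid) {
    path <- file.path(input_dir, "counts", paste0(sid, ".tsv"))
    if (!file.exists(path)) stop("[counts] missing count file for ", sid)
    tryCatch(read_bin_counts(path, layout),
             error = function(e) stop("[counts] sample ", sid, ": ",
                                      conditionMessage(e)))
  }

  ## stage 1: panel of normals
  is_ctrl <- samples$phase == "control"
  if (sum(is_ctrl) < 2) stop("[pon] need >= 2 control samples")
  message("[pon] correcting ", sum(is_ctrl), " controls")
  corrected_ctrl <- lapply(samples$sample_id[is_ctrl], function(sid)
    tryCatch(correct_bias(read_counts(sid), ann),
             error = function(e) stop("[pon] sample ", sid, ": ",
                                      conditionMessage(e))))
  pon <- build_pon(corrected_ctrl, ann)
  write_pon(pon, layout, file.path(out_dir, "pon.tsv"))

  ## stage 2: per-sample two-pass TFx estimation
  todo <- if (estimate_controls) seq_len(nrow(samples)) else which(!is_ctrl)
  message("[tfx] estimating ", length(todo), " samples")
  summaries <- vector("list", length(todo))
  arm_calls <- list()
  for (k in seq_along(todo)) {
    j <- todo[k]
    sid <- samples$sample_id[j]
    prof <- tryCatch(
      normalize_sample(correct_bias(read_counts(sid), ann), pon, layout,
                       sample_id = sid),
      error = function(e) stop("[normalize] sample ", sid, ": ",
                               conditionMessage(e)))
    fit <- estimate_tumor_fraction(prof, params, low_params)
    write_seg(fit$segments, sid, file.path(out_dir, "seg",
                                           paste0(sid, ".seg")))
    burden <- total_altered_mb(fit$segments)
    summaries[[k]] <- data.frame(
      sample_id = sid, patient_id = samples$patient_id[j],
      session = samples$session[j], phase = samples$phase[j],
      tfx = fit$tfx, ploidy = fit$ploidy, loglik = fit$loglik,
      pass = fit$pass_index, converged = fit$converged,
      amplified_mb = burden$amplified_mb, deleted_mb = burden$deleted_mb,
      stringsAsFactors = FALSE)
    if (samples$phase[j] == "pre" && samples$session[j] == 1)
      arm_calls[[samples$patient_id[j]]] <-
        call_arm_events(fit$segments, layout, thresholds$arm_min_fraction)
  }
  summary_tab <- do.call(rbind, summaries)
  utils::write.table(summary_tab, file.path(out_dir, "tfx_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: cohort CNV summaries (baseline samples)
  freq <- if (length(arm_calls))
    cohort_frequency_profile(arm_calls) else NULL
  if (!is.null(freq))
    utils::write.table(freq, file.path(out_dir, "arm_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 4: response classification and statistics
  pat <- summary_tab[summary_tab$phase %in% c("pre", "post"), ]
  tfx_table <- do.call(rbind, lapply(split(pat, list(pat$patient_id,
                                                     pat$session),
                                           drop = TRUE), function(d) {
    data.frame(patient_id = d$patient_id[1], session = d$session[1],
               pre_tfx = d$tfx[d$phase == "pre"][1],
               post_tfx = d$tfx[d$phase == "post"][1],
               stringsAsFactors = FALSE)
  }))
  base_amp <- pat[pat$phase == "pre" & pat$session == 1, ]
  clinical$amplified_mb <-
    base_amp$amplified_mb[match(clinical$patient_id, base_amp$patient_id)]
  res <- analyze_cohort_response(tfx_table, clinical, outcomes, thresholds)
  utils::write.table(res$patients, file.path(out_dir, "patient_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats_clean <- lapply(res$stats, function(s) {
    if (is.table(s)) return(as.list(s))
    s$survdiff <- NULL; s$fit <- NULL; s$roc <- NULL
    s
  })
  jsonlite::write_json(stats_clean, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  ## manifest
  arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  arts <- setdiff(arts, file.path(out_dir, "manifest.json"))
  manifest <- list(
    created = format(t0), elapsed_s = as.numeric(Sys.time() - t0, "secs"),
    input_dir = normalizePath(input_dir),
    n_controls = sum(is_ctrl), n_samples_estimated = length(todo),
    params = params[setdiff(names(params), "")],
    thresholds = thresholds,
    files = data.frame(path = sub(paste0("^", out_dir, "/?"), "", arts),
                       md5 = unname(tools::md5sum(arts)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
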