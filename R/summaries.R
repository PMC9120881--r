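#' Chromosome-arm level event calls from a segment set
#'
#' For each arm, computes the fraction of the arm covered by gain/amplification
#' segments and by deletion segments; the arm is called `gain` when gain
#' coverage reaches `min_fraction` of the arm length and exceeds the loss
#' coverage (symmetrically for `loss`), else `neutral`.
#'
#' @param segments Segment data.frame with `chrom`, `start`, `end`, `call`
#'   (from [viterbi_segments()] or [truth_segments()]).
#' @param layout A `genome_layout`.
#' @param min_fraction Minimum covered fraction for an arm call (default 0.5).
#' @return Data.frame with `arm`, `gain_fraction`, `loss_fraction`, `call`.
#' @export
call_arm_events <- function(segments, layout, min_fraction = 0.5) {
  stopifnot(inherits(layout, "genome_layout"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must lie in (0, 1]")
  if (nrow(segments) > 0 && !all(segments$chrom %in% layout$genome$chrom))
    stop("segment on a chromosome absent from the layout")
  arms <- arm_table(layout)
  gain_cov <- loss_cov <- numeric(nrow(arms))
  for (i in seq_len(nrow(segments))) {
    if (segments$call[i] == "neutral") next
    on_chr <- arms$chrom == segments$chrom[i]
    ov <- pmin(arms$end[on_chr], segments$end[i]) -
      pmax(arms$start[on_chr], segments$start[i])
    ov <- pmax(ov, 0)
    if (segments$call[i] %in% c("gain", "amplification"))
      gain_cov[on_chr] <- gain_cov[on_chr] + ov
    else loss_cov[on_chr] <- loss_cov[on_chr] + ov
  }
  gain_frac <- gain_cov / arms$length
  loss_frac <- loss_cov / arms$length
  call <- ifelse(gain_frac >= min_fraction & gain_frac > loss_frac, "gain",
          ifelse(loss_frac >= min_fraction & loss_frac > gain_frac, "loss",
                 "neutral"))
  data.frame(arm = arms$arm, gain_fraction = gain_frac,
             loss_fraction = loss_frac, call = call,
             stringsAsFactors = FALSE)
}

#' Cohort-level arm event frequencies
#'
#' @param arm_calls List of per-sample arm-call tables from
#'   [call_arm_events()].
#' @return Data.frame with `arm`, `event` (`gain`/`loss`), `n`, `frequency`,
#'   sorted by descending frequency with ties broken by arm name then event.
#' @export
cohort_frequency_profile <- function(arm_calls) {
  if (length(arm_calls) == 0) stop("no samples supplied")
  arms <- arm_calls[[1]]$arm
  n_samples <- length(arm_calls)
  counts <- sapply(arm_calls, function(ac) ac$call[match(arms, ac$arm)])
  counts <- matrix(counts, nrow = length(arms))
  out <- rbind(
    data.frame(arm = arms, event = "gain",
               n = rowSums(counts == "gain"), stringsAsFactors = FALSE),
    data.frame(arm = arms, event = "loss",
               n = rowSums(counts == "loss"), stringsAsFactors = FALSE))
  out$frequency <- out$n / n_samples
  out <- out[order(-out$frequency, out$arm, out$event), ]
  rownames(out) <- NULL
  out
}

#' Total altered genome length of a segment set
#'
#' Sums segment lengths by call class: `amplified_mb` covers `gain` and
#' `amplification` segments, `deleted_mb` covers deletions; both in Mb.
#'
#' @param segments Segment data.frame with `start`, `end`, `call`.
#' @return List with `amplified_mb` and `deleted_mb`.
#' @export
total_altered_mb <- function(segments) {
  len <- segments$end - segments$start
  list(amplified_mb = sum(len[segments$call %in% c("gain", "amplification")]) / 1e6,
       deleted_mb = sum(len[segments$call == "deletion"]) / 1e6)
}

#' Is a locus amplified in a segment set?
#'
#' Any-overlap rule: returns `TRUE` when at least one gain/amplification
#' segment overlaps the query interval by one or more base pairs.
#'
#' @param segments Segment data.frame with `chrom`, `start`, `end`, `call`.
#' @param chrom,start,end Query interval, 0-based half-open.
#' @param layout Optional `genome_layout` used to validate the chromosome.
#' @return List with `amplified` (logical) and `overlapping` (the overlapping
#'   gain/amplification segments, possibly empty).
#' @export
locus_amplified <- function(segments, chrom, start, end, layout = NULL) {
  if (!is.null(layout) && !chrom %in% layout$genome$chrom)
    stop("unknown chromosome: ", chrom)
  hit <- segments$chrom == chrom &
    segments$call %in% c("gain", "amplification") &
    segments$start < end & segments$end > start
  list(amplified = any(hit), overlapping = segments[hit, , drop = FALSE])
}

#' Segment view of a copy-number truth table
#'
#' Expresses a generator truth (`cn_truth`) in the same segment format as
#' [viterbi_segments()] so the summarization operations apply to ground truth
#' as well as to fitted profiles.
#'
#' @param truth A `cn_truth` table.
#' @return Data.frame with `chrom`, `start`, `end`, `copy`, `call`.
#' @export
truth_segments <- function(truth) {
  call <- ifelse(truth$copy < 2, "deletion",
          ifelse(truth$copy == 2, "neutral",
          ifelse(truth$copy == 3, "gain", "amplification")))
  data.frame(chrom = truth$chrom, start = truth$start, end = truth$end,
             copy = truth$copy, call = call, stringsAsFactors = FALSE)
}
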