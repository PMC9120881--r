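#' GC and mappability correction of binned read counts
#'
#' Removes the sample-specific GC bias by dividing counts by a loess fit of
#' count on GC fraction, then divides by bin mappability, and rescales so the
#' median corrected ratio over usable bins is 1. Bins with zero counts or zero
#' mappability are masked (NA) rather than floored.
#'
#' @param counts Integer/numeric vector of per-bin read counts.
#' @param annotation Data.frame with per-bin `gc` and `mappability`.
#' @param span Loess span for the GC trend (default 0.3).
#' @return Numeric vector of corrected ratios (median 1), NA where masked.
#' @export
correct_bias <- function(counts, annotation, span = 0.3) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == nrow(annotation))
  usable <- is.finite(counts) & counts > 0 & annotation$mappability > 0
  if (!any(usable) || all(counts[usable] == 0)) stop("all counts are zero")
  if (sum(usable) < 100) stop("fewer than 100 usable bins")
  if (stats::sd(annotation$gc[usable]) < 1e-8) {
    # no GC trend to remove: correction reduces to a global scaling
    trend <- rep(mean(counts[usable]), length(counts))
  } else {
    # symmetric family: M-estimation downweights bins shifted by real
    # copy-number events so the GC trend is fit on the neutral mass
    fit <- stats::loess(counts[usable] ~ annotation$gc[usable],
                        span = span, degree = 2, family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    trend <- stats::predict(fit, newdata = annotation$gc)
  }
  trend[!is.finite(trend) | trend <= 0] <- NA
  ratio <- counts / trend / annotation$mappability
  ratio[!usable] <- NA
  ratio / stats::median(ratio, na.rm = TRUE)
}

#' Build a panel of normals from corrected control profiles
#'
#' Summarizes >= 2 bias-corrected control samples into a per-bin reference:
#' the median and MAD of log2 corrected ratios across controls, plus a bin
#' blacklist (extreme GC, low mappability, or inter-normal MAD above a high
#' quantile). Subtracting the panel median from a sample profile removes
#' recurrent technical structure that single-sample GC correction leaves
#' behind.
#'
#' @param corrected List (or matrix, bins x samples) of corrected ratio
#'   vectors from [correct_bias()], all on the same layout.
#' @param annotation Per-bin `gc` and `mappability` data.frame.
#' @param gc_range Usable GC window (default `c(0.28, 0.65)`).
#' @param map_min Minimum usable mappability (default 0.9).
#' @param mad_quantile Inter-normal MAD quantile above which bins are
#'   blacklisted (default 0.99). Set any threshold to `NULL`/extremes to
#'   disable a rule.
#' @return List of class `reference_panel`: `median`, `mad` (per-bin, log2
#'   scale), `blacklist` (logical per bin), `n_samples`, `thresholds`.
#' @export
build_pon <- function(corrected, annotation, gc_range = c(0.28, 0.65),
                      map_min = 0.9, mad_quantile = 0.99) {
  if (is.list(corrected)) {
    len <- vapply(corrected, length, 0L)
    if (length(unique(len)) != 1) stop("control profiles have mismatched layouts")
    corrected <- do.call(cbind, corrected)
  }
  if (ncol(corrected) < 2) stop("a panel of normals needs at least 2 controls")
  if (nrow(corrected) != nrow(annotation))
    stop("controls and annotation have mismatched layouts")
  lg <- log2(corrected)
  lg[!is.finite(lg)] <- NA
  med <- apply(lg, 1, stats::median, na.rm = TRUE)
  md <- apply(lg, 1, stats::mad, na.rm = TRUE)
  blacklist <- annotation$gc < gc_range[1] | annotation$gc > gc_range[2] |
    annotation$mappability < map_min
  if (!is.null(mad_quantile)) {
    cut <- stats::quantile(md, mad_quantile, na.rm = TRUE)
    blacklist <- blacklist | (is.finite(md) & md > cut)
  }
  blacklist <- blacklist | !is.finite(med)
  structure(list(median = med, mad = md, blacklist = blacklist,
                 n_samples = ncol(corrected),
                 thresholds = list(gc_range = gc_range, map_min = map_min,
                                   mad_quantile = mad_quantile)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", x$n_samples, "controls,",
      sum(x$blacklist), "of", length(x$median), "bins blacklisted\n")
  invisible(x)
}

#' Normalize one corrected sample against a panel of normals
#'
#' Computes per-bin `log2(corrected ratio) - panel median`, masks blacklisted
#' and non-finite bins, and re-centres the profile so the median usable value
#' is 0. The result is the observation sequence the copy-number HMM segments.
#'
#' @param corrected Corrected ratio vector from [correct_bias()].
#' @param panel A `reference_panel` from [build_pon()], or `NULL` to skip PON
#'   subtraction (GC/mappability correction only).
#' @param layout A `genome_layout` providing bin coordinates.
#' @param sample_id Identifier stored on the profile.
#' @return Data.frame of class `log2_profile` with columns `chrom`, `start`,
#'   `end`, `log2ratio`, `masked`, and attributes `sample_id` and `noise`
#'   (median absolute difference of adjacent usable bins).
#' @export
normalize_sample <- function(corrected, panel, layout, sample_id = "sample") {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(corrected) != nrow(layout$bins))
    stop("sample and layout have mismatched lengths")
  lr <- log2(corrected)
  masked <- !is.finite(lr)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "reference_panel"))
    if (length(panel$median) != length(corrected))
      stop("sample and panel have mismatched layouts")
    lr <- lr - panel$median
    masked <- masked | panel$blacklist | !is.finite(lr)
  }
  lr[masked] <- NA
  lr <- lr - stats::median(lr, na.rm = TRUE)
  out <- data.frame(chrom = layout$bins$chrom, start = layout$bins$start,
                    end = layout$bins$end, log2ratio = lr, masked = masked,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "noise") <- stats::median(abs(diff(lr[!masked])), na.rm = TRUE)
  class(out) <- c("log2_profile", "data.frame")
  out
}
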