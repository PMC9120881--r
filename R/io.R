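#' Read and write binned read counts
#'
#' Bin counts travel as TSV with columns `chrom`, `start`, `end`, `count`
#' (0-based half-open coordinates matching the layout), or as fixed-step WIG
#' (one `fixedStep` block per chromosome at the layout's bin size).
#'
#' @param counts Integer vector of per-bin counts.
#' @param layout A `genome_layout`.
#' @param path Output/input file path.
#' @return `read_bin_counts()` returns an integer vector aligned to the
#'   layout; writers return `path` invisibly.
#' @export
write_bin_counts <- function(counts, layout, path) {
  stopifnot(length(counts) == nrow(layout$bins))
  df <- data.frame(chrom = layout$bins$chrom, start = layout$bins$start,
                   end = layout$bins$end, count = as.integer(counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path, layout) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(df)))
    stop("malformed bin-count file (need chrom/start/end/count): ", path)
  key_file <- paste(df$chrom, df$start)
  key_layout <- paste(layout$bins$chrom, layout$bins$start)
  idx <- match(key_layout, key_file)
  if (anyNA(idx)) stop("bin-count file does not match the layout: ", path)
  as.integer(df$count[idx])
}

#' @rdname write_bin_counts
#' @export
write_wig <- function(counts, layout, path) {
  stopifnot(length(counts) == nrow(layout$bins))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in layout$genome$chrom) {
    sel <- layout$bins$chrom == ch
    # WIG fixedStep is 1-based
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d", ch,
                       as.integer(layout$bin_size),
                       as.integer(layout$bin_size)), con)
    writeLines(format(counts[sel], scientific = FALSE, trim = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_wig <- function(path, layout) {
  lines <- readLines(path)
  heads <- grep("^fixedStep", lines)
  if (!length(heads)) stop("not a fixedStep WIG file: ", path)
  out <- rep(NA_integer_, nrow(layout$bins))
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads)) {
    ch <- sub('.*chrom=([^ ]+).*', '\\1', lines[heads[i]])
    vals <- as.integer(lines[(heads[i] + 1):(bounds[i + 1] - 1)])
    sel <- which(layout$bins$chrom == ch)
    if (length(vals) != length(sel))
      stop("WIG block length mismatch on ", ch)
    out[sel] <- vals
  }
  if (anyNA(out)) stop("WIG file missing chromosomes present in the layout")
  out
}

#' Read and write SEG-format segment tables
#'
#' Standard SEG columns: sample, chrom, start, end, n_bins (`num.mark`),
#' seg_mean, plus the package's copy-number `call` column.
#'
#' @param segments Segment data.frame from [viterbi_segments()].
#' @param sample_id Sample identifier for the first column.
#' @param path File path.
#' @return `read_seg()` returns a data.frame; writers return `path`
#'   invisibly.
#' @export
write_seg <- function(segments, sample_id, path) {
  df <- data.frame(sample = sample_id, chrom = segments$chrom,
                   start = segments$start, end = segments$end,
                   n_bins = segments$n_bins,
                   seg_mean = round(segments$seg_mean, 6),
                   copy = segments$copy, call = segments$call)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "call")
  if (!all(need %in% names(df))) stop("malformed SEG file: ", path)
  df
}

#' Write a log2-ratio profile as TSV
#'
#' @param profile A `log2_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(chrom = profile$chrom, start = profile$start,
                   end = profile$end,
                   log2ratio = round(profile$log2ratio, 6),
                   masked = profile$masked)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a panel of normals
#'
#' The panel is stored as TSV with a `#`-comment header recording the number
#' of control samples and the blacklist thresholds.
#'
#' @param panel A `reference_panel`.
#' @param layout A `genome_layout`.
#' @param path File path.
#' @return `read_pon()` returns a `reference_panel`.
#' @export
write_pon <- function(panel, layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  th <- panel$thresholds
  writeLines(c(
    sprintf("# n_samples=%d", panel$n_samples),
    sprintf("# gc_range=%g,%g", th$gc_range[1], th$gc_range[2]),
    sprintf("# map_min=%g", th$map_min),
    sprintf("# mad_quantile=%s",
            if (is.null(th$mad_quantile)) "NA" else format(th$mad_quantile))),
    con)
  df <- data.frame(chrom = layout$bins$chrom, start = layout$bins$start,
                   end = layout$bins$end,
                   median = round(panel$median, 6), mad = round(panel$mad, 6),
                   blacklist = panel$blacklist)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pon
#' @export
read_pon <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  get <- function(key) sub(paste0("# ", key, "="), "",
                           grep(paste0("^# ", key, "="), hdr, value = TRUE))
  gc_range <- as.numeric(strsplit(get("gc_range"), ",")[[1]])
  mq <- get("mad_quantile")
  structure(list(median = df$median, mad = df$mad, blacklist = df$blacklist,
                 n_samples = as.integer(get("n_samples")),
                 thresholds = list(gc_range = gc_range,
                                   map_min = as.numeric(get("map_min")),
                                   mad_quantile = if (mq == "NA") NULL else
                                     as.numeric(mq))),
            class = "reference_panel")
}

#' Write a synthetic cohort to a pipeline-ready directory
#'
#' Lays out a simulated cohort as the pipeline expects its inputs: one
#' bin-count TSV per sample under `counts/`, the bin annotation, a sample
#' sheet, per-patient truth segments (one SEG-like TSV), clinical and outcome
#' tables, and the generating configuration as JSON.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()] (with counts).
#' @param dir Output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$counts)) stop("cohort was simulated without counts")
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory not empty (use overwrite = TRUE): ", dir)
  dir.create(file.path(dir, "counts"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  layout <- cohort$layout
  for (sid in colnames(cohort$counts))
    write_bin_counts(cohort$counts[, sid], layout,
                     file.path(dir, "counts", paste0(sid, ".tsv")))
  utils::write.table(cbind(layout$bins, cohort$annotation),
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$outcomes, file.path(dir, "outcomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(cohort$truth)) {
    tr <- cohort$truth[[i]]
    utils::write.table(
      data.frame(patient_id = sprintf("P%02d", i), tr),
      file.path(dir, "truth", sprintf("P%02d.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- unclass(cohort$config)
  cfg$event_menu <- as.list(cfg$event_menu)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
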