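#' hg19 autosome table
#'
#' Chromosome lengths and centromere (p/q boundary) positions for the 22 human
#' autosomes on the hg19 assembly, following UCSC cytoband conventions. This is
#' the coordinate frame shared by every binned profile in the package; sex
#' chromosomes are deliberately excluded because copy-ratio interpretation on
#' chrX/chrY depends on patient sex.
#'
#' @return A data.frame with columns `chrom`, `length` (bp) and `centromere`
#'   (bp position splitting the p and q arms).
#' @export
hg19_genome_table <- function() {
  path <- system.file("extdata", "hg19_autosomes.tsv", package = "shallowCNA",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a fixed-width bin layout over the autosomes
#'
#' Tiles each chromosome of `genome_table` with non-overlapping windows of
#' `bin_size` base pairs (0-based, half-open); the last window of a chromosome
#' may be shorter. Each bin is assigned to the p or q arm by its midpoint
#' relative to the centromere position.
#'
#' @param bin_size Window width in base pairs (default 1 Mb, the resolution at
#'   which large-scale copy-number events are profiled from ~3x cfDNA WGS).
#' @param genome_table A data.frame with columns `chrom`, `length`,
#'   `centromere`; defaults to [hg19_genome_table()].
#' @return An object of class `genome_layout`: a list with `bin_size`,
#'   `genome` (the input table) and `bins`, a data.frame with columns `chrom`,
#'   `start`, `end`, `arm` (e.g. `"1q"`).
#' @examples
#' layout <- make_layout()
#' sum(layout$bins$chrom == "chr21")  # 49 one-megabase bins
#' @export
make_layout <- function(bin_size = 1e6, genome_table = hg19_genome_table()) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("`bin_size` must be a single positive number")
  need <- c("chrom", "length", "centromere")
  if (!all(need %in% names(genome_table)))
    stop("`genome_table` must have columns chrom, length, centromere")
  if (anyDuplicated(genome_table$chrom))
    stop("duplicated chromosome names in `genome_table`")
  bin_size <- as.numeric(bin_size)
  pieces <- lapply(seq_len(nrow(genome_table)), function(i) {
    len <- genome_table$length[i]
    cen <- genome_table$centromere[i]
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    mid <- (starts + ends) / 2
    arm_letter <- ifelse(mid < cen, "p", "q")
    data.frame(chrom = genome_table$chrom[i], start = starts, end = ends,
               arm = paste0(sub("^chr", "", genome_table$chrom[i]), arm_letter),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  structure(list(bin_size = bin_size, genome = genome_table, bins = bins),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$genome), "chromosomes,",
      nrow(x$bins), "bins of", format(x$bin_size, big.mark = ","), "bp\n")
  invisible(x)
}

#' Chromosome-arm intervals of a layout
#'
#' @param layout A `genome_layout`.
#' @return A data.frame with columns `arm`, `chrom`, `start`, `end`,
#'   `length` (bp), one row per arm in genome order.
#' @export
arm_table <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  g <- layout$genome
  out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    nm <- sub("^chr", "", g$chrom[i])
    data.frame(arm = paste0(nm, c("p", "q")), chrom = g$chrom[i],
               start = c(0, g$centromere[i]),
               end = c(g$centromere[i], g$length[i]),
               stringsAsFactors = FALSE)
  }))
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

# index of the chromosome of each bin, as a factor in genome order
.bin_chrom_factor <- function(layout) {
  factor(layout$bins$chrom, levels = layout$genome$chrom)
}

# deterministic child seed for a named random substream (kept < 2^31)
.substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  s <- as.double(seed %% 2147483647)
  for (k in codes) s <- (s * 69069 + k) %% 2147483647
  as.integer(s)
}
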