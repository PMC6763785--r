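#' Genomic interval (1-based, inclusive)
#'
#' Coordinates are 1-based with inclusive ends, the convention under
#' which the exon-4 quantification window spans exactly 42 nt = 14
#' codons. BED input (0-based half-open) is converted on read.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions, `1 <= start <= end`.
#' @param label Optional interval label.
#' @return Object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, label = NA_character_) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  stop_if_not_scalar_num_(start, "start"); stop_if_not_scalar_num_(end, "end")
  if (start < 1) stop("positions are 1-based: start must be >= 1",
                      call. = FALSE)
  if (start > end) stop("start must be <= end", call. = FALSE)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), label = label),
            class = "genomic_interval")
}

#' Length of a genomic interval in nucleotides
#'
#' @param interval A [genomic_interval].
#' @return `end - start + 1`.
#' @export
interval_length <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  interval$end - interval$start + 1L
}

#' CD300f exon quantification windows (GRCh38)
#'
#' The two read-counting windows used to contrast canonical CD300f
#' (exon-4-lacking) with the exon-4 splice form: exon 3 at
#' chr17:74,704,478-74,704,517 (40 nt, shared by all isoforms) and exon 4
#' at chr17:74,703,100-74,703,141 (42 nt, the Ser/Thr-rich 14-codon
#' insert present only in the splice form). Treated as opaque
#' quantification targets.
#'
#' @return Named list of [genomic_interval]s (`exon3`, `exon4`).
#' @export
cd300f_exon_model <- function() {
  list(exon3 = genomic_interval("chr17", 74704478, 74704517, "exon3"),
       exon4 = genomic_interval("chr17", 74703100, 74703141, "exon4"))
}

reads_df_ <- function(reads) {
  if (inherits(reads, "read_alignment_set")) reads <- reads$reads
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "end") %in% names(reads)))
  reads
}

#' Count reads overlapping a target interval
#'
#' A read counts when it shares at least `min_overlap` bases with the
#' target on the same chromosome (inclusive coordinates, so a read ending
#' at `start - 1` does not count). Strand is ignored.
#'
#' @param reads A `read_alignment_set` or a data.frame with columns
#'   `chrom`, `start`, `end` (1-based inclusive).
#' @param target A [genomic_interval].
#' @param min_overlap Minimum shared bases (>= 1).
#' @return Integer count.
#' @export
count_overlapping_reads <- function(reads, target, min_overlap = 1) {
  stopifnot(inherits(target, "genomic_interval"))
  if (!is.numeric(min_overlap) || length(min_overlap) != 1L ||
      min_overlap < 1)
    stop("min_overlap must be >= 1", call. = FALSE)
  df <- reads_df_(reads)
  df <- df[df$chrom == target$chrom, , drop = FALSE]
  if (!nrow(df)) return(0L)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  tg <- GenomicRanges::GRanges(target$chrom,
                               IRanges::IRanges(target$start, target$end))
  GenomicRanges::countOverlaps(tg, gr, minoverlap = as.integer(min_overlap))
}

#' Reads per kilobase of target per million library reads
#'
#' `RPKM = (count / (total_reads / 1e6)) / (target length in kb)`.
#'
#' @param count Reads overlapping the target (>= 0).
#' @param total_reads Total aligned reads in the library (> 0).
#' @param target A [genomic_interval].
#' @return Scalar RPKM.
#' @export
rpkm <- function(count, total_reads, target) {
  stop_if_not_scalar_num_(count, "count")
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  stop_if_not_scalar_num_(total_reads, "total_reads", positive = TRUE)
  (count / (total_reads / 1e6)) / (interval_length(target) / 1000)
}

#' Per-sample exon counts and RPKM over an exon model
#'
#' @param read_sets List of `read_alignment_set` objects (from
#'   [simulate_reads] or [read_reads_bed]).
#' @param exon_model Named list of [genomic_interval]s.
#' @param min_overlap Passed to [count_overlapping_reads].
#' @return data.frame: sample, group, exon, count, rpkm.
#' @export
quantify_exons <- function(read_sets, exon_model = cd300f_exon_model(),
                           min_overlap = 1) {
  stopifnot(length(read_sets) > 0)
  rows <- lapply(read_sets, function(rs) {
    stopifnot(inherits(rs, "read_alignment_set"))
    do.call(rbind, lapply(names(exon_model), function(ex) {
      cnt <- count_overlapping_reads(rs, exon_model[[ex]], min_overlap)
      data.frame(sample = rs$sample, group = rs$group, exon = ex,
                 count = cnt,
                 rpkm = rpkm(cnt, rs$total_reads, exon_model[[ex]]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison of exon-level expression
#'
#' Per exon, a one-way ANOVA of RPKM across groups with pairwise post hoc
#' comparisons (Tukey HSD by default, Holm-corrected pairwise Welch tests
#' as an alternative).
#'
#' @param expressions data.frame from [quantify_exons] (columns `group`,
#'   `exon`, and the value column).
#' @param value Column to compare (default `"rpkm"`).
#' @param posthoc `"tukey"` or `"holm_welch"`.
#' @return Named list (one element per exon) of
#'   [one_way_anova_posthoc] results.
#' @export
exon_usage_compare <- function(expressions, value = "rpkm",
                               posthoc = c("tukey", "holm_welch")) {
  posthoc <- match.arg(posthoc)
  stopifnot(is.data.frame(expressions),
            all(c("group", "exon", value) %in% names(expressions)))
  out <- lapply(split(expressions, expressions$exon), function(d) {
    one_way_anova_posthoc(d[[value]], d$group, posthoc = posthoc)
  })
  out
}

#' Estimate the exon-4 transcript fraction from exon RPKMs
#'
#' Because every CD300f transcript carries the exon-3 window and only the
#' splice form carries exon 4, the length-normalised pooled count ratio
#' `(sum count4 / len4) / (sum count3 / len3)` estimates the exon-4
#' transcript fraction.
#'
#' @param expressions data.frame from [quantify_exons]; may span several
#'   samples of one group.
#' @param exon_model Exon model supplying interval lengths.
#' @return Estimated fraction in \[0, 1\] (can exceed 1 under sampling
#'   noise at fractions near 1).
#' @export
estimate_exon4_fraction <- function(expressions,
                                    exon_model = cd300f_exon_model()) {
  stopifnot(all(c("exon", "count") %in% names(expressions)))
  c4 <- sum(expressions$count[expressions$exon == "exon4"])
  c3 <- sum(expressions$count[expressions$exon == "exon3"])
  if (c3 == 0) stop("no exon-3 reads: fraction undefined", call. = FALSE)
  (c4 / interval_length(exon_model$exon4)) /
    (c3 / interval_length(exon_model$exon3))
}
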