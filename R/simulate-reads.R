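#' Minimal CD300f transcript model for read simulation
#'
#' A two-transcript model of the locus sufficient for the exon-window
#' contrast: both transcripts share an upstream block, the exon-3 window
#' and a downstream block; only the splice-form transcript additionally
#' carries the exon-4 window. Block coordinates bracket the genuine
#' GRCh38 quantification windows; the flanking blocks are synthetic
#' transcript body standing in for the remaining exons, sized so the
#' canonical transcript is 2 kb.
#'
#' @return List with `chrom` and two data.frames of blocks in transcript
#'   order (`blocks_C`, `blocks_SI4`; columns start, end, label).
#' @export
cd300f_transcript_model <- function() {
  ex <- cd300f_exon_model()
  upstream <- data.frame(start = 74706000L, end = 74706999L,
                         label = "body_upstream")
  exon3 <- data.frame(start = ex$exon3$start, end = ex$exon3$end,
                      label = "exon3")
  exon4 <- data.frame(start = ex$exon4$start, end = ex$exon4$end,
                      label = "exon4")
  downstream <- data.frame(start = 74701500L, end = 74702459L,
                           label = "body_downstream")
  list(chrom = "chr17",
       blocks_C = rbind(upstream, exon3, downstream),
       blocks_SI4 = rbind(upstream, exon3, exon4, downstream))
}

blocks_len_ <- function(blocks) sum(blocks$end - blocks$start + 1L)

#' Read-simulation specification
#'
#' Each group has an exon-4 transcript fraction (fraction of CD300f
#' molecules that are the splice form), a mean expression level (the
#' fraction of the aligned library falling on the CD300f locus) and a
#' sample count. Per sample, the number of locus reads is
#' `round(library_size * expression * lognormal(cv = expression_cv))`;
#' `library_size` is the total aligned library used as the RPKM
#' denominator.
#'
#' @param groups Named list; each element a list with `exon4_fraction`
#'   in \[0, 1\], `n_samples` >= 1 and optional `expression` overriding
#'   the shared default.
#' @param library_size Total aligned reads per library (> 0).
#' @param read_length Read length in nt (> 0).
#' @param expression Default locus expression fraction.
#' @param expression_cv Between-sample log-normal CV of expression.
#' @param transcript_model See [cd300f_transcript_model].
#' @return Object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(groups, library_size = 1e6, read_length = 50,
                          expression = 0.002, expression_cv = 0.15,
                          transcript_model = cd300f_transcript_model()) {
  stopifnot(length(groups) > 0, !is.null(names(groups)))
  for (g in names(groups)) {
    f <- groups[[g]]$exon4_fraction
    if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
      stop(sprintf("group '%s': exon4_fraction must lie in [0, 1]", g),
           call. = FALSE)
    ns <- groups[[g]]$n_samples
    if (!is.numeric(ns) || ns < 1)
      stop(sprintf("group '%s': n_samples must be >= 1", g), call. = FALSE)
  }
  stop_if_not_scalar_num_(library_size, "library_size", positive = TRUE)
  stop_if_not_scalar_num_(read_length, "read_length")
  if (read_length <= 0) stop("read_length must be > 0", call. = FALSE)
  stop_if_not_scalar_num_(expression, "expression", positive = TRUE)
  structure(list(groups = groups, library_size = library_size,
                 read_length = as.integer(read_length),
                 expression = expression, expression_cv = expression_cv,
                 transcript_model = transcript_model),
            class = "read_sim_spec")
}

#' Aligned-read interval set for one sample
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param total_reads Library size for RPKM normalisation; must be at
#'   least the number of stored reads.
#' @param sample,group Identifiers.
#' @return Object of class `read_alignment_set`.
#' @export
read_alignment_set <- function(reads, total_reads, sample, group = NA) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "end") %in% names(reads)))
  if (total_reads < nrow(reads))
    stop("total_reads must be >= the number of stored reads", call. = FALSE)
  structure(list(reads = reads, total_reads = total_reads,
                 n_reads = nrow(reads), sample = sample, group = group),
            class = "read_alignment_set")
}

#' @export
print.read_alignment_set <- function(x, ...) {
  cat(sprintf("<read_alignment_set> %s (%s): %d reads / library %g\n",
              x$sample, x$group, x$n_reads, x$total_reads))
  invisible(x)
}

# Place `n` reads of length L uniformly over a transcript given as
# ordered blocks; each read is reported as one genomic interval — the
# block holding the read midpoint, clipped to that block — so expected
# window counts are proportional to window length.
place_reads_ <- function(n, blocks, L, chrom) {
  lens <- blocks$end - blocks$start + 1L
  tlen <- sum(lens)
  if (tlen < L) stop("read_length exceeds transcript length", call. = FALSE)
  starts <- sample.int(tlen - L + 1L, n, replace = TRUE) - 1L  # 0-based
  mids <- starts + (L - 1L) %/% 2L
  toffs <- cumsum(c(0L, lens))                  # block start offsets
  bi <- findInterval(mids, toffs, rightmost.closed = FALSE)
  bstart_t <- toffs[bi]
  bend_t <- toffs[bi + 1L] - 1L
  clip_s <- pmax(starts, bstart_t)
  clip_e <- pmin(starts + L - 1L, bend_t)
  gstart <- blocks$start[bi] + (clip_s - bstart_t)
  gend <- blocks$start[bi] + (clip_e - bstart_t)
  data.frame(chrom = chrom, start = gstart, end = gend,
             stringsAsFactors = FALSE)
}

#' Simulate aligned reads over the CD300f locus
#'
#' For each sample, reads are drawn from the two-transcript pool with
#' molecule abundances `(1 - f, f)` for the canonical and splice-form
#' transcripts; a transcript is chosen with probability proportional to
#' abundance times its number of valid read start positions, then the
#' start is uniform along the transcript. Only splice-form reads can
#' overlap the exon-4 window; every transcript covers exon 3.
#'
#' @param spec A [read_sim_spec].
#' @param seed Integer seed (fixed seed, identical read sets).
#' @return Named list of [read_alignment_set], one per sample
#'   (`<group>_<i>`).
#' @export
simulate_reads <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "read_sim_spec"))
  tm <- spec$transcript_model
  L <- spec$read_length
  len_C <- blocks_len_(tm$blocks_C)
  len_SI4 <- blocks_len_(tm$blocks_SI4)
  with_seed_(seed, {
    out <- list()
    for (g in names(spec$groups)) {
      grp <- spec$groups[[g]]
      f <- grp$exon4_fraction
      expr_mean <- if (!is.null(grp$expression)) grp$expression
                   else spec$expression
      for (i in seq_len(grp$n_samples)) {
        cv <- spec$expression_cv
        expr <- if (cv > 0) expr_mean * lnorm_noise_(1, cv) else expr_mean
        n <- max(0L, as.integer(round(spec$library_size * expr)))
        w_si4 <- f * (len_SI4 - L + 1L)
        w_c <- (1 - f) * (len_C - L + 1L)
        n_si4 <- stats::rbinom(1, n, w_si4 / (w_si4 + w_c))
        reads <- rbind(
          if (n - n_si4 > 0) place_reads_(n - n_si4, tm$blocks_C, L,
                                          tm$chrom),
          if (n_si4 > 0) place_reads_(n_si4, tm$blocks_SI4, L, tm$chrom))
        if (is.null(reads))
          reads <- data.frame(chrom = character(0), start = integer(0),
                              end = integer(0))
        id <- sprintf("%s_%d", g, i)
        out[[id]] <- read_alignment_set(reads, spec$library_size, id, g)
      }
    }
    out
  })
}
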