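#' Isoform-specific CD300f primer set
#'
#' The splice-variant primer set: a splice-form-specific forward primer
#' (CD300f_SI4_F, detecting the exon-4-containing isoforms 4 and 6), a
#' canonical-junction forward primer (CD300f_C_F, detecting the
#' exon-4-lacking isoforms 1, 2, 3, 5 and 7), a shared reverse primer
#' (CD300f_Ex4_R), and the HPRT1 endogenous-control pair.
#'
#' @return data.frame: name, sequence (5' to 3').
#' @export
cd300f_primers <- function() {
  data.frame(
    name = c("Fw_hHPRT1", "Rv_hHPRT1", "CD300f_SI4_F", "CD300f_C_F",
             "CD300f_Ex4_R"),
    sequence = c("AATTATGGACAGGACTGAACGTCTTGCT",
                 "TCCAGCAGGTCAGCAAAGAATTTATAGC",
                 "CACGCCTACCTCCACTACGTTT",
                 "ATTGACCCAGCACCAGTCACC",
                 "GGTGGCCGGTCAGAGTTG"),
    stringsAsFactors = FALSE)
}

#' Map a primer pair to the CD300f isoform class it amplifies
#'
#' The splice-form forward primer with the shared reverse amplifies the
#' exon-4-containing isoforms (4 and 6); the canonical forward primer
#' with the shared reverse amplifies the exon-4-lacking isoforms (1, 2,
#' 3, 5, 7); the HPRT1 pair is the endogenous reference. (The published
#' annotation of the canonical forward primer reads "amplifies exon 4"
#' although its targets lack exon 4; the mapping here implements the
#' evident class split.)
#'
#' @param forward,reverse Primer names (see [cd300f_primers]).
#' @return Character vector of isoform names, or `"reference"`.
#' @export
assign_amplicon <- function(forward, reverse) {
  key <- paste(forward, reverse, sep = "+")
  map <- list(
    "CD300f_SI4_F+CD300f_Ex4_R" = c("Isoform 4", "Isoform 6"),
    "CD300f_C_F+CD300f_Ex4_R" = c("Isoform 1", "Isoform 2", "Isoform 3",
                                  "Isoform 5", "Isoform 7"),
    "Fw_hHPRT1+Rv_hHPRT1" = "reference")
  hit <- map[[key]]
  if (is.null(hit))
    stop(sprintf("unknown primer pair %s + %s", forward, reverse),
         call. = FALSE)
  hit
}

#' Relative quantification by the delta-delta-CT method
#'
#' Technical replicates are averaged (arithmetic mean of CT), each
#' sample's target CT is normalised against the reference gene
#' (`dCT = CT_target - CT_reference`), and fold changes are expressed
#' against a calibrator sample: `ddCT = dCT_sample - dCT_calibrator`,
#' `fold = 2^-ddCT`. The calibrator's fold change is exactly 1. The
#' estimator assumes efficiency 1 (plain `2^-ddCT`); censored CTs
#' propagate a censored flag with `NA` fold change rather than a number.
#'
#' @param measurements data.frame: sample, amplicon, replicate, ct, and
#'   optionally censored.
#' @param reference_gene Amplicon id of the endogenous reference.
#' @param calibrator_sample Sample id of the calibrator.
#' @return data.frame of class `fold_change_result`: sample, amplicon,
#'   delta_ct, delta_delta_ct, fold_change, censored.
#' @export
delta_delta_ct <- function(measurements, reference_gene,
                           calibrator_sample) {
  stopifnot(is.data.frame(measurements),
            all(c("sample", "amplicon", "ct") %in% names(measurements)))
  if (is.null(measurements$censored)) measurements$censored <- FALSE
  agg <- stats::aggregate(
    cbind(ct = measurements$ct, censored = measurements$censored),
    by = list(sample = measurements$sample,
              amplicon = measurements$amplicon),
    FUN = function(x) mean(x))
  agg$censored <- agg$censored > 0
  ref <- agg[agg$amplicon == reference_gene, ]
  if (!nrow(ref))
    stop(sprintf("no measurements for reference gene '%s'", reference_gene),
         call. = FALSE)
  targets <- agg[agg$amplicon != reference_gene, ]
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  missing_ref <- setdiff(unique(targets$sample), names(ref_ct))
  if (length(missing_ref))
    stop("samples lack a reference-gene CT: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  targets$delta_ct <- targets$ct - ref_ct[targets$sample]
  if (!calibrator_sample %in% targets$sample)
    stop(sprintf("calibrator sample '%s' not found", calibrator_sample),
         call. = FALSE)
  out <- do.call(rbind, lapply(split(targets, targets$amplicon),
                               function(d) {
    cal <- d$delta_ct[d$sample == calibrator_sample]
    if (!length(cal))
      stop(sprintf("calibrator lacks amplicon '%s'", d$amplicon[1]),
           call. = FALSE)
    d$delta_delta_ct <- d$delta_ct - cal
    d$delta_delta_ct[d$sample == calibrator_sample] <- 0
    d$fold_change <- 2^(-d$delta_delta_ct)
    d$fold_change[d$censored] <- NA_real_
    d
  }))
  rownames(out) <- NULL
  out <- out[, c("sample", "amplicon", "delta_ct", "delta_delta_ct",
                 "fold_change", "censored")]
  class(out) <- c("fold_change_result", class(out))
  out
}

#' Group contrast of qPCR fold changes per amplicon class
#'
#' Welch t-test on log2 fold changes between two groups, separately for
#' each amplicon.
#'
#' @param results data.frame from [delta_delta_ct].
#' @param groups Named character vector mapping sample id -> group label
#'   (exactly two groups, each with >= 2 samples per amplicon).
#' @return data.frame: amplicon, group_a, group_b, statistic, df,
#'   p_value, direction (sign of group_a minus group_b mean log2 fold).
#' @export
isoform_class_contrast <- function(results, groups) {
  stopifnot(is.data.frame(results),
            all(c("sample", "amplicon", "fold_change") %in% names(results)))
  results <- results[results$sample %in% names(groups) &
                       !is.na(results$fold_change), ]
  results$group <- groups[results$sample]
  lv <- unique(groups)
  if (length(lv) != 2)
    stop("exactly two groups are required", call. = FALSE)
  out <- do.call(rbind, lapply(split(results, results$amplicon),
                               function(d) {
    a <- log2(d$fold_change[d$group == lv[1]])
    b <- log2(d$fold_change[d$group == lv[2]])
    tt <- welch_t_test(a, b)
    data.frame(amplicon = d$amplicon[1], group_a = lv[1], group_b = lv[2],
               statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
               direction = tt$direction, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
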