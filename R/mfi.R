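#' Median fluorescence intensity of a gated population
#'
#' The MFI is the median channel intensity (even counts: midpoint of the
#' two central order statistics). Some instruments report a geometric
#' mean instead; that is available as an option, but the median is the
#' canonical statistic here.
#'
#' @param events Event-table data.frame (nonempty).
#' @param channel Channel name.
#' @param type `"median"` (default) or `"geom_mean"`.
#' @return Scalar intensity.
#' @export
mfi <- function(events, channel, type = c("median", "geom_mean")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(events))
  if (!channel %in% names(events))
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  x <- events[[channel]]
  if (!length(x)) stop("cannot compute an MFI on an empty subset",
                       call. = FALSE)
  if (type == "median") stats::median(x) else exp(mean(log(x)))
}

#' MFI ratio of a stained population over its isotype control
#'
#' @param mfi_stained,mfi_isotype Scalar MFIs; the isotype MFI must be
#'   positive (a nonpositive value signals an invalid control).
#' @return `mfi_stained / mfi_isotype`.
#' @export
mfi_ratio <- function(mfi_stained, mfi_isotype) {
  stop_if_not_scalar_num_(mfi_stained, "mfi_stained")
  stop_if_not_scalar_num_(mfi_isotype, "mfi_isotype")
  if (mfi_isotype <= 0)
    stop("isotype MFI must be > 0 (invalid isotype control)", call. = FALSE)
  mfi_stained / mfi_isotype
}

#' Positivity call from an MFI ratio
#'
#' A population is called positive when its MFI ratio is greater than or
#' equal to the threshold (default 3, the conventional cutoff used for
#' these panels).
#'
#' @param ratio Finite MFI ratio.
#' @param threshold Positivity cutoff (inclusive).
#' @return Logical.
#' @export
call_positive <- function(ratio, threshold = 3) {
  stop_if_not_scalar_num_(ratio, "ratio")
  ratio >= threshold
}

#' Percent binding of a test antibody in a cross-blocking experiment
#'
#' `100 * (MFI_test_after_primary - background_primary) /
#'        (MFI_test_after_isotype - background_isotype)`.
#' 0% means the saturating primary completely blocked the test antibody
#' (full epitope overlap); 100% means binding was unaffected (independent
#' epitopes); values above 100% indicate conformational enhancement.
#' Negative values (blocked arm below its background) are returned as-is
#' with a `low_signal` attribute rather than clamped.
#'
#' @param mfi_test_given_primary MFI of the test stain after primary
#'   preincubation.
#' @param mfi_background_primary_condition Background (test-isotype) MFI
#'   in the primary-preincubated arm.
#' @param mfi_test_given_isotype MFI of the test stain after isotype
#'   preincubation (the unblocked reference).
#' @param mfi_background_isotype_condition Background MFI in the
#'   isotype-preincubated arm.
#' @return Percent binding (scalar); attribute `low_signal` is `TRUE`
#'   when the value is negative.
#' @export
percent_binding <- function(mfi_test_given_primary,
                            mfi_background_primary_condition,
                            mfi_test_given_isotype,
                            mfi_background_isotype_condition) {
  den <- mfi_test_given_isotype - mfi_background_isotype_condition
  if (!is.finite(den) || den <= 0)
    stop("unblocked test stain is not above background (failed staining)",
         call. = FALSE)
  num <- mfi_test_given_primary - mfi_background_primary_condition
  structure(100 * num / den, low_signal = num < 0)
}

#' Conformational-enhancement index
#'
#' Ratio of background-subtracted test-antibody MFIs with and without a
#' preincubated enhancer antibody; values above 1 indicate enhancement.
#'
#' @param mfi_test_given_enhancer Test MFI after enhancer preincubation.
#' @param mfi_test_given_isotype Test MFI after isotype preincubation.
#' @param shared_background Background MFI common to both arms; must be
#'   below the isotype-arm signal.
#' @return Nonnegative ratio.
#' @export
enhancement_index <- function(mfi_test_given_enhancer,
                              mfi_test_given_isotype,
                              shared_background) {
  den <- mfi_test_given_isotype - shared_background
  if (!is.finite(den) || den <= 0)
    stop("test stain is not above background in the control arm",
         call. = FALSE)
  (mfi_test_given_enhancer - shared_background) / den
}

#' Summarise a simulated blocking experiment
#'
#' Computes the four arm MFIs of a [simulate_blocking_experiment] result
#' and the derived percent-binding statistic.
#'
#' @param sim A `blocking_sim` object.
#' @param type MFI statistic passed to [mfi].
#' @return One-row data.frame of class `blocking_result`: antibody names,
#'   the four MFIs, `percent_binding`, `fraction_bound`, `low_signal`.
#' @export
blocking_result <- function(sim, type = "median") {
  stopifnot(inherits(sim, "blocking_sim"))
  channel <- attr(sim, "test")
  m <- vapply(sim, mfi, numeric(1), channel = channel, type = type)
  pb <- percent_binding(m[["test_given_primary"]],
                        m[["background_primary"]],
                        m[["test_given_isotype"]],
                        m[["background_isotype"]])
  out <- data.frame(primary = attr(sim, "primary"), test = channel,
                    mfi_test_given_primary = m[["test_given_primary"]],
                    mfi_background_primary_condition = m[["background_primary"]],
                    mfi_test_given_isotype = m[["test_given_isotype"]],
                    mfi_background_isotype_condition = m[["background_isotype"]],
                    percent_binding = as.numeric(pb),
                    fraction_bound = as.numeric(pb) / 100,
                    low_signal = isTRUE(attr(pb, "low_signal")),
                    stringsAsFactors = FALSE)
  class(out) <- c("blocking_result", class(out))
  out
}

#' Epitope cross-blocking matrix
#'
#' Arranges pairwise percent-binding results into a primary-by-test
#' matrix and categorises each cell: `blocked` below `blocked_lt`,
#' `enhanced` above `enhanced_gt`, `independent` between. Self pairs are
#' expected `blocked`. The thresholds binarise a continuous statistic and
#' are configurable.
#'
#' @param results data.frame with columns `primary`, `test`,
#'   `percent_binding` (e.g. rbind-ed [blocking_result] rows), one row
#'   per ordered pair.
#' @param blocked_lt,enhanced_gt Category thresholds (percent).
#' @return Object of class `overlap_matrix`: list with numeric
#'   `percent` and character `category` matrices.
#' @export
epitope_overlap_matrix <- function(results, blocked_lt = 30,
                                   enhanced_gt = 130) {
  stopifnot(is.data.frame(results),
            all(c("primary", "test", "percent_binding") %in% names(results)))
  if (anyDuplicated(results[c("primary", "test")]))
    stop("duplicate antibody pair entries", call. = FALSE)
  abs_ <- union(results$primary, results$test)
  percent <- matrix(NA_real_, length(abs_), length(abs_),
                    dimnames = list(primary = abs_, test = abs_))
  percent[cbind(results$primary, results$test)] <- results$percent_binding
  category <- ifelse(is.na(percent), NA_character_,
                     ifelse(percent < blocked_lt, "blocked",
                            ifelse(percent > enhanced_gt, "enhanced",
                                   "independent")))
  structure(list(percent = percent, category = category,
                 blocked_lt = blocked_lt, enhanced_gt = enhanced_gt),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, digits = 1, ...) {
  cat("Cross-blocking matrix (% binding of test antibody; rows = primary)\n")
  print(round(x$percent, digits))
  cat(sprintf("\nCategories (blocked < %g%%, enhanced > %g%%):\n",
              x$blocked_lt, x$enhanced_gt))
  print(x$category, quote = FALSE)
  invisible(x)
}

#' Per-population MFI statistics and positivity calls
#'
#' For each gated population and each non-isotype antibody channel,
#' computes the MFI, the MFI ratio over the isotype channel within the
#' same population, and the positivity call.
#'
#' @param gated Named list of event-table subsets (e.g. from
#'   [apply_gates]).
#' @param panel Named list of [antibody_model] with an isotype control.
#' @param threshold Positivity threshold on the MFI ratio.
#' @return data.frame: population, antibody, n_events, mfi, mfi_isotype,
#'   mfi_ratio, positive.
#' @export
population_stats <- function(gated, panel, threshold = 3) {
  iso <- panel_isotype_(panel)
  tests <- Filter(function(a) !a$is_isotype, panel)
  rows <- list()
  for (popname in names(gated)) {
    ev <- gated[[popname]]
    if (!nrow(ev)) next
    m_iso <- mfi(ev, iso$name)
    for (ab in tests) {
      m <- mfi(ev, ab$name)
      r <- mfi_ratio(m, m_iso)
      rows[[length(rows) + 1L]] <- data.frame(
        population = popname, antibody = ab$name, n_events = nrow(ev),
        mfi = m, mfi_isotype = m_iso, mfi_ratio = r,
        positive = call_positive(r, threshold), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
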