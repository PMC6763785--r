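#' Amplicon definitions for the qPCR simulator
#'
#' @param amplicon Amplicon ids.
#' @param target_class Transcript class each amplicon amplifies (must
#'   match the class names used in the abundance table).
#' @param efficiency Per-amplicon amplification efficiency in (0, 1]
#'   (1 = perfect doubling per cycle).
#' @return data.frame with one row per amplicon.
#' @export
amplicon_set <- function(amplicon, target_class, efficiency = 1) {
  stopifnot(length(amplicon) == length(target_class))
  efficiency <- rep_len(efficiency, length(amplicon))
  if (any(efficiency <= 0 | efficiency > 1))
    stop("efficiency must lie in (0, 1]", call. = FALSE)
  data.frame(amplicon = amplicon, target_class = target_class,
             efficiency = efficiency, stringsAsFactors = FALSE)
}

#' Simulate qPCR CT values from transcript abundances
#'
#' Under efficiency `E`, the template doubles by `(1 + E)` per cycle, so
#' `CT = ct_ref - log(abundance / ref_abundance) / log(1 + E)` plus
#' Gaussian replicate noise (duplicate wells by default). Zero-abundance
#' classes — and any CT reaching the cycle limit — are censored at
#' `max_cycles`.
#'
#' @param abundances data.frame with columns `sample`, `class`,
#'   `abundance` (>= 0).
#' @param amplicons data.frame from [amplicon_set].
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per well (default 2).
#' @param replicate_sd Gaussian SD of replicate CT noise in cycles
#'   (0 = noiseless).
#' @param ct_ref CT of a template at `ref_abundance`.
#' @param ref_abundance Abundance anchoring `ct_ref`.
#' @param max_cycles Censoring limit.
#' @return data.frame of class `qpcr_measurements`: sample, amplicon,
#'   replicate, ct, censored.
#' @export
simulate_qpcr <- function(abundances, amplicons, seed = NULL,
                          n_replicates = 2, replicate_sd = 0.2,
                          ct_ref = 20, ref_abundance = 1,
                          max_cycles = 40) {
  stopifnot(is.data.frame(abundances),
            all(c("sample", "class", "abundance") %in% names(abundances)),
            all(abundances$abundance >= 0),
            all(c("amplicon", "target_class", "efficiency") %in%
                  names(amplicons)))
  if (any(amplicons$efficiency <= 0 | amplicons$efficiency > 1))
    stop("efficiency must lie in (0, 1]", call. = FALSE)
  with_seed_(seed, {
    rows <- list()
    for (a in seq_len(nrow(amplicons))) {
      amp <- amplicons[a, ]
      ab <- abundances[abundances$class == amp$target_class, ]
      for (s in seq_len(nrow(ab))) {
        x <- ab$abundance[s]
        for (r in seq_len(n_replicates)) {
          if (x <= 0) {
            ct <- max_cycles; cens <- TRUE
          } else {
            ct <- ct_ref - log(x / ref_abundance) / log1p(amp$efficiency) +
              (if (replicate_sd > 0) stats::rnorm(1, 0, replicate_sd) else 0)
            cens <- ct >= max_cycles
            if (cens) ct <- max_cycles
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample = ab$sample[s], amplicon = amp$amplicon, replicate = r,
            ct = ct, censored = cens, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("qpcr_measurements", class(out))
    out
  })
}
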