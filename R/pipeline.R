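#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the simulation specs, gate tree, antibody panel, thresholds
#' and seed for [run_pipeline]. All defaults describe the study
#' conditions the package emulates: an AML-like cohort with SI4-rich
#' monocytic populations, a CD300f-high cell-line profile for the
#' cross-blocking matrix, surface-SI4-rich vs surface-SI4-free group
#' profiles for the enhancement contrast, and RNA-seq / qPCR groups with
#' a high exon-4 transcript fraction only in the monocytic-AML-like
#' group.
#'
#' @param seed Integer master seed; stage seeds are derived as small
#'   offsets.
#' @param cohort [cohort_spec] for the gating/positivity stage.
#' @param gate_tree Root [gate_node].
#' @param panel Antibody panel (named list of [antibody_model]).
#' @param positivity_threshold MFI-ratio positivity cutoff.
#' @param blocking_profile [isoform_profile] of the cross-blocking
#'   target cells (cell-line-like, ~10^4 total copies).
#' @param blocking_n Events per blocking arm.
#' @param blocked_lt,enhanced_gt Category thresholds for the
#'   cross-blocking matrix (percent).
#' @param enhancement_profiles Named list of [isoform_profile], one per
#'   group, for the DCR-2 -> UP-D2 enhancement contrast.
#' @param enhancement_reps Replicate experiments per group.
#' @param read_spec [read_sim_spec] for the exon-quantification stage.
#' @param qpcr_groups Named list group -> list(C=, SI4=) mean abundances.
#' @param qpcr_n_samples Samples per qPCR group.
#' @param qpcr_cv Between-sample log-normal CV of abundances.
#' @param alpha Significance level used throughout.
#' @param out_dir Optional directory for JSON/TSV/Markdown outputs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            cohort = default_cohort_spec(),
                            gate_tree = default_gate_tree(),
                            panel = default_antibody_panel(),
                            positivity_threshold = 3,
                            blocking_profile = isoform_profile(4000, 6000),
                            blocking_n = 5000,
                            blocked_lt = 30, enhanced_gt = 130,
                            enhancement_profiles = list(
                              monocytic_aml = isoform_profile(600, 2400),
                              hspc = isoform_profile(1000, 0)),
                            enhancement_reps = 8,
                            read_spec = default_read_spec(),
                            qpcr_groups = list(
                              hspc = list(C = 1, SI4 = 0.05),
                              aml = list(C = 1, SI4 = 1)),
                            qpcr_n_samples = 6, qpcr_cv = 0.3,
                            alpha = 0.05, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(gate_tree, "gate_node"),
            inherits(blocking_profile, "isoform_profile"),
            inherits(read_spec, "read_sim_spec"))
  panel_isotype_(panel)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Default RNA-seq group specification
#'
#' Three groups of six libraries: HSPC-like (exon-4 transcript fraction
#' 0.05), monocytic-AML-like (0.5) and nonmonocytic-AML-like (0.1),
#' sharing the same mean CD300f expression so only exon-4 usage differs.
#'
#' @param n_samples Libraries per group.
#' @param library_size Total aligned reads per library.
#' @return A [read_sim_spec].
#' @export
default_read_spec <- function(n_samples = 6, library_size = 1e6) {
  read_sim_spec(groups = list(
    hspc = list(exon4_fraction = 0.05, n_samples = n_samples),
    monocytic_aml = list(exon4_fraction = 0.5, n_samples = n_samples),
    nonmonocytic_aml = list(exon4_fraction = 0.1, n_samples = n_samples)),
    library_size = library_size)
}

stage_ <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

# Epitope groups = connected components of the symmetric "blocked"
# relation between distinct antibodies in the category matrix.
epitope_groups_ <- function(category) {
  abs_ <- rownames(category)
  comp <- seq_along(abs_)
  for (i in seq_along(abs_)) for (j in seq_along(abs_)) {
    if (i == j) next
    blocked <- identical(category[i, j], "blocked") ||
      identical(category[j, i], "blocked")
    if (isTRUE(blocked)) comp[comp == comp[j]] <- comp[i]
  }
  unname(split(abs_, comp))
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Executes, in order: cytometry simulation, hierarchical gating,
#' per-population MFI-ratio positivity; the pairwise cross-blocking
#' matrix; the DCR-2 -> UP-D2 enhancement contrast between group
#' profiles; exon-level read simulation, RPKM quantification and ANOVA;
#' qPCR simulation, delta-delta-CT and the isoform-class contrast. A
#' stage failure aborts with the stage named.
#'
#' @param config A [pipeline_config].
#' @return Object of class `epitoflow_report`: a list with elements
#'   `positivity`, `blocking` (results + matrix + epitope groups),
#'   `enhancement` (per-group indices, tests and flags), `exon`
#'   (expression table + per-exon tests), `qpcr` (fold changes +
#'   contrast), and a `summary` character vector. When
#'   `config$out_dir` is set, JSON/TSV results and a Markdown summary
#'   are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  panel <- config$panel

  ## 1. cytometry: simulate, gate, positivity ---------------------------
  positivity <- stage_("cytometry", {
    ev <- simulate_event_table(config$cohort, panel, seed = seed)
    gated <- apply_gates(ev, config$gate_tree)
    leaves <- intersect(names(gated),
                        leaf_labels_(config$gate_tree))
    population_stats(gated[leaves], panel, config$positivity_threshold)
  })

  ## 2. cross-blocking matrix -------------------------------------------
  blocking <- stage_("blocking", {
    tests <- Filter(function(a) !a$is_isotype, panel)
    rows <- list(); k <- 0L
    for (p in tests) for (t in tests) {
      k <- k + 1L
      sim <- simulate_blocking_experiment(
        p, t, config$blocking_profile, n = config$blocking_n,
        seed = seed + 100 + k)
      rows[[k]] <- blocking_result(sim)
    }
    results <- do.call(rbind, rows)
    mat <- epitope_overlap_matrix(results, config$blocked_lt,
                                  config$enhanced_gt)
    enhanced <- which(mat$category == "enhanced", arr.ind = TRUE)
    list(results = results, matrix = mat,
         epitope_groups = epitope_groups_(mat$category),
         enhanced_pairs = if (nrow(enhanced)) data.frame(
           primary = rownames(mat$category)[enhanced[, 1]],
           test = colnames(mat$category)[enhanced[, 2]],
           stringsAsFactors = FALSE) else NULL)
  })

  ## 3. enhancement contrast between group profiles ---------------------
  enhancement <- stage_("enhancement", {
    primary <- panel[["DCR-2"]]; test <- panel[["UP-D2"]]
    if (is.null(primary) || is.null(test))
      stop("panel must contain DCR-2 and UP-D2 for the enhancement stage")
    out <- list()
    for (g in names(config$enhancement_profiles)) {
      idx <- vapply(seq_len(config$enhancement_reps), function(r) {
        sim <- simulate_blocking_experiment(
          primary, test, config$enhancement_profiles[[g]],
          n = config$blocking_n,
          seed = seed + 1000 + 100 * match(g, names(config$enhancement_profiles)) + r)
        bg <- mfi(rbind(sim$background_primary, sim$background_isotype),
                  test$name)
        enhancement_index(mfi(sim$test_given_primary, test$name),
                          mfi(sim$test_given_isotype, test$name), bg)
      }, numeric(1))
      tt <- stats::t.test(log(idx), mu = 0)
      out[[g]] <- list(indices = idx, mean_index = mean(idx),
                       p_value = tt$p.value,
                       flagged = tt$p.value < config$alpha && mean(idx) > 1)
    }
    out
  })

  ## 4. exon-level quantification ---------------------------------------
  exon <- stage_("exonquant", {
    rs <- simulate_reads(config$read_spec, seed = seed + 5000)
    expr <- quantify_exons(rs)
    tests <- exon_usage_compare(expr)
    list(expression = expr, tests = tests)
  })

  ## 5. qPCR ------------------------------------------------------------
  qpcr <- stage_("qpcr", {
    ab <- with_seed_(seed + 7000, {
      rows <- list()
      for (g in names(config$qpcr_groups)) {
        mu <- config$qpcr_groups[[g]]
        for (i in seq_len(config$qpcr_n_samples)) {
          s <- sprintf("%s_%d", g, i)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s,
            class = c("C", "SI4", "HPRT"),
            abundance = c(mu$C * lnorm_noise_(1, config$qpcr_cv),
                          mu$SI4 * lnorm_noise_(1, config$qpcr_cv),
                          lnorm_noise_(1, 0.1)),
            stringsAsFactors = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = "U937", class = c("C", "SI4", "HPRT"),
        abundance = c(1, 0.5, 1), stringsAsFactors = FALSE)
      do.call(rbind, rows)
    })
    amps <- amplicon_set(c("CD300f_C", "CD300f_SI4", "HPRT"),
                         c("C", "SI4", "HPRT"))
    meas <- simulate_qpcr(ab, amps, seed = seed + 7001)
    fc <- delta_delta_ct(meas, "HPRT", "U937")
    groups <- stats::setNames(
      rep(names(config$qpcr_groups), each = config$qpcr_n_samples),
      unlist(lapply(names(config$qpcr_groups), function(g)
        sprintf("%s_%d", g, seq_len(config$qpcr_n_samples)))))
    list(fold_changes = fc,
         contrast = isoform_class_contrast(fc, groups))
  })

  ## summary ------------------------------------------------------------
  alpha <- config$alpha
  exon_p <- vapply(exon$tests, function(x) x$test$p_value, numeric(1))
  flagged <- vapply(enhancement, `[[`, logical(1), "flagged")
  qc <- qpcr$contrast
  summary <- c(
    sprintf("Positive populations (MFI ratio >= %g): %d of %d calls",
            config$positivity_threshold, sum(positivity$positive),
            nrow(positivity)),
    sprintf("Cross-blocking: %d distinct epitope groups; %d enhanced pair(s)",
            length(blocking$epitope_groups),
            if (is.null(blocking$enhanced_pairs)) 0L
            else nrow(blocking$enhanced_pairs)),
    sprintf("Enhancement (DCR-2 -> UP-D2) flagged in: %s",
            if (any(flagged)) paste(names(flagged)[flagged],
                                    collapse = ", ") else "none"),
    sprintf("Exon-level ANOVA p-values: %s",
            paste(sprintf("%s = %.3g%s", names(exon_p), exon_p,
                          ifelse(exon_p < alpha, " *", "")),
                  collapse = ", ")),
    sprintf("qPCR class contrasts: %s",
            paste(sprintf("%s p = %.3g%s", qc$amplicon, qc$p_value,
                          ifelse(qc$p_value < alpha, " *", "")),
                  collapse = ", ")))

  report <- structure(
    list(positivity = positivity, blocking = blocking,
         enhancement = enhancement, exon = exon, qpcr = qpcr,
         summary = summary, config = config),
    class = "epitoflow_report")
  if (!is.null(config$out_dir)) write_report_(report, config$out_dir)
  report
}

leaf_labels_ <- function(node) {
  if (!length(node$children)) return(node$label)
  unlist(lapply(node$children, leaf_labels_))
}

write_report_ <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$positivity, file.path(dir, "positivity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$blocking$results,
                     file.path(dir, "blocking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$exon$expression,
                     file.path(dir, "exon_expression.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$qpcr$fold_changes,
                     file.path(dir, "qpcr_fold_changes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  machine <- list(
    epitope_groups = report$blocking$epitope_groups,
    enhanced_pairs = report$blocking$enhanced_pairs,
    enhancement = lapply(report$enhancement, function(x)
      x[c("mean_index", "p_value", "flagged")]),
    exon_anova_p = lapply(report$exon$tests,
                          function(x) x$test$p_value),
    qpcr_contrast = report$qpcr$contrast)
  jsonlite::write_json(machine, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c("# epitoflow pipeline summary", "", report$summary),
             file.path(dir, "summary.md"))
  invisible(dir)
}

#' @export
print.epitoflow_report <- function(x, ...) {
  cat("epitoflow pipeline report\n")
  cat(paste0("  - ", x$summary, collapse = "\n"), "\n")
  invisible(x)
}
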