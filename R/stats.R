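#' Welch two-sample t-test
#'
#' Unequal-variance t-test (Welch statistic, Welch-Satterthwaite degrees
#' of freedom, two-sided p). When both groups have zero variance and
#' equal means, the statistic is 0 and p = 1.
#'
#' @param group_a,group_b Numeric vectors with >= 2 values each.
#' @param paired If `TRUE`, a paired t-test on the differences.
#' @return One-row data.frame (class `test_result`): test, statistic,
#'   df, p_value, mean_a, mean_b, direction (+1 if group_a's mean is
#'   larger, -1 if smaller, 0 if equal).
#' @export
welch_t_test <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least two observations", call. = FALSE)
  ma <- mean(group_a); mb <- mean(group_b)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 && !paired) {
    if (ma == mb) {
      stat <- 0; df <- length(group_a) + length(group_b) - 2; p <- 1
    } else {
      stat <- sign(ma - mb) * Inf
      df <- length(group_a) + length(group_b) - 2; p <- 0
    }
  } else {
    tt <- stats::t.test(group_a, group_b, paired = paired,
                        var.equal = FALSE)
    stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  out <- data.frame(test = if (paired) "paired_t" else "welch_t",
                    statistic = stat, df = df, p_value = p,
                    mean_a = ma, mean_b = mb,
                    direction = sign(ma - mb), stringsAsFactors = FALSE)
  class(out) <- c("test_result", class(out))
  out
}

#' One-way ANOVA with pairwise post hoc comparisons
#'
#' Fits `values ~ group` by `aov` and reports the omnibus F-test plus a
#' pairwise post hoc table — Tukey HSD by default, or Holm-corrected
#' pairwise Welch t-tests.
#'
#' @param values Numeric response.
#' @param group Group labels (>= 2 groups, each with >= 2 values).
#' @param posthoc `"tukey"` or `"holm_welch"`.
#' @return List of class `anova_posthoc`: `test` (one-row
#'   `test_result` with the F statistic), `posthoc` (data.frame:
#'   contrast, estimate, p_adj), `group_means`.
#' @export
one_way_anova_posthoc <- function(values, group,
                                  posthoc = c("tukey", "holm_welch")) {
  posthoc <- match.arg(posthoc)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(group) < 2))
    stop("every group needs at least two observations", call. = FALSE)
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  test <- data.frame(test = "one_way_anova",
                     statistic = tab[["F value"]][1],
                     df = tab[["Df"]][1], df_resid = tab[["Df"]][2],
                     p_value = tab[["Pr(>F)"]][1], stringsAsFactors = FALSE)
  class(test) <- c("test_result", class(test))
  if (posthoc == "tukey") {
    th <- stats::TukeyHSD(fit)$group
    ph <- data.frame(contrast = rownames(th), estimate = th[, "diff"],
                     p_adj = th[, "p adj"], stringsAsFactors = FALSE)
  } else {
    lv <- levels(group)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      tt <- welch_t_test(values[group == pr[2]], values[group == pr[1]])
      data.frame(contrast = paste(pr[2], pr[1], sep = "-"),
                 estimate = tt$mean_a - tt$mean_b, p_raw = tt$p_value,
                 stringsAsFactors = FALSE)
    })
    ph <- do.call(rbind, rows)
    ph$p_adj <- stats::p.adjust(ph$p_raw, method = "holm")
    ph$p_raw <- NULL
  }
  rownames(ph) <- NULL
  structure(list(test = test, posthoc = ph,
                 group_means = tapply(values, group, mean)),
            class = "anova_posthoc")
}

#' @export
print.anova_posthoc <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$test$df, x$test$df_resid, x$test$statistic,
              x$test$p_value))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo power for a two-group mean contrast
#'
#' Simulates `reps` datasets of two normal groups differing by `delta`
#' and reports the fraction rejected by the Welch test at level `alpha`.
#' With `delta = 0` the result estimates the test's size.
#'
#' @param delta True mean difference.
#' @param n Observations per group.
#' @param reps Simulated datasets (>= 1).
#' @param seed Integer seed.
#' @param sd Common group SD.
#' @param alpha Significance level.
#' @return Rejection fraction in \[0, 1\].
#' @export
power_estimate <- function(delta, n, reps = 1000, seed = NULL, sd = 1,
                           alpha = 0.05) {
  stop_if_not_scalar_num_(delta, "delta")
  stop_if_not_scalar_num_(sd, "sd", positive = TRUE)
  if (!is.numeric(reps) || reps < 1) stop("reps must be >= 1",
                                          call. = FALSE)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2 per group",
                                    call. = FALSE)
  with_seed_(seed, {
    rej <- vapply(seq_len(reps), function(i) {
      a <- stats::rnorm(n, 0, sd); b <- stats::rnorm(n, delta, sd)
      welch_t_test(a, b)$p_value < alpha
    }, logical(1))
    mean(rej)
  })
}
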