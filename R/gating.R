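#' Hierarchical gate node
#'
#' A node in a manual gating tree. Each node applies one single-channel
#' predicate (`gt`, `lt` or `between`) and events in a node are those
#' satisfying the conjunction of predicates from the root down. Gating
#' thresholds are fixed numbers; there is no automated valley-finding.
#'
#' @param label Unique node label.
#' @param channel Channel the predicate applies to (`NULL` for a
#'   pass-through root).
#' @param op One of `"gt"`, `"lt"`, `"between"`.
#' @param threshold One finite number for `gt`/`lt`, two (low, high) for
#'   `between`.
#' @param children List of child `gate_node`s.
#' @return An object of class `gate_node`.
#' @examples
#' viable <- gate_node("viable", "PI", "lt", 100,
#'   children = list(gate_node("cd45hi", "CD45", "gt", 2000)))
#' @export
gate_node <- function(label, channel = NULL, op = c("gt", "lt", "between"),
                      threshold = NULL, children = list()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.null(channel)) {
    op <- match.arg(op)
    need <- if (op == "between") 2L else 1L
    if (!is.numeric(threshold) || length(threshold) != need ||
        !all(is.finite(threshold)))
      stop(sprintf("gate '%s': op '%s' needs %d finite threshold(s)",
                   label, op, need), call. = FALSE)
    if (op == "between" && threshold[1] > threshold[2])
      stop(sprintf("gate '%s': between thresholds must be ordered", label),
           call. = FALSE)
  } else {
    op <- NULL; threshold <- NULL
  }
  if (!all(vapply(children, inherits, logical(1), "gate_node")))
    stop("children must be gate_node objects", call. = FALSE)
  structure(list(label = label, channel = channel, op = op,
                 threshold = threshold, children = children),
            class = "gate_node")
}

gate_labels_ <- function(node) {
  c(node$label, unlist(lapply(node$children, gate_labels_)))
}

gate_mask_ <- function(node, events) {
  if (is.null(node$channel)) return(rep(TRUE, nrow(events)))
  if (!node$channel %in% names(events))
    stop(sprintf("gated channel '%s' not present in the event table",
                 node$channel), call. = FALSE)
  x <- events[[node$channel]]
  switch(node$op,
         gt = x > node$threshold,
         lt = x < node$threshold,
         between = x >= node$threshold[1] & x <= node$threshold[2])
}

#' Apply a gate tree to an event table
#'
#' Returns, for every labelled node, the subset of events satisfying all
#' predicates on the path from the root to that node.
#'
#' @param events Event-table data.frame.
#' @param tree Root [gate_node] (conventionally the viability gate).
#' @return Named list of data.frame subsets, one per node label.
#' @export
apply_gates <- function(events, tree) {
  stopifnot(is.data.frame(events), inherits(tree, "gate_node"))
  labs <- gate_labels_(tree)
  if (anyDuplicated(labs))
    stop("duplicate gate labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  out <- list()
  walk <- function(node, mask) {
    mask <- mask & gate_mask_(node, events)
    out[[node$label]] <<- events[mask, , drop = FALSE]
    for (ch in node$children) walk(ch, mask)
  }
  walk(tree, rep(TRUE, nrow(events)))
  out
}

#' Assign each event to its deepest matching leaf gate
#'
#' Events matching no leaf get `NA`. Leaves are visited in tree order and
#' the first match wins (with non-overlapping sibling predicates the
#' assignment is unique).
#'
#' @inheritParams apply_gates
#' @return Character vector of leaf labels, length `nrow(events)`.
#' @export
gate_membership <- function(events, tree) {
  stopifnot(is.data.frame(events), inherits(tree, "gate_node"))
  assigned <- rep(NA_character_, nrow(events))
  walk <- function(node, mask) {
    mask <- mask & gate_mask_(node, events)
    if (!length(node$children)) {
      assigned[mask & is.na(assigned)] <<- node$label
    } else {
      for (ch in node$children) walk(ch, mask)
    }
  }
  walk(tree, rep(TRUE, nrow(events)))
  assigned
}

#' Agreement between gate assignments and simulator truth labels
#'
#' @param events Event table carrying a truth-label column.
#' @param tree Gate tree whose leaves correspond to (possibly merged)
#'   truth labels.
#' @param label_map Named character vector mapping truth labels to leaf
#'   labels; unmapped truth labels map to themselves.
#' @param truth Name of the truth column.
#' @return Fraction of events whose assigned leaf equals the mapped truth
#'   label (unassigned events count as disagreement).
#' @export
gate_recovery <- function(events, tree, label_map = character(),
                          truth = "truth_label") {
  if (!truth %in% names(events))
    stop(sprintf("column '%s' not found", truth), call. = FALSE)
  expected <- events[[truth]]
  hit <- expected %in% names(label_map)
  expected[hit] <- label_map[expected[hit]]
  assigned <- gate_membership(events, tree)
  mean(!is.na(assigned) & assigned == expected)
}

#' Default gate tree for the default synthetic cohort
#'
#' Viable (PI-negative) events split into CD45-high cells — lymphocytes
#' (CD14-low) and monocytes (CD14-high) — and CD45dim blasts gated
#' SSC-low, mirroring the standard CD45/SSC blast gate.
#'
#' @return Root [gate_node].
#' @export
default_gate_tree <- function() {
  gate_node("viable", "PI", "lt", 100, children = list(
    gate_node("cd45hi", "CD45", "gt", 2000, children = list(
      gate_node("lymphocyte", "CD14", "lt", 300),
      gate_node("monocyte", "CD14", "gt", 300))),
    gate_node("cd45dim", "CD45", "between", c(30, 2000), children = list(
      gate_node("blast", "SSC", "lt", 350)))))
}
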