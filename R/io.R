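## Plain-text readers/writers for the pipeline's interchange formats:
## event tables as CSV, read sets as BED6 with a JSON sidecar for library
## sizes, gate trees as YAML or JSON.

#' Write / read an event table as CSV
#'
#' One header row of channel names; the simulator's `truth_label` column
#' travels with the data.
#'
#' @param events Event-table data.frame.
#' @param path File path.
#' @return `read_event_table` returns the data.frame;
#'   `write_event_table` returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  stopifnot(is.data.frame(events))
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read aligned reads as BED6 plus a JSON sidecar
#'
#' Reads are stored 0-based half-open (BED convention) and converted to
#' the package's 1-based inclusive coordinates on read. The sidecar JSON
#' carries sample id, group and total library size.
#'
#' @param read_set A [read_alignment_set].
#' @param bed_path BED6 output path; the sidecar is written next to it
#'   as `<bed_path>.json` unless `json_path` is given.
#' @param json_path Optional sidecar path.
#' @return `read_reads_bed` returns a [read_alignment_set];
#'   `write_reads_bed` returns `bed_path` invisibly.
#' @export
write_reads_bed <- function(read_set, bed_path, json_path = NULL) {
  stopifnot(inherits(read_set, "read_alignment_set"))
  if (is.null(json_path)) json_path <- paste0(bed_path, ".json")
  df <- read_set$reads
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = sprintf("read_%d", seq_len(nrow(df))),
                    score = rep(0L, nrow(df)),
                    strand = rep(".", nrow(df)))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(sample = read_set$sample,
                            group = read_set$group,
                            total_reads = read_set$total_reads),
                       json_path, auto_unbox = TRUE)
  invisible(bed_path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(bed_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- paste0(bed_path, ".json")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  bed <- tryCatch(
    utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) NULL)
  reads <- if (is.null(bed) || !nrow(bed)) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  } else {
    data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
               stringsAsFactors = FALSE)
  }
  read_alignment_set(reads, meta$total_reads, meta$sample,
                     if (is.null(meta$group)) NA else meta$group)
}

gate_from_list_ <- function(x) {
  gate_node(label = x$label, channel = x$channel,
            op = if (is.null(x$op)) "gt" else x$op,
            threshold = if (is.null(x$threshold)) NULL
                        else as.numeric(unlist(x$threshold)),
            children = lapply(x$children, gate_from_list_))
}

gate_to_list_ <- function(node) {
  out <- list(label = node$label)
  if (!is.null(node$channel)) {
    out$channel <- node$channel
    out$op <- node$op
    out$threshold <- node$threshold
  }
  if (length(node$children))
    out$children <- lapply(node$children, gate_to_list_)
  out
}

#' Read / write a gate tree as YAML or JSON
#'
#' Each node is a mapping with `label`, optional `channel`/`op`/
#' `threshold`, and a `children` list. Format follows the file
#' extension (`.json` = JSON, anything else YAML).
#'
#' @param path File path.
#' @param tree Root [gate_node].
#' @return `read_gate_tree` returns a [gate_node]; `write_gate_tree`
#'   returns `path` invisibly.
#' @export
read_gate_tree <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  gate_from_list_(x)
}

#' @rdname read_gate_tree
#' @export
write_gate_tree <- function(tree, path) {
  stopifnot(inherits(tree, "gate_node"))
  x <- gate_to_list_(tree)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}
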