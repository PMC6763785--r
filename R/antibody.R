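#' Antibody binding model
#'
#' Describes how one antibody binds the two surface forms of CD300f: the
#' canonical form lacking the exon-4 insert (`C`) and the splice form
#' carrying the Ser/Thr-rich exon-4 insert (`SI4`). Epitope accessibility
#' is the fraction of surface copies of each isoform whose epitope the
#' antibody can reach, so the expected specific signal per cell is
#' `gain * (n_C * acc_C + n_SI4 * acc_SI4)`.
#'
#' Cross-blocking behaviour is captured by `overlap`: a named list giving,
#' for each *test* antibody, the directional epitope-overlap fraction
#' omega in \[0, 1\] — the fraction of the test antibody's accessible
#' epitopes occluded when this antibody saturates the cell first.
#' Conformational enhancement (the DCR-2 to UP-D2 effect, where binding of
#' one antibody exposes another's epitope) is captured by `enhancer_of`:
#' per-isoform multiplicative factors `c(e_C, e_SI4)` (each >= 1) applied
#' to the test antibody's accessibility while this antibody is bound.
#'
#' @param name Antibody identifier; also used as the detector channel name.
#' @param acc_C,acc_SI4 Epitope accessibility on each isoform, in \[0, 1\].
#' @param is_isotype Logical; isotype controls must have zero accessibility
#'   on both isoforms (they measure background only).
#' @param overlap Named list, test-antibody name -> overlap fraction in
#'   \[0, 1\].
#' @param enhancer_of Named list, test-antibody name -> numeric
#'   `c(e_C, e_SI4)` with both factors >= 1.
#' @return An object of class `antibody_model`.
#' @examples
#' dcr2 <- antibody_model("DCR-2", acc_C = 0.8, acc_SI4 = 0.9,
#'                        overlap = list("UP-D2" = 0),
#'                        enhancer_of = list("UP-D2" = c(1, 3)))
#' @export
antibody_model <- function(name, acc_C, acc_SI4, is_isotype = FALSE,
                           overlap = list(), enhancer_of = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stop_if_not_scalar_num_(acc_C, "acc_C")
  stop_if_not_scalar_num_(acc_SI4, "acc_SI4")
  if (acc_C < 0 || acc_C > 1 || acc_SI4 < 0 || acc_SI4 > 1)
    stop("accessibilities must lie in [0, 1]", call. = FALSE)
  if (is_isotype && (acc_C != 0 || acc_SI4 != 0))
    stop("an isotype control must have zero accessibility on both isoforms",
         call. = FALSE)
  for (w in overlap) {
    if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1)
      stop("overlap fractions must be single numbers in [0, 1]", call. = FALSE)
  }
  for (e in enhancer_of) {
    if (!is.numeric(e) || length(e) != 2L || any(e < 1))
      stop("enhancement factors must be c(e_C, e_SI4) with both >= 1",
           call. = FALSE)
  }
  structure(
    list(name = name, acc_C = acc_C, acc_SI4 = acc_SI4,
         is_isotype = is_isotype, overlap = overlap,
         enhancer_of = enhancer_of),
    class = "antibody_model"
  )
}

#' @export
print.antibody_model <- function(x, ...) {
  cat(sprintf("<antibody_model> %s%s  acc_C=%.3g acc_SI4=%.3g\n",
              x$name, if (x$is_isotype) " (isotype)" else "",
              x$acc_C, x$acc_SI4))
  if (length(x$overlap))
    cat("  overlap ->", paste(sprintf("%s:%.2f", names(x$overlap),
                                      unlist(x$overlap)), collapse = ", "), "\n")
  if (length(x$enhancer_of))
    cat("  enhances ->", paste(names(x$enhancer_of), collapse = ", "), "\n")
  invisible(x)
}

# Directional overlap fraction primary -> test. A self pair is a complete
# block by definition; any other undefined pair is an error (the model
# must be explicit about epitope relationships it claims to simulate).
overlap_fraction_ <- function(primary, test) {
  if (identical(primary$name, test$name)) return(1)
  w <- primary$overlap[[test$name]]
  if (is.null(w))
    stop(sprintf("overlap %s -> %s is not defined in the antibody model",
                 primary$name, test$name), call. = FALSE)
  w
}

enhancement_factors_ <- function(primary, test) {
  e <- primary$enhancer_of[[test$name]]
  if (is.null(e)) c(1, 1) else e
}

#' Default CD300f antibody panel
#'
#' Five CD300f antibodies plus one isotype control, parameterised to
#' reproduce the qualitative epitope map of the panel: four distinct
#' epitopes (UP-D1; the shared DCR-2/234903 epitope; UP-D2; CLM-1), no
#' complete cross-block between different epitopes, UP-D1 preferring the
#' SI4 splice form about three-fold, and DCR-2 conformationally enhancing
#' UP-D2 binding on SI4-bearing cells.
#'
#' @param e_C,e_SI4 Per-isoform DCR-2 -> UP-D2 enhancement factors. The
#'   default models the enhancement as specific to the exon-4 splice form.
#' @return Named list of [antibody_model] objects.
#' @export
default_antibody_panel <- function(e_C = 1, e_SI4 = 3) {
  others <- function(self) setdiff(
    c("UP-D1", "DCR-2", "Ab234903", "UP-D2", "CLM-1"), self)
  zero_overlap <- function(self) {
    w <- as.list(rep(0, length(others(self))))
    names(w) <- others(self)
    w
  }
  upd1 <- antibody_model("UP-D1", acc_C = 0.3, acc_SI4 = 0.9,
                         overlap = zero_overlap("UP-D1"))
  dcr2_ov <- zero_overlap("DCR-2"); dcr2_ov[["Ab234903"]] <- 0.85
  dcr2 <- antibody_model("DCR-2", acc_C = 0.8, acc_SI4 = 0.9,
                         overlap = dcr2_ov,
                         enhancer_of = list("UP-D2" = c(e_C, e_SI4)))
  ab234903_ov <- zero_overlap("Ab234903"); ab234903_ov[["DCR-2"]] <- 0.85
  ab234903 <- antibody_model("Ab234903", acc_C = 0.75, acc_SI4 = 0.85,
                             overlap = ab234903_ov)
  upd2 <- antibody_model("UP-D2", acc_C = 0.7, acc_SI4 = 0.8,
                         overlap = zero_overlap("UP-D2"))
  clm1 <- antibody_model("CLM-1", acc_C = 0.6, acc_SI4 = 0.5,
                         overlap = zero_overlap("CLM-1"))
  iso <- antibody_model("IgG1", acc_C = 0, acc_SI4 = 0, is_isotype = TRUE)
  list("UP-D1" = upd1, "DCR-2" = dcr2, "Ab234903" = ab234903,
       "UP-D2" = upd2, "CLM-1" = clm1, "IgG1" = iso)
}

panel_isotype_ <- function(panel) {
  iso <- Filter(function(a) isTRUE(a$is_isotype), panel)
  if (!length(iso))
    stop("panel must contain at least one isotype control", call. = FALSE)
  iso[[1L]]
}
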