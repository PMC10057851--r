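#' Confusion counts against a validation set
#'
#' @param reported character vector of reported target accessions.
#' @param validation character vector: the positive set.
#' @return named integer vector `c(tp, fp, fn)`: reported-and-validated,
#'   reported-not-validated, validated-not-reported.
#' @export
confusion_counts <- function(reported, validation) {
  if (length(validation) == 0L) stop_param("empty validation set")
  reported <- unique(reported)
  validation <- unique(validation)
  c(tp = length(intersect(reported, validation)),
    fp = length(setdiff(reported, validation)),
    fn = length(setdiff(validation, reported)))
}

#' Precision, recall and F1 from confusion counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2*recall*precision/(recall+precision)`; any metric with a zero
#' denominator is 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return one-row data.frame with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * recall * precision / (recall + precision) else 0
  data.frame(tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a reported protein list
#'
#' Convenience wrapper: confusion counts then metrics.
#'
#' @param reported reported target accessions.
#' @param validation positive accession set.
#' @return one-row metrics data.frame.
#' @export
evaluate_report <- function(reported, validation) {
  cc <- confusion_counts(reported, validation)
  precision_recall_f1(cc[["tp"]], cc[["fp"]], cc[["fn"]])
}

#' Assemble a spectral-count matrix across samples
#'
#' Counts, per sample, the PSMs whose peptide maps to each reported
#' protein. The row space is the union of the per-sample reported lists;
#' a protein unreported in a sample gets 0 there. With
#' `counting = "all"`, an ambiguous PSM contributes one count to every
#' reported protein it maps to; with `"unique"`, only PSMs mapping to a
#' single protein are counted.
#'
#' @param psms_by_sample named list: sample -> PSM data.frame.
#' @param reported_by_sample named list: sample -> reported accessions
#'   (same names as `psms_by_sample`).
#' @param counting `"all"` or `"unique"`.
#' @return integer matrix, proteins x samples.
#' @export
spectral_counts <- function(psms_by_sample, reported_by_sample,
                            counting = c("all", "unique")) {
  counting <- match.arg(counting)
  stopifnot(identical(names(psms_by_sample), names(reported_by_sample)))
  samples <- names(psms_by_sample)
  rows <- sort(unique(unlist(reported_by_sample, use.names = FALSE)))
  mat <- matrix(0L, nrow = length(rows), ncol = length(samples),
                dimnames = list(rows, samples))
  for (s in samples) {
    psms <- psms_by_sample[[s]]
    reported <- reported_by_sample[[s]]
    if (nrow(psms) == 0L || length(reported) == 0L) next
    ids <- psms$protein_ids
    if (counting == "unique") ids <- ids[lengths(ids) == 1L]
    hits <- unlist(lapply(ids, intersect, y = reported), use.names = FALSE)
    if (length(hits) == 0L) next
    tab <- table(hits)
    mat[names(tab), s] <- mat[names(tab), s] + as.integer(tab)
  }
  mat
}

#' Sweep PSM-filtering thresholds and reporting FDRs
#'
#' Runs the full pipeline once per combination of PEP filtering threshold
#' and reporting FDR, evaluating each reported list against a validation
#' set. The default grids are the canonical operating-point scans:
#' thresholds 0.01–0.999 and FDRs 0.005–0.05.
#'
#' @param psms PSM data.frame.
#' @param proteome proteome data.frame.
#' @param complexes optional complex list (enables rescue).
#' @param validation positive accession set.
#' @param thresholds PEP filtering grid.
#' @param fdrs reporting FDR grid.
#' @param ... passed to [accpep()].
#' @return data.frame with one row per (threshold, fdr): reported count,
#'   tp, fp, fn, precision, recall, f1.
#' @export
sweep_pep_thresholds <- function(psms, proteome, complexes = NULL,
                                 validation,
                                 thresholds = c(0.01, 0.05, 0.1, 0.25,
                                                0.5, 0.75, 0.999),
                                 fdrs = c(0.005, 0.01, 0.025, 0.05),
                                 ...) {
  stopifnot(length(thresholds) > 0L, length(fdrs) > 0L)
  rows <- list()
  for (th in thresholds) {
    for (f in fdrs) {
      fit <- accpep(psms, proteome, complexes, pep_max = th, fdr = f, ...)
      reported <- report_at_fdr(fit, f)
      m <- evaluate_report(reported, validation)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(pep_threshold = th, fdr = f,
                         reported = length(reported)), m)
    }
  }
  do.call(rbind, rows)
}
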