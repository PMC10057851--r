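#' Protein inference from scored PSMs
#'
#' The package's main driver. Filters PSMs by posterior error probability,
#' collapses them to peptides, builds the peptide-protein bipartite map,
#' scores every candidate protein by length-adjusted error accumulation
#' with target-decoy q-values, and — when a complex catalogue is supplied —
#' rescues weakly supported proteins by propagating posteriors through
#' protein-complex membership.
#'
#' @param psms a PSM data.frame (see [read_psm_table()]) or a path to a
#'   PSM table.
#' @param proteome a proteome data.frame (see [read_fasta()]) or a path to
#'   a target-decoy FASTA.
#' @param complexes optional list of protein complexes (see
#'   [read_complexes()]) or a path to a complex TSV; members are matched
#'   to FASTA accessions through [accession_index()].
#' @param pep_max PSM retention threshold (default 0.999 keeps almost all
#'   PSMs; the scoring rule, not early filtering, handles noise).
#' @param fdr working FDR threshold used by the rescue stopping rule and
#'   by [report_at_fdr()] defaults.
#' @param rescue run complex rescue (default: whenever complexes are
#'   given).
#' @param aggregator complex posterior aggregator, `"max"` or `"mean"`.
#' @param decoy_prefix accession prefix tagging decoys.
#' @param min_complex_size drop complexes with fewer members.
#' @param max_iters rescue iteration cap.
#' @param contaminant_tags passed to [read_fasta()] when `proteome` is a
#'   path.
#' @return an object of class `accpep`: a list with `proteins` (ranked
#'   protein table with accPEP, confidence score, posterior, q-value and
#'   rescue flag), `params`, and `rescue` (iteration trace or NULL).
#' @examples
#' sim <- simulate_dataset(seed = 7)
#' fit <- accpep(sim$psms, sim$proteome, sim$complexes)
#' fit
#' head(report_at_fdr(fit, 0.01))
#' @export
accpep <- function(psms, proteome, complexes = NULL,
                   pep_max = 0.999, fdr = 0.01,
                   rescue = !is.null(complexes),
                   aggregator = c("max", "mean"),
                   decoy_prefix = "DECOY_",
                   min_complex_size = 1L, max_iters = 100L,
                   contaminant_tags = c("cRAP", "CONTAM")) {
  aggregator <- match.arg(aggregator)
  if (is.character(psms)) psms <- read_psm_table(psms)
  if (is.character(proteome))
    proteome <- read_fasta(proteome, decoy_prefix, contaminant_tags)
  if (is.character(complexes)) complexes <- read_complexes(complexes)

  kept <- filter_psms(psms, pep_max)
  peptides <- collapse_to_peptides(kept)
  bip <- build_bipartite(peptides, proteome)
  proteins <- infer_proteins(bip, proteome)

  rescue_state <- NULL
  if (rescue && length(complexes %||% list()) > 0L) {
    idx <- accession_index(proteome$accession, decoy_prefix)
    complexes <- lapply(complexes, function(cx) {
      hit <- idx[cx$members]
      cx$members <- unique(hit[!is.na(hit)])
      cx
    })
    complexes <- Filter(function(cx) length(cx$members) > 0L, complexes)
    rescue_state <- iterate_rescue(proteins, complexes, f = fdr,
                                   aggregator = aggregator,
                                   decoy_prefix = decoy_prefix,
                                   min_complex_size = min_complex_size,
                                   max_iters = max_iters)
    proteins <- rescue_state$proteins
    rescue_state$proteins <- NULL
  }

  structure(
    list(
      proteins = proteins,
      params = list(pep_max = pep_max, fdr = fdr, rescue = rescue,
                    aggregator = aggregator, decoy_prefix = decoy_prefix,
                    min_complex_size = min_complex_size,
                    max_iters = max_iters,
                    n_psms_in = nrow(psms), n_psms_kept = nrow(kept),
                    n_peptides = nrow(bip$peptides)),
      rescue = rescue_state
    ),
    class = "accpep"
  )
}

#' @export
print.accpep <- function(x, ...) {
  p <- x$proteins
  cat("Protein inference by accumulated PEP\n")
  cat(sprintf("  PSMs: %d kept of %d (PEP <= %g); peptides: %d\n",
              x$params$n_psms_kept, x$params$n_psms_in, x$params$pep_max,
              x$params$n_peptides))
  cat(sprintf("  candidates scored: %d (%d targets, %d decoys, %d contaminants)\n",
              nrow(p), sum(!p$is_decoy & !p$is_contaminant),
              sum(p$is_decoy), sum(p$is_contaminant)))
  if (!is.null(x$rescue))
    cat(sprintf("  complex rescue: %d iteration(s), %d protein(s) rescued\n",
                x$rescue$iterations, sum(p$rescued)))
  cat(sprintf("  targets reported at FDR %g: %d\n", x$params$fdr,
              length(report_at_fdr(x, x$params$fdr))))
  invisible(x)
}

#' @export
summary.accpep <- function(object, fdr_grid = c(0.005, 0.01, 0.025, 0.05),
                           ...) {
  counts <- vapply(fdr_grid, function(f)
    length(report_at_fdr(object, f)), 0L)
  out <- list(params = object$params,
              reported = data.frame(fdr = fdr_grid, n_targets = counts),
              top = utils::head(object$proteins, 10L))
  class(out) <- "summary.accpep"
  out
}

#' @export
print.summary.accpep <- function(x, ...) {
  cat("Targets reported per FDR threshold:\n")
  print(x$reported, row.names = FALSE)
  cat("\nTop of the ranking:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.accpep <- function(x, ...) x$proteins

#' Score-distribution plot of an inference result
#'
#' Overlays the confidence-score distributions of targets and decoys and
#' marks the score cutoff implied by the working FDR — the standard visual
#' check that decoys model the null score distribution.
#'
#' @param x an `accpep` object.
#' @param fdr FDR threshold to mark (default: the fit's working FDR).
#' @param ... passed to [graphics::hist()].
#' @export
plot.accpep <- function(x, fdr = x$params$fdr, ...) {
  p <- x$proteins[!x$proteins$is_contaminant, ]
  brk <- pretty(range(p$score), n = 40)
  ht <- graphics::hist(p$score[!p$is_decoy], breaks = brk, plot = FALSE)
  hd <- graphics::hist(p$score[p$is_decoy], breaks = brk, plot = FALSE)
  ylim <- c(0, max(ht$counts, hd$counts))
  graphics::plot(ht, col = grDevices::adjustcolor("steelblue", 0.6),
                 border = NA, ylim = ylim, xlab = "confidence score (dB)",
                 main = "target vs decoy confidence scores", ...)
  graphics::plot(hd, col = grDevices::adjustcolor("firebrick", 0.6),
                 border = NA, add = TRUE)
  rep_acc <- report_at_fdr(x, fdr)
  if (length(rep_acc)) {
    cut <- min(p$score[p$accession %in% rep_acc])
    graphics::abline(v = cut, lty = 2)
    graphics::mtext(sprintf("FDR %g cutoff", fdr), at = cut, cex = 0.8)
  }
  graphics::legend("topright", fill = c("steelblue", "firebrick"),
                   legend = c("targets", "decoys"), bty = "n")
  invisible(x)
}
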