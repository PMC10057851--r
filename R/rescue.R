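#' Build decoy complexes
#'
#' For every curated (target) complex, constructs a decoy twin whose
#' members are the decoy counterparts of the target members. Scoring
#' decoy proteins through decoy complexes mirrors the rescue of targets
#' through real complexes, which keeps the target-decoy FDR estimate
#' unbiased after rescue.
#'
#' @param complexes list of target complexes from [read_complexes()].
#' @param decoy_prefix prefix producing decoy accessions.
#' @return list of length `2 * length(complexes)`: the originals followed
#'   by their decoy twins (ids suffixed `"_decoy"`).
#' @export
build_decoy_complexes <- function(complexes, decoy_prefix = "DECOY_") {
  stopifnot(all(!vapply(complexes, `[[`, TRUE, "is_decoy")))
  twins <- lapply(complexes, function(cx) {
    list(complex_id = paste0(cx$complex_id, "_decoy"),
         members = paste0(decoy_prefix, cx$members),
         is_decoy = TRUE)
  })
  c(complexes, twins)
}

#' Posterior probability that a complex is present
#'
#' Aggregates the posteriors of the complex members that appear in the
#' scored candidate list (members with no score contribute nothing); the
#' default aggregator is the maximum — a complex is at least as likely to
#' be present as its most confidently identified member. An empty
#' intersection yields 0.
#'
#' @param complex one complex (list with `members`).
#' @param posteriors named numeric vector: accession -> posterior
#'   `p = 1 - accPEP`.
#' @param aggregator `"max"` (default) or `"mean"`.
#' @return probability in \[0, 1\].
#' @export
complex_posterior <- function(complex, posteriors,
                              aggregator = c("max", "mean")) {
  aggregator <- match.arg(aggregator)
  p <- posteriors[intersect(complex$members, names(posteriors))]
  if (length(p) == 0L) return(0)
  if (aggregator == "max") max(p) else mean(p)
}

#' Complex-derived posterior of a protein
#'
#' The maximum posterior over the complexes that contain the protein, or
#' 0 if none does. A protein draws only from complexes of its own decoy
#' class: targets from curated complexes, decoys from decoy twins.
#'
#' @param accession protein accession.
#' @param is_decoy whether the protein is a decoy.
#' @param complexes full complex list (targets + decoy twins).
#' @param complex_posteriors named numeric vector keyed by `complex_id`.
#' @return probability in \[0, 1\].
#' @export
protein_complex_posterior <- function(accession, is_decoy, complexes,
                                      complex_posteriors) {
  p <- 0
  for (cx in complexes) {
    if (cx$is_decoy != is_decoy) next
    if (accession %in% cx$members) {
      pc <- complex_posteriors[[cx$complex_id]]
      if (pc > p) p <- pc
    }
  }
  p
}

# vectorized form used by the iteration: one pass over complexes instead
# of one pass per protein
all_protein_complex_posteriors <- function(proteins, complexes,
                                           complex_posteriors) {
  p_cpx <- numeric(nrow(proteins))
  names(p_cpx) <- proteins$accession
  for (cx in complexes) {
    pc <- complex_posteriors[[cx$complex_id]]
    if (pc <= 0) next
    hit <- match(cx$members, proteins$accession)
    hit <- hit[!is.na(hit)]
    hit <- hit[proteins$is_decoy[hit] == cx$is_decoy]
    sel <- hit[p_cpx[hit] < pc]
    p_cpx[sel] <- pc
  }
  p_cpx
}

#' Apply one rescue update to a protein table
#'
#' Raises each protein's posterior to the maximum of its current value
#' and its complex-derived posterior, recomputes accPEP, confidence
#' scores and q-values, and flags proteins whose posterior strictly
#' increased as rescued.
#'
#' @param proteins ranked protein data.frame (with `posterior`, `score`,
#'   `q_value`).
#' @param p_cpx named numeric vector of complex-derived posteriors keyed
#'   by accession (missing accessions are treated as 0).
#' @return updated ranked data.frame.
#' @export
rescue_update <- function(proteins, p_cpx) {
  stopifnot(is_prob(unname(p_cpx)))
  p0 <- proteins$posterior
  pc <- p_cpx[proteins$accession]
  pc[is.na(pc)] <- 0
  p1 <- pmax(p0, pc)
  proteins$rescued <- proteins$rescued | p1 > p0
  proteins$posterior <- p1
  proteins$acc_pep <- 1 - p1
  proteins$score <- confidence_score(proteins$acc_pep)
  rank_and_qvalues(proteins[setdiff(names(proteins), "q_value")])
}

#' Iterate complex rescue to convergence
#'
#' Alternates complex inference and protein rescoring: from the current
#' protein posteriors compute each complex's posterior, propagate the
#' best complex posterior back to every member, raise protein posteriors
#' by `max`, recompute q-values, and count the targets reported at the
#' working FDR. The loop re-enters while any posterior changed and stops
#' at the propagation fixpoint (posteriors are monotone non-decreasing
#' over a finite value set, so the fixpoint is reached in finitely many
#' rounds; at the fixpoint the reported count has necessarily stopped
#' increasing as well, so this subsumes a stop-at-first-non-increase
#' rule while also propagating rescues that chain across overlapping
#' complexes). `max_iters` caps pathological inputs.
#'
#' @param proteins ranked protein data.frame from [infer_proteins()].
#' @param complexes target complexes; decoy twins are added internally.
#' @param f working FDR threshold.
#' @param aggregator complex aggregator, `"max"` or `"mean"`.
#' @param decoy_prefix decoy accession prefix.
#' @param min_complex_size drop complexes with fewer members (default 1:
#'   use every curated complex).
#' @param max_iters iteration cap.
#' @return list with `proteins` (final ranked table), `reported_counts`
#'   (targets reported at `f` per state: initial then after each
#'   iteration), `iterations`, and `converged`.
#' @export
iterate_rescue <- function(proteins, complexes, f = 0.01,
                           aggregator = c("max", "mean"),
                           decoy_prefix = "DECOY_",
                           min_complex_size = 1L, max_iters = 100L) {
  aggregator <- match.arg(aggregator)
  if (max_iters < 1L) stop_param("max_iters must be >= 1")
  complexes <- Filter(function(cx) length(cx$members) >= min_complex_size,
                      complexes)
  all_cx <- build_decoy_complexes(complexes, decoy_prefix)
  counts <- length(report_at_fdr(proteins, f))
  it <- 0L
  converged <- FALSE
  while (!converged && it < max_iters) {
    it <- it + 1L
    posteriors <- stats::setNames(proteins$posterior, proteins$accession)
    cx_post <- vapply(all_cx, complex_posterior, 0,
                      posteriors = posteriors, aggregator = aggregator)
    names(cx_post) <- vapply(all_cx, `[[`, "", "complex_id")
    p_cpx <- all_protein_complex_posteriors(proteins, all_cx, cx_post)
    updated <- rescue_update(proteins, p_cpx)
    changed <- !isTRUE(all.equal(
      updated$posterior[order(updated$accession)],
      proteins$posterior[order(proteins$accession)], tolerance = 0))
    proteins <- updated
    counts <- c(counts, length(report_at_fdr(proteins, f)))
    if (!changed) converged <- TRUE
  }
  if (!converged)
    warning("complex rescue did not converge within ", max_iters,
            " iterations")
  list(proteins = proteins, reported_counts = counts,
       iterations = it, converged = converged)
}
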