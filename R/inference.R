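#' Length share of an ambiguous peptide
#'
#' An ambiguous peptide is apportioned among its N candidate proteins in
#' proportion to the reciprocal of their lengths: longer proteins are more
#' likely to generate spurious matches, so they receive a smaller share of
#' the peptide's support. Writing T for the summed candidate lengths, the
#' share of candidate h is
#' \deqn{\phi_h = \frac{T / len_h}{\sum_i T / len_i}
#'             = \frac{1/len_h}{\sum_i 1/len_i},}
#' so the shares of all candidates sum to 1 and equal-length candidates
#' each receive 1/N.
#'
#' @param candidate_lengths positive integer residue counts, one per
#'   candidate protein of the peptide.
#' @param index_of_target which candidate's share to return; omit to get
#'   the full share vector.
#' @return share(s) in (0, 1].
#' @export
length_share <- function(candidate_lengths, index_of_target = NULL) {
  if (length(candidate_lengths) == 0L)
    stop_param("length_share: empty candidate list")
  if (any(candidate_lengths < 1)) stop_param("protein lengths must be >= 1")
  inv <- 1 / candidate_lengths
  phi <- inv / sum(inv)
  if (is.null(index_of_target)) phi else phi[[index_of_target]]
}

#' Error of a peptide supporting one protein
#'
#' The probability that using the peptide to support the protein is wrong.
#' For a unique peptide this is its PEP. For an ambiguous peptide it is
#' the chance the identification is wrong plus the chance it is right but
#' originates from another candidate, i.e. `1 - (1 - pep) * phi` where
#' `phi` is the protein's length share. At phi = 1 the two branches agree.
#'
#' @param pep posterior error probability of the peptide.
#' @param is_unique logical.
#' @param phi length share; required when ambiguous.
#' @return error probability in \[0, 1\] (vectorized).
#' @export
peptide_support_error <- function(pep, is_unique, phi = 1) {
  stopifnot(is_prob(pep))
  ifelse(is_unique, pep, 1 - (1 - pep) * phi)
}

#' Accumulated PEP of a protein
#'
#' The probability that a protein is a false report given its supporting
#' peptides, assuming peptides support it independently: the product of
#' the per-peptide support errors. The product is accumulated in log
#' space (hundreds of small factors underflow doubles); an exact zero
#' factor short-circuits to zero via `log(0) = -Inf`.
#'
#' @param errors per-peptide support errors, each in \[0, 1\], non-empty.
#' @return accumulated error probability.
#' @export
protein_accpep <- function(errors) {
  if (length(errors) == 0L)
    stop_param("protein_accpep: a candidate protein always has >= 1 peptide")
  stopifnot(is_prob(errors))
  exp(sum(log(errors)))
}

#' Deciban confidence score
#'
#' `S = -10 * log10(accPEP + 1e-14)`; the spike keeps the score finite
#' (S = 140) when the accumulated error is exactly zero.
#'
#' @param acc_pep accumulated error probability (vectorized).
#' @return confidence score in decibans.
#' @export
confidence_score <- function(acc_pep) {
  -10 * log10(acc_pep + ACCPEP_SPIKE)
}

#' Rank proteins and compute target-decoy q-values
#'
#' Proteins are ranked by confidence score descending (at ties, decoys are
#' printed before targets; q-values are tie-invariant because the FDR
#' threshold is inclusive). The FDR at threshold x is
#' \deqn{FDR(x) = \frac{|\{decoys: S \ge x\}| + 1}{|\{targets: S \ge x\}| + 1},}
#' clamped at 1. The q-value of the bottom-ranked protein is the FDR at
#' its score; walking up the ranking each q-value is the minimum of the
#' FDR at that score and the q-value below, so q-values are non-increasing
#' with score. Contaminants are flagged entries counted in neither the
#' decoy nor the target tally.
#'
#' @param scores data.frame with at least `accession`, `score`, `is_decoy`
#'   and optionally `is_contaminant`.
#' @return the data.frame in rank order with a `q_value` column.
#' @export
rank_and_qvalues <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("accession", "score", "is_decoy") %in% names(scores)))
  if (is.null(scores$is_contaminant)) scores$is_contaminant <- FALSE
  if (!any(!scores$is_decoy & !scores$is_contaminant))
    stop_param("no target proteins: FDR is undefined")
  ord <- order(-scores$score, !scores$is_decoy)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  n_decoy <- cumsum(scores$is_decoy & !scores$is_contaminant)
  n_target <- cumsum(!scores$is_decoy & !scores$is_contaminant)
  # inclusive >= threshold: at tied scores every tied entry sees the
  # counts at the bottom of its tie group
  group_end <- stats::ave(seq_len(nrow(scores)), scores$score, FUN = max)
  fdr <- pmin(1, (n_decoy[group_end] + 1) / (n_target[group_end] + 1))
  scores$q_value <- rev(cummin(rev(fdr)))
  scores
}

#' Score every candidate protein from a bipartite map
#'
#' For each protein with at least one supporting peptide, computes the
#' per-peptide support errors (ambiguous peptides apportioned by length
#' share over the peptide's full candidate list), accumulates them into
#' accPEP, transforms to a confidence score and posterior
#' `p = 1 - accPEP`, then ranks all candidates and assigns target-decoy
#' q-values. Decoy proteins are scored by the identical rule so that the
#' decoy score distribution remains a fair model of false targets.
#'
#' @param bipartite list from [build_bipartite()].
#' @param proteome data.frame from [read_fasta()].
#' @return data.frame of ranked protein scores (one row per candidate
#'   protein).
#' @export
infer_proteins <- function(bipartite, proteome) {
  peptides <- bipartite$peptides
  # one long row per (peptide, candidate) edge
  pep_idx <- rep(seq_len(nrow(peptides)), peptides$n_candidates)
  acc <- unlist(peptides$candidates, use.names = FALSE)
  phi <- unlist(lapply(seq_len(nrow(peptides)), function(j) {
    ls <- proteome[peptides$candidates[[j]], "length"]
    if (length(ls) == 1L) 1 else length_share(ls)
  }), use.names = FALSE)
  err <- peptide_support_error(peptides$pep[pep_idx],
                               peptides$is_unique[pep_idx], phi)
  log_err <- log(err)
  by_prot <- rowsum(log_err, acc)
  acc_pep <- exp(by_prot[, 1L])
  n_pep <- rowsum(rep(1L, length(acc)), acc)[, 1L]
  n_unique <- rowsum(as.integer(peptides$is_unique[pep_idx]), acc)[, 1L]
  accs <- rownames(by_prot)
  out <- data.frame(
    accession = accs,
    n_peptides = as.integer(n_pep),
    n_unique_peptides = as.integer(n_unique),
    acc_pep = unname(acc_pep),
    score = confidence_score(unname(acc_pep)),
    posterior = 1 - unname(acc_pep),
    is_decoy = proteome[accs, "is_decoy"],
    is_contaminant = proteome[accs, "is_contaminant"],
    rescued = FALSE,
    row.names = NULL
  )
  rank_and_qvalues(out)
}

#' Report target proteins at an FDR threshold
#'
#' @param result an `accpep` object or a ranked protein data.frame with
#'   q-values.
#' @param f FDR threshold in (0, 1].
#' @return character vector of non-decoy, non-contaminant accessions with
#'   q-value <= f, in rank order.
#' @export
report_at_fdr <- function(result, f = 0.01) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop_param("FDR threshold must be in (0, 1]")
  tab <- if (inherits(result, "accpep")) result$proteins else result
  tab$accession[!tab$is_decoy & !tab$is_contaminant & tab$q_value <= f]
}
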