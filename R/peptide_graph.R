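#' Filter PSMs by posterior error probability
#'
#' Drops PSMs whose PEP exceeds `pep_max`. The default operating point
#' keeps almost everything (PEP <= 0.999): downstream scoring is designed
#' to tolerate low-confidence peptides, and dropping them early discards
#' signal that complex-based rescue could otherwise use.
#'
#' @param psms data.frame as returned by [read_psm_table()].
#' @param pep_max retention threshold in (0, 1].
#' @return the retained rows, original order preserved.
#' @export
filter_psms <- function(psms, pep_max = 0.999) {
  if (!is.numeric(pep_max) || length(pep_max) != 1L ||
      is.na(pep_max) || pep_max <= 0 || pep_max > 1)
    stop_param("pep_max must be a probability in (0, 1], got %s",
               format(pep_max))
  psms[psms$pep <= pep_max, , drop = FALSE]
}

#' Collapse PSMs to peptide evidence
#'
#' Aggregates PSMs sharing a normalized peptide string into one evidence
#' record: the peptide's PEP is the minimum (best observation) over its
#' PSMs, and its provisional candidate set is the union of the mapped
#' protein ids.
#'
#' @param psms data.frame of PSMs.
#' @return data.frame with columns `peptide`, `pep`, `n_psms` and list
#'   column `candidates`.
#' @export
collapse_to_peptides <- function(psms) {
  if (nrow(psms) == 0L)
    return(data.frame(peptide = character(), pep = numeric(),
                      n_psms = integer(), candidates = I(list())))
  grp <- split(seq_len(nrow(psms)), psms$peptide)
  # split() sorts keys; keep first-appearance order
  grp <- grp[order(vapply(grp, `[[`, 1L, 1L))]
  data.frame(
    peptide = names(grp),
    pep = vapply(grp, function(i) min(psms$pep[i]), 0),
    n_psms = lengths(grp),
    candidates = I(lapply(grp, function(i)
      unique(unlist(psms$protein_ids[i], use.names = FALSE)))),
    row.names = NULL
  )
}

#' Build the peptide-protein bipartite map
#'
#' Restricts each peptide's candidate set to accessions present in the
#' searched database, classifies peptides as unique (one candidate) or
#' ambiguous (several), and indexes, for every protein with at least one
#' supporting peptide, the peptides that support it. The proteins indexed
#' here are the candidate list that inference will score.
#'
#' @param peptides data.frame from [collapse_to_peptides()].
#' @param proteome data.frame from [read_fasta()].
#' @return list with `peptides` (with recomputed `n_candidates`,
#'   `is_unique`) and `protein_index` (named list: accession -> integer
#'   indices into `peptides`).
#' @export
build_bipartite <- function(peptides, proteome) {
  if (nrow(proteome) == 0L) stop_param("empty proteome")
  cand <- lapply(peptides$candidates, intersect, y = proteome$accession)
  keep <- lengths(cand) > 0L
  n_drop_edge <- sum(lengths(peptides$candidates) - lengths(cand))
  if (n_drop_edge > 0L)
    message(n_drop_edge, " peptide-protein edge(s) removed: protein absent from FASTA")
  if (!any(keep)) stop_param("no mappable peptides")
  if (any(!keep))
    warning(sum(!keep), " peptide(s) dropped: no candidate in FASTA")
  peptides <- peptides[keep, , drop = FALSE]
  cand <- cand[keep]
  peptides$candidates <- I(cand)
  peptides$n_candidates <- lengths(cand)
  peptides$is_unique <- peptides$n_candidates == 1L
  rownames(peptides) <- NULL
  protein_index <- split(
    rep(seq_len(nrow(peptides)), peptides$n_candidates),
    unlist(cand, use.names = FALSE)
  )
  list(peptides = peptides, protein_index = protein_index)
}
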