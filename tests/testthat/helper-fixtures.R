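# In-code fixtures shared across test files.

# minimal proteome table in the layout of read_fasta()
make_proteome <- function(accession, length,
                          is_decoy = startsWith(accession, "DECOY_"),
                          is_contaminant = FALSE) {
  out <- data.frame(accession = accession, length = length,
                    is_decoy = is_decoy, is_contaminant = is_contaminant)
  rownames(out) <- accession
  out
}

# minimal PSM table in the layout of read_psm_table()
make_psms <- function(peptide, pep, protein_ids,
                      psm_id = sprintf("psm%03d", seq_along(peptide))) {
  data.frame(psm_id = psm_id, peptide = peptide, pep = pep,
             protein_ids = I(protein_ids))
}

# protein score table ready for rank_and_qvalues(): acc_pep drives
# score/posterior so rescue fixtures stay self-consistent
make_scores <- function(accession, acc_pep,
                        is_decoy = startsWith(accession, "DECOY_") |
                          startsWith(accession, "D"),
                        is_contaminant = FALSE) {
  data.frame(accession = accession,
             n_peptides = 1L, n_unique_peptides = 1L,
             acc_pep = acc_pep,
             score = confidence_score(acc_pep),
             posterior = 1 - acc_pep,
             is_decoy = is_decoy, is_contaminant = is_contaminant,
             rescued = FALSE)
}

# Percolator-style PSM TSV on disk
write_psm_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("PSMId\tpeptide\tposterior_error_prob\tproteinIds", lines),
             path)
  path
}

write_fasta_fixture <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]]))), path)
  path
}

# independent brute-force accumulation oracle: plain product
naive_accpep <- function(errors) prod(errors)

# independent q-value oracle: literal double loop over the definition
# (inclusive >= threshold, +1 pseudocounts, clamp, cumulative min from
# the bottom of the ranking)
oracle_qvalues <- function(score, is_decoy, is_contaminant = FALSE) {
  if (length(is_contaminant) == 1L)
    is_contaminant <- rep(is_contaminant, length(score))
  ord <- order(-score, !is_decoy)
  score <- score[ord]; is_decoy <- is_decoy[ord]
  is_contaminant <- is_contaminant[ord]
  n <- length(score)
  fdr <- numeric(n)
  for (k in seq_len(n)) {
    x <- score[k]
    d <- sum(is_decoy & !is_contaminant & score >= x)
    t <- sum(!is_decoy & !is_contaminant & score >= x)
    fdr[k] <- min(1, (d + 1) / (t + 1))
  }
  q <- fdr
  for (k in rev(seq_len(n - 1))) q[k] <- min(fdr[k], q[k + 1])
  list(order = ord, q = q)
}
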