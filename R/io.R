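#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches (PSMs) with
#' per-PSM posterior error probabilities (PEPs) and mapped protein
#' accessions. The default column map follows the Percolator output
#' dialect (`PSMId`, `peptide`, `posterior_error_prob`, `proteinIds`);
#' other dialects are handled by overriding `column_map`. In Percolator
#' output the protein-id field may span several tab-separated trailing
#' columns, so by default the protein cell is split on any of tab,
#' semicolon or comma.
#'
#' @param path path to a TSV file with a header row.
#' @param column_map named character vector mapping the logical columns
#'   `psm_id`, `peptide`, `pep`, `protein_ids` to actual header names.
#' @param protein_delim regular expression splitting the protein-id cell.
#' @return a data.frame with columns `psm_id`, `peptide` (flanking
#'   residues stripped, modifications kept), `pep`, and the list column
#'   `protein_ids` (duplicate-free character vectors).
#' @export
read_psm_table <- function(path,
                           column_map = c(psm_id = "PSMId",
                                          peptide = "peptide",
                                          pep = "posterior_error_prob",
                                          protein_ids = "proteinIds"),
                           protein_delim = "[\t;,]") {
  if (!file.exists(path)) stop_param("PSM table not found: %s", path)
  needed <- c("psm_id", "peptide", "pep", "protein_ids")
  if (!all(needed %in% names(column_map)))
    stop_param("column_map must name columns: %s",
               paste(setdiff(needed, names(column_map)), collapse = ", "))
  # The protein-id field can contain raw tabs (Percolator writes one mapped
  # protein per trailing column), so rows are split manually.
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop_param("empty PSM table: %s", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  col <- match(column_map[needed], header)
  if (anyNA(col)) {
    miss <- column_map[needed][is.na(col)]
    stop_param("PSM table %s lacks mapped column(s): %s", path,
               paste(miss, collapse = ", "))
  }
  names(col) <- needed
  if (length(lines) == 1L) {
    return(data.frame(psm_id = character(), peptide = character(),
                      pep = numeric(),
                      protein_ids = I(list())))
  }
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(cells) < max(col))
  if (length(bad))
    stop_param("PSM table %s: row at line %d has too few columns",
               path, bad[[1L]] + 1L)
  pep <- suppressWarnings(as.numeric(vapply(cells, `[[`, "", col[["pep"]])))
  bad <- which(is.na(pep) | pep < 0 | pep > 1)
  if (length(bad))
    stop_param("PSM table %s: PEP not a probability at line %d",
               path, bad[[1L]] + 1L)
  # everything from the protein column rightwards belongs to the protein
  # field when it is the last mapped column (Percolator layout)
  prot_raw <- if (col[["protein_ids"]] == max(col)) {
    vapply(cells, function(x)
      paste(x[seq(col[["protein_ids"]], length(x))], collapse = "\t"), "")
  } else {
    vapply(cells, `[[`, "", col[["protein_ids"]])
  }
  prots <- lapply(strsplit(prot_raw, protein_delim), function(x) {
    x <- trimws(x)
    unique(x[nzchar(x)])
  })
  bad <- which(lengths(prots) == 0L)
  if (length(bad))
    stop_param("PSM table %s: no protein ids at line %d", path, bad[[1L]] + 1L)
  data.frame(
    psm_id = vapply(cells, `[[`, "", col[["psm_id"]]),
    peptide = strip_flanks(vapply(cells, `[[`, "", col[["peptide"]])),
    pep = pep,
    protein_ids = I(prots)
  )
}

#' Strip flanking-residue notation from peptide strings
#'
#' Search engines report peptides as `K.PEPTIDER.A` (preceding and
#' following residues around the cleavage sites). The flanks are removed;
#' modification annotations inside the sequence are kept untouched.
#'
#' @param peptide character vector.
#' @return character vector of bare (but possibly modified) peptides.
#' @export
strip_flanks <- function(peptide) {
  peptide <- sub("^[A-Z_-]\\.", "", peptide)
  sub("\\.[A-Z_-]$", "", peptide)
}

#' Read a protein database in FASTA format
#'
#' Loads targets, decoys and contaminants from a concatenated
#' target-decoy FASTA and records each protein's residue count, which the
#' inference step uses to apportion ambiguous-peptide support.
#'
#' @param path FASTA file.
#' @param decoy_prefix accession prefix tagging decoy entries (decoys are
#'   conventionally reversed target sequences).
#' @param contaminant_tags substrings of the accession marking known
#'   contaminants (e.g. from the cRAP collection).
#' @return a data.frame keyed by `accession` (header token up to the first
#'   whitespace) with columns `length`, `is_decoy`, `is_contaminant`.
#' @export
read_fasta <- function(path, decoy_prefix = "DECOY_",
                       contaminant_tags = c("cRAP", "CONTAM")) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop_param("no FASTA records in %s", path)
  acc <- sub("\\s.*$", "", names(seqs))
  len <- Biostrings::width(seqs)
  if (any(len == 0L)) stop_param("FASTA record with empty sequence in %s", path)
  is_con <- Reduce(`|`, lapply(contaminant_tags, grepl, x = acc, fixed = TRUE),
                   accumulate = FALSE, right = FALSE,
                   init = logical(length(acc)))
  data.frame(
    accession = acc,
    length = len,
    is_decoy = startsWith(acc, decoy_prefix),
    is_contaminant = is_con,
    row.names = acc
  )
}

#' Read a protein-complex catalogue
#'
#' Supports the CORUM `coreComplexes` TSV (complex name plus a
#' semicolon-separated subunit accession column) and a minimal two-column
#' `complex_id TAB member` format. Members are normalised with
#' `id_normalizer` so they can later be matched against FASTA accessions.
#' Complexes with no parseable member are skipped with a warning.
#'
#' @param path TSV file.
#' @param format `"corum"` or `"two_column"`.
#' @param id_normalizer function applied to each member id (default trims
#'   whitespace).
#' @return list of complexes, each a list with `complex_id`, `members`
#'   (unique character vector) and `is_decoy = FALSE`.
#' @export
read_complexes <- function(path, format = c("two_column", "corum"),
                           id_normalizer = trimws) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "two_column") {
    if (ncol(tab) < 2L)
      stop_param("two_column complex file needs >= 2 columns: %s", path)
    ids <- as.character(tab[[1L]])
    members <- id_normalizer(as.character(tab[[2L]]))
    keep <- nzchar(members) & !is.na(members)
    split_members <- split(members[keep], ids[keep])
    dropped <- setdiff(unique(ids), names(split_members))
    if (length(dropped))
      warning("skipped ", length(dropped), " complex(es) with no members")
    cxs <- lapply(names(split_members), function(id)
      list(complex_id = id, members = unique(split_members[[id]]),
           is_decoy = FALSE))
    return(cxs)
  }
  # CORUM coreComplexes dialect
  name_col <- intersect(c("ComplexName", "ComplexID", "complex_name"),
                        names(tab))[1L]
  sub_col <- intersect(c("subunits(UniProt IDs)", "subunits_uniprot_id",
                         "subunits.UniProt.IDs."), names(tab))[1L]
  if (is.na(name_col) || is.na(sub_col))
    stop_param("CORUM-style file %s lacks complex-name/subunit columns", path)
  out <- vector("list", nrow(tab))
  n_skip <- 0L
  for (i in seq_len(nrow(tab))) {
    members <- id_normalizer(strsplit(as.character(tab[[sub_col]][i]),
                                      ";", fixed = TRUE)[[1L]])
    members <- unique(members[nzchar(members) & !is.na(members)])
    if (length(members) == 0L) { n_skip <- n_skip + 1L; next }
    out[[i]] <- list(complex_id = as.character(tab[[name_col]][i]),
                     members = members, is_decoy = FALSE)
  }
  if (n_skip > 0L)
    warning("skipped ", n_skip, " complex(es) with no members")
  Filter(Negate(is.null), out)
}

#' Read a validation protein list
#'
#' One accession per line; blank lines ignored, surrounding whitespace
#' trimmed, duplicates collapsed. Used as the positive set when computing
#' recall/precision/F1 of a reported protein list.
#'
#' @param path text file.
#' @return character vector (a set) of accessions.
#' @export
read_validation_list <- function(path) {
  acc <- trimws(readLines(path, warn = FALSE))
  acc <- unique(acc[nzchar(acc)])
  if (length(acc) == 0L) stop_param("validation list %s is empty", path)
  acc
}

RESULT_COLUMNS <- c("accession", "n_peptides", "n_unique_peptides", "acc_pep",
                    "score", "q_value", "posterior", "is_decoy",
                    "is_contaminant", "rescued")

#' Write / read an inference result table
#'
#' Writes the ranked protein table of an inference result to TSV, one row
#' per protein in rank order, with enough digits that a read-back
#' round-trips every numeric field to at least 12 significant digits.
#'
#' @param result an object of class `accpep` or its `$proteins` data.frame.
#' @param path output TSV path.
#' @export
write_inference_tsv <- function(result, path) {
  tab <- if (inherits(result, "accpep")) result$proteins else result
  stopifnot(is.data.frame(tab), all(RESULT_COLUMNS %in% names(tab)))
  tab <- tab[, RESULT_COLUMNS]
  num <- vapply(tab, is.numeric, TRUE) & !vapply(tab, is.integer, TRUE)
  tab[num] <- lapply(tab[num], formatC, digits = 15, format = "g")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_inference_tsv
#' @export
read_inference_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(RESULT_COLUMNS %in% names(tab)))
    stop_param("%s is not an inference result table", path)
  tab
}
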