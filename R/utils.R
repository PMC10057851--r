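#' @keywords internal
"_PACKAGE"

# Probability floor added to accPEP before the deciban transform so the
# score of a perfectly supported protein (accPEP = 0) is finite (S = 140).
ACCPEP_SPIKE <- 1e-14

`%||%` <- function(a, b) if (is.null(a)) b else a

is_prob <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 0 & x <= 1)

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

#' Build an accession lookup table
#'
#' Search engines report proteins as full FASTA header tokens such as
#' `sp|P41182|BCL6_HUMAN`, while complex catalogues (CORUM-style) list bare
#' UniProt accessions such as `P41182`. This index maps both forms — the
#' full token and each `|`-separated piece — to the canonical accession used
#' throughout a result. Decoy accessions additionally index their
#' prefix-tagged pieces (`DECOY_P41182` for `DECOY_sp|P41182|BCL6_HUMAN`) so
#' that decoy-complex members resolve symmetrically to decoy proteins.
#'
#' @param accessions character vector of canonical accessions (FASTA
#'   header tokens up to the first whitespace).
#' @param decoy_prefix prefix tagging decoy accessions.
#' @return a named character vector mapping alias -> canonical accession.
#'   Aliases claimed by several accessions (generic tokens such as the
#'   `sp`/`tr` database tags) are dropped; a full accession always maps to
#'   itself.
#' @export
accession_index <- function(accessions, decoy_prefix = "DECOY_") {
  stopifnot(is.character(accessions))
  alias_of <- function(acc) {
    bare <- sub(paste0("^", decoy_prefix), "", acc)
    toks <- unique(c(acc, strsplit(bare, "|", fixed = TRUE)[[1]]))
    if (startsWith(acc, decoy_prefix)) {
      toks <- unique(c(acc, paste0(decoy_prefix, setdiff(toks, acc))))
    }
    toks
  }
  aliases <- lapply(accessions, alias_of)
  idx <- rep(accessions, lengths(aliases))
  names(idx) <- unlist(aliases)
  ambiguous <- names(idx)[duplicated(names(idx))]
  idx <- idx[!names(idx) %in% ambiguous]
  # a literal accession always resolves, even if one of its tokens clashed
  idx[accessions] <- accessions
  idx
}
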