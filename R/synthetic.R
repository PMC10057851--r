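# Ground-truthed synthetic benchmark generator.
#
# Emulates the inputs of a target-decoy shotgun proteomics experiment:
# a searched database with decoys, PSMs with PEPs drawn from separate
# laws for correct and incorrect identifications, shared peptides, decoy
# mirror matches, and complexes enriched for co-present proteins.
# Peptide strings are synthetic tokens, not tryptic digests — only the
# mapping topology and the PEP distributions matter to the method.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Generate a synthetic target-decoy proteome
#'
#' Target lengths are drawn from a log-normal law (median ~400 residues,
#' clipped to \[50, 5000\], mimicking a reviewed proteome's length
#' distribution); each target gets a reversed-sequence decoy. A fixed
#' fraction of the targets is marked truly present.
#'
#' @param n_proteins number of target proteins (>= 2).
#' @param present_fraction fraction of targets truly present, in (0, 1).
#' @param length_meanlog,length_sdlog log-normal parameters of target
#'   lengths.
#' @param length_range clipping bounds for lengths.
#' @param decoy_prefix decoy accession prefix.
#' @param seed RNG seed; the same seed reproduces the proteome exactly.
#' @return list with `proteome` (data.frame as from [read_fasta()], plus
#'   a `sequence` column), `present` (accessions truly present) and
#'   `params`.
#' @export
generate_proteome <- function(n_proteins = 200L, present_fraction = 0.6,
                              length_meanlog = log(400), length_sdlog = 0.6,
                              length_range = c(50L, 5000L),
                              decoy_prefix = "DECOY_", seed = 1L) {
  if (n_proteins < 2L) stop_param("n_proteins must be >= 2")
  if (present_fraction <= 0 || present_fraction >= 1)
    stop_param("present_fraction must be in (0, 1)")
  set.seed(seed)
  len <- as.integer(pmin(pmax(round(stats::rlnorm(n_proteins, length_meanlog,
                                                  length_sdlog)),
                              length_range[[1L]]), length_range[[2L]]))
  acc <- sprintf("sp|P%05d|SYNT", seq_len(n_proteins))
  seqs <- vapply(len, function(l)
    paste(sample(AA20, l, replace = TRUE), collapse = ""), "")
  rev_seq <- vapply(strsplit(seqs, "", fixed = TRUE), function(x)
    paste(rev(x), collapse = ""), "")
  present <- sort(sample(acc, round(present_fraction * n_proteins)))
  proteome <- data.frame(
    accession = c(acc, paste0(decoy_prefix, acc)),
    length = c(len, len),
    is_decoy = rep(c(FALSE, TRUE), each = n_proteins),
    is_contaminant = FALSE,
    sequence = c(seqs, rev_seq)
  )
  rownames(proteome) <- proteome$accession
  list(proteome = proteome, present = present,
       params = list(n_proteins = n_proteins,
                     present_fraction = present_fraction,
                     length_meanlog = length_meanlog,
                     length_sdlog = length_sdlog,
                     length_range = length_range,
                     decoy_prefix = decoy_prefix, seed = seed))
}

# share a fraction of peptides with 1-3 extra proteins drawn at random
# from `pool` (the proteins a peptide of this class could also map to)
add_ambiguity <- function(protein_ids, pool, ambiguity_fraction) {
  lapply(protein_ids, function(host) {
    if (stats::runif(1) >= ambiguity_fraction || length(pool) < 2L)
      return(host)
    extra <- sample(setdiff(pool, host),
                    min(sample(1:3, 1L), length(pool) - 1L))
    c(host, extra)
  })
}

#' Generate a synthetic PSM table
#'
#' Truly present proteins emit correct peptides at a Poisson rate
#' proportional to their length, with PEPs drawn from the correct-class
#' law (default Beta(1, 19), mean 0.05). Spurious matches land on any
#' target in proportion to length with PEPs from the incorrect-class law
#' (default Beta(8, 2), mean 0.8); decoy matches mirror the spurious
#' matches at `decoy_match_rate` and use the same incorrect-class law.
#' A fraction of peptides is additionally mapped to 1-3 random extra
#' proteins, creating ambiguous (N > 1) peptides: correct peptides share
#' among the truly present targets (modelling co-expressed paralogs),
#' spurious target matches among all targets, and decoy matches among
#' decoys, so sharing never crosses the target/decoy boundary.
#'
#' @param truth list from [generate_proteome()].
#' @param peptides_per_kres correct peptides per 1000 residues of a
#'   present protein.
#' @param incorrect_per_kres spurious peptides per 1000 residues summed
#'   over all targets.
#' @param ambiguity_fraction fraction of peptides mapped to > 1 protein.
#' @param pep_correct_shape,pep_incorrect_shape Beta shape pairs for the
#'   two PEP laws.
#' @param decoy_match_rate decoy PSMs per incorrect target PSM.
#' @param seed RNG seed.
#' @return a PSM data.frame in the layout of [read_psm_table()].
#' @export
generate_psms <- function(truth, peptides_per_kres = 8,
                          incorrect_per_kres = 0.5,
                          ambiguity_fraction = 0.15,
                          pep_correct_shape = c(1, 19),
                          pep_incorrect_shape = c(8, 2),
                          decoy_match_rate = 1, seed = 1L) {
  stopifnot(ambiguity_fraction >= 0, ambiguity_fraction <= 1,
            peptides_per_kres > 0, incorrect_per_kres >= 0,
            decoy_match_rate >= 0)
  set.seed(seed)
  prot <- truth$proteome
  targets <- prot[!prot$is_decoy, ]
  decoys <- prot[prot$is_decoy, ]

  # correct peptides from present proteins
  pres <- targets[targets$accession %in% truth$present, ]
  n_cor <- stats::rpois(nrow(pres), pres$length / 1000 * peptides_per_kres)
  host_cor <- rep(pres$accession, n_cor)
  pep_cor <- stats::rbeta(length(host_cor), pep_correct_shape[[1L]],
                          pep_correct_shape[[2L]])

  # spurious matches to any target, length-weighted
  n_inc <- stats::rpois(1L, sum(targets$length) / 1000 * incorrect_per_kres)
  host_inc <- sample(targets$accession, n_inc, replace = TRUE,
                     prob = targets$length)
  pep_inc <- stats::rbeta(n_inc, pep_incorrect_shape[[1L]],
                          pep_incorrect_shape[[2L]])

  # decoy mirror matches
  n_dec <- stats::rpois(1L, n_inc * decoy_match_rate)
  host_dec <- sample(decoys$accession, n_dec, replace = TRUE,
                     prob = decoys$length)
  pep_dec <- stats::rbeta(n_dec, pep_incorrect_shape[[1L]],
                          pep_incorrect_shape[[2L]])

  # correct peptides are shared among truly present targets (co-expressed
  # paralogs); spurious ones among any protein of their decoy class, so
  # the decoy channel stays a fair null model for absent targets
  ids_cor <- add_ambiguity(host_cor, pres$accession, ambiguity_fraction)
  ids_inc <- add_ambiguity(host_inc, targets$accession, ambiguity_fraction)
  ids_tgt <- c(ids_cor, ids_inc)
  ids_dec <- add_ambiguity(host_dec, decoys$accession, ambiguity_fraction)
  n <- length(ids_tgt) + length(ids_dec)
  psms <- data.frame(
    psm_id = sprintf("PSM%06d", seq_len(n)),
    peptide = sprintf("PEPTIDE%06d", seq_len(n)),
    pep = c(pep_cor, pep_inc, pep_dec),
    protein_ids = I(c(ids_tgt, ids_dec))
  )
  attr(psms, "truth_class") <- rep(c("correct", "incorrect", "decoy"),
                                   c(length(host_cor), n_inc, n_dec))
  psms
}

#' Generate synthetic protein complexes
#'
#' Complex sizes are uniform on `size_range`; each member slot is filled
#' from the truly present targets with probability `coherence`, else from
#' all targets — so coherence 1 yields complexes of co-present proteins
#' and coherence 0 makes membership independent of presence. Members are
#' written as bare UniProt-style ids (the middle `|` token), as curated
#' catalogues do. Decoy twins are not generated here: the inference tool
#' builds them.
#'
#' @param truth list from [generate_proteome()].
#' @param n_complexes number of complexes.
#' @param size_range integer bounds on complex size.
#' @param coherence probability a member is drawn from the present set.
#' @param seed RNG seed.
#' @return list of complexes in the layout of [read_complexes()].
#' @export
generate_complexes <- function(truth, n_complexes = 40L,
                               size_range = c(2L, 10L), coherence = 0.8,
                               seed = 1L) {
  if (coherence < 0 || coherence > 1)
    stop_param("coherence must be in [0, 1]")
  set.seed(seed)
  bare <- function(acc) vapply(strsplit(acc, "|", fixed = TRUE),
                               `[[`, "", 2L)
  targets <- truth$proteome$accession[!truth$proteome$is_decoy]
  lapply(seq_len(n_complexes), function(j) {
    size <- sample(seq(size_range[[1L]], size_range[[2L]]), 1L)
    from_present <- stats::runif(size) < coherence
    members <- character(size)
    members[from_present] <- sample(truth$present,
                                    sum(from_present), replace = TRUE)
    members[!from_present] <- sample(targets,
                                     sum(!from_present), replace = TRUE)
    list(complex_id = sprintf("CPX%03d", j),
         members = unique(bare(members)), is_decoy = FALSE)
  })
}

#' Generate a complete synthetic dataset
#'
#' One call producing a coherent proteome, PSM table, complex catalogue
#' and validation list (the truly present targets), all sharing one base
#' seed.
#'
#' @param seed base RNG seed (sub-seeds are derived deterministically).
#' @param coherence complex coherence.
#' @param ... passed on to the individual generators, matched by name:
#'   arguments of [generate_proteome()], [generate_psms()] and
#'   [generate_complexes()].
#' @return list with `proteome`, `present`, `psms`, `complexes`,
#'   `validation` and `params`.
#' @export
simulate_dataset <- function(seed = 1L, coherence = 0.8, ...) {
  dots <- list(...)
  pick <- function(fn) dots[intersect(names(dots), names(formals(fn)))]
  truth <- do.call(generate_proteome,
                   c(list(seed = seed), pick(generate_proteome)))
  psms <- do.call(generate_psms,
                  c(list(truth = truth, seed = seed + 1L),
                    pick(generate_psms)))
  complexes <- do.call(generate_complexes,
                       c(list(truth = truth, seed = seed + 2L,
                              coherence = coherence),
                         pick(generate_complexes)))
  list(proteome = truth$proteome, present = truth$present, psms = psms,
       complexes = complexes, validation = truth$present,
       params = c(truth$params, list(base_seed = seed,
                                     coherence = coherence)))
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact formats the readers consume: a FASTA database, a
#' tab-separated PSM table (Percolator-style columns), a two-column
#' complex TSV, a validation list, and a truth manifest.
#'
#' @param sim list from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the five file paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "proteome.fasta"),
             psms = file.path(dir, "psms.tsv"),
             complexes = file.path(dir, "complexes.tsv"),
             validation = file.path(dir, "validation.txt"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(paste0(">", sim$proteome$accession, "\n", sim$proteome$sequence),
             paths[["fasta"]])
  psm_tab <- data.frame(
    PSMId = sim$psms$psm_id,
    peptide = sim$psms$peptide,
    posterior_error_prob = formatC(sim$psms$pep, digits = 15, format = "g"),
    proteinIds = vapply(sim$psms$protein_ids, paste, "", collapse = ";")
  )
  utils::write.table(psm_tab, paths[["psms"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cx_tab <- data.frame(
    complex_id = rep(vapply(sim$complexes, `[[`, "", "complex_id"),
                     vapply(sim$complexes, function(x) length(x$members), 0L)),
    member = unlist(lapply(sim$complexes, `[[`, "members"), use.names = FALSE)
  )
  utils::write.table(cx_tab, paths[["complexes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$validation, paths[["validation"]])
  utils::write.table(
    data.frame(accession = sim$proteome$accession[!sim$proteome$is_decoy],
               present = sim$proteome$accession[!sim$proteome$is_decoy] %in%
                 sim$present),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

#' Calibration and rescue-power experiment
#'
#' Repeats the full pipeline on independently generated synthetic
#' datasets and measures, per seed, the empirical false-discovery
#' proportion (FDP) among targets reported at the nominal FDR and the
#' number of truly present targets reported, with and without complex
#' rescue. An empty reported list has FDP 0.
#'
#' @param n_seeds number of replicate datasets (>= 2 for a meaningful
#'   mean; 1 is allowed).
#' @param nominal_fdr reporting FDR under test.
#' @param seed base seed; replicate r uses `seed + (r - 1) * 101`.
#' @param coherence complex coherence passed to the generator.
#' @param ... further generator parameters for [simulate_dataset()].
#' @return list with `per_seed` (one row per replicate) and `summary`
#'   (one row of means, including `rescue_gain` = mean extra true targets
#'   reported with rescue).
#' @export
calibration_experiment <- function(n_seeds = 20L, nominal_fdr = 0.01,
                                   seed = 1L, coherence = 0.8, ...) {
  if (n_seeds < 1L) stop_param("n_seeds must be >= 1")
  rows <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    s <- seed + (r - 1L) * 101L
    sim <- simulate_dataset(seed = s, coherence = coherence, ...)
    fit0 <- accpep(sim$psms, sim$proteome, complexes = NULL,
                   fdr = nominal_fdr)
    fit1 <- accpep(sim$psms, sim$proteome, complexes = sim$complexes,
                   fdr = nominal_fdr)
    stat <- function(fit) {
      rep_acc <- report_at_fdr(fit, nominal_fdr)
      tp <- sum(rep_acc %in% sim$present)
      c(reported = length(rep_acc), tp = tp,
        fdp = if (length(rep_acc)) 1 - tp / length(rep_acc) else 0)
    }
    s0 <- stat(fit0); s1 <- stat(fit1)
    rows[[r]] <- data.frame(
      seed = s,
      reported_norescue = s0[["reported"]], tp_norescue = s0[["tp"]],
      fdp_norescue = s0[["fdp"]],
      reported_rescue = s1[["reported"]], tp_rescue = s1[["tp"]],
      fdp_rescue = s1[["fdp"]])
  }
  per_seed <- do.call(rbind, rows)
  summary <- data.frame(
    n_seeds = n_seeds, nominal_fdr = nominal_fdr,
    mean_fdp_norescue = mean(per_seed$fdp_norescue),
    mean_fdp_rescue = mean(per_seed$fdp_rescue),
    mean_tp_norescue = mean(per_seed$tp_norescue),
    mean_tp_rescue = mean(per_seed$tp_rescue),
    rescue_gain = mean(per_seed$tp_rescue - per_seed$tp_norescue))
  list(per_seed = per_seed, summary = summary)
}
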