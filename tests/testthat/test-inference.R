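test_that("length shares follow inverse length and sum to one", {
  expect_equal(length_share(250, 1), 1)
  expect_equal(length_share(rep(123, 4)), rep(0.25, 4))
  # hand arithmetic: lengths (100, 300), total 400;
  # shares (400/100, 400/300) normalised -> 4 / (4 + 4/3) = 0.75
  expect_equal(length_share(c(100, 300), 1), 0.75)
  expect_equal(length_share(c(100, 300), 2), 0.25)
  expect_error(length_share(numeric(0)), "empty")
  set.seed(3)
  for (i in 1:50) {
    lens <- sample(50:5000, sample(2:12, 1))
    expect_equal(sum(length_share(lens)), 1, tolerance = 1e-9)
  }
})

test_that("peptide support error follows the unique/ambiguous branches", {
  expect_equal(peptide_support_error(0.01, TRUE), 0.01)
  expect_equal(peptide_support_error(0.1, FALSE, 0.75), 1 - 0.9 * 0.75)
  # at full share the ambiguous branch reduces to the unique one
  expect_equal(peptide_support_error(0.37, FALSE, 1),
               peptide_support_error(0.37, TRUE))
})

test_that("accumulated PEP is the product of support errors", {
  expect_equal(protein_accpep(0.42), 0.42)
  expect_equal(protein_accpep(c(0.5, 0.5, 0.5)), 0.125)
  expect_equal(protein_accpep(c(0.3, 0, 0.9)), 0)
  expect_error(protein_accpep(numeric(0)), "peptide")
})

test_that("log-space accumulation matches the naive product", {
  set.seed(17)
  for (i in 1:200) {
    errs <- runif(sample(1:40, 1))
    expect_equal(protein_accpep(errs), naive_accpep(errs),
                 tolerance = 1e-12)
  }
})

test_that("confidence score is the spiked deciban transform", {
  expect_equal(confidence_score(0), 140)
  expect_equal(confidence_score(1), -10 * log10(1 + 1e-14))
  expect_equal(confidence_score(0.1), 10, tolerance = 1e-10)
})

test_that("q-values on the five-protein toy ranking match hand computation", {
  scores <- data.frame(
    accession = c("T1", "T2", "D1", "T3", "D2"),
    score = c(10, 8, 6, 5, 3),
    is_decoy = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  ranked <- rank_and_qvalues(scores)
  # FDR walk: 1/2, 1/3, 2/3, 2/4, 3/4; cummin from the bottom
  expect_equal(ranked$q_value, c(1/3, 1/3, 1/2, 1/2, 3/4))
  expect_equal(ranked$accession, c("T1", "T2", "D1", "T3", "D2"))
})

test_that("q-value degenerate cases: no decoys, single target, ties", {
  all_t <- rank_and_qvalues(data.frame(
    accession = c("A", "B", "C"), score = c(3, 2, 1), is_decoy = FALSE))
  expect_equal(all_t$q_value, c(0.25, 0.25, 0.25))  # cummin of 1/(k+1)
  single <- rank_and_qvalues(data.frame(
    accession = "A", score = 5, is_decoy = FALSE))
  expect_equal(single$q_value, 0.5)
  tied <- rank_and_qvalues(data.frame(
    accession = c("T1", "T2", "D1"), score = c(7, 7, 7),
    is_decoy = c(FALSE, FALSE, TRUE)))
  expect_equal(length(unique(tied$q_value)), 1L)
  expect_equal(tied$accession[1], "D1")  # decoys ranked first at ties
  expect_error(rank_and_qvalues(data.frame(
    accession = "D", score = 1, is_decoy = TRUE)), "target")
})

test_that("q-values match an independent oracle and are monotone", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(3:40, 1)
    score <- round(runif(n, 0, 30), sample(c(0, 1, 3), 1))  # force some ties
    is_decoy <- runif(n) < 0.4
    if (!any(!is_decoy)) is_decoy[1] <- FALSE
    ranked <- rank_and_qvalues(data.frame(
      accession = sprintf("P%02d", 1:n), score = score, is_decoy = is_decoy))
    orc <- oracle_qvalues(score, is_decoy)
    expect_equal(ranked$q_value, orc$q, tolerance = 1e-12)
    expect_true(all(diff(ranked$q_value) >= -1e-12))
    expect_true(all(ranked$q_value > 0 & ranked$q_value <= 1))
  }
})

test_that("contaminants are flagged but excluded from the FDR tallies", {
  with_con <- rank_and_qvalues(data.frame(
    accession = c("T1", "CON", "D1"), score = c(10, 8, 6),
    is_decoy = c(FALSE, FALSE, TRUE),
    is_contaminant = c(FALSE, TRUE, FALSE)))
  without <- rank_and_qvalues(data.frame(
    accession = c("T1", "D1"), score = c(10, 6),
    is_decoy = c(FALSE, TRUE)))
  expect_equal(with_con$q_value[with_con$accession == "T1"],
               without$q_value[without$accession == "T1"])
})

test_that("protein scoring chains shares, errors, accumulation and ranking", {
  proteome <- make_proteome(c("A", "B", "DECOY_A"), c(200, 200, 200))
  # A: one unique peptide pep 0.05 -> accPEP 0.05, S ~= 13.0103
  # A and B share a peptide (equal lengths -> phi = 0.5 each)
  psms <- make_psms(c("PEP1", "PEP2", "PEP3"),
                    c(0.05, 0.2, 0.9),
                    list("A", c("A", "B"), "DECOY_A"))
  bip <- build_bipartite(collapse_to_peptides(psms), proteome)
  res <- infer_proteins(bip, proteome)
  a <- res[res$accession == "A", ]
  b <- res[res$accession == "B", ]
  shared_err <- 1 - (1 - 0.2) * 0.5          # 0.6
  expect_equal(a$acc_pep, 0.05 * shared_err)
  expect_equal(b$acc_pep, shared_err)
  expect_equal(a$n_peptides, 2L)
  expect_equal(a$n_unique_peptides, 1L)
  expect_equal(a$score, -10 * log10(a$acc_pep + 1e-14))
  expect_equal(a$posterior, 1 - a$acc_pep)
  # adding a supporting peptide with error < 1 strictly lowers accPEP
  expect_lt(a$acc_pep, 0.05)
})

test_that("proteins sharing one peptide at equal lengths score identically", {
  proteome <- make_proteome(c("A", "B"), c(300, 300))
  psms <- make_psms("PEP1", 0.1, list(c("A", "B")))
  res <- infer_proteins(build_bipartite(collapse_to_peptides(psms), proteome),
                        proteome)
  expect_equal(res$acc_pep[1], res$acc_pep[2])
})

test_that("single unique peptide gives accPEP = pep and S ~= 13.0103 at 0.05", {
  proteome <- make_proteome(c("A", "DECOY_B"), c(100, 100))
  psms <- make_psms(c("PEP1", "PEP2"), c(0.05, 0.8), list("A", "DECOY_B"))
  res <- infer_proteins(build_bipartite(collapse_to_peptides(psms), proteome),
                        proteome)
  a <- res[res$accession == "A", ]
  expect_equal(a$acc_pep, 0.05)
  expect_equal(a$score, 13.0103, tolerance = 1e-4)
})

test_that("reporting at an FDR returns ranked targets under the q cutoff", {
  ranked <- rank_and_qvalues(data.frame(
    accession = c("T1", "T2", "D1", "T3", "D2"),
    score = c(10, 8, 6, 5, 3),
    is_decoy = c(FALSE, FALSE, TRUE, FALSE, TRUE)))
  expect_equal(report_at_fdr(ranked, 0.5), c("T1", "T2", "T3"))
  expect_equal(report_at_fdr(ranked, 0.4), c("T1", "T2"))
  expect_equal(report_at_fdr(ranked, 1), c("T1", "T2", "T3"))
  expect_equal(report_at_fdr(ranked, 0.1), character(0))
  expect_error(report_at_fdr(ranked, 0), "FDR")
})
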