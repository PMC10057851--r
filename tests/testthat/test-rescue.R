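test_that("decoy complex twins mirror target complexes member-by-member", {
  cxs <- list(list(complex_id = "c1", members = c("P1", "P2"), is_decoy = FALSE),
              list(complex_id = "c2", members = "P3", is_decoy = FALSE),
              list(complex_id = "c3", members = c("P1", "P4"), is_decoy = FALSE))
  all_cx <- build_decoy_complexes(cxs)
  expect_length(all_cx, 6L)
  twin <- all_cx[[4L]]
  expect_true(twin$is_decoy)
  expect_equal(twin$members, c("DECOY_P1", "DECOY_P2"))
  expect_length(build_decoy_complexes(list()), 0L)
})

test_that("complex posteriors aggregate member posteriors over the scored set", {
  cx <- list(complex_id = "c1", members = c("A", "B"), is_decoy = FALSE)
  post <- c(A = 0.9, B = 0.4, C = 0.99)
  expect_equal(complex_posterior(cx, post, "max"), 0.9)
  expect_equal(complex_posterior(cx, post, "mean"), 0.65)
  disjoint <- list(complex_id = "c2", members = c("X", "Y"), is_decoy = FALSE)
  expect_equal(complex_posterior(disjoint, post), 0)
})

test_that("a protein draws the best posterior from same-class complexes only", {
  cxs <- list(
    list(complex_id = "c1", members = c("A", "B"), is_decoy = FALSE),
    list(complex_id = "c2", members = "A", is_decoy = FALSE),
    list(complex_id = "c1_decoy", members = c("DECOY_A", "DECOY_B"),
         is_decoy = TRUE))
  cp <- c(c1 = 0.2, c2 = 0.8, c1_decoy = 0.6)
  expect_equal(protein_complex_posterior("A", FALSE, cxs, cp), 0.8)
  expect_equal(protein_complex_posterior("Z", FALSE, cxs, cp), 0)
  expect_equal(protein_complex_posterior("DECOY_A", TRUE, cxs, cp), 0.6)
  # a target never draws from a decoy complex even if (erroneously) listed
  bad <- list(list(complex_id = "cx", members = "A", is_decoy = TRUE))
  expect_equal(protein_complex_posterior("A", FALSE, bad, c(cx = 0.9)), 0)
})

test_that("rescue update raises posteriors by max and flags strict increases", {
  ranked <- rank_and_qvalues(make_scores(c("A", "B", "DECOY_C"),
                                         acc_pep = c(0.3, 0.1, 0.8)))
  up <- rescue_update(ranked, c(A = 0.9, B = 0.7))
  a <- up[up$accession == "A", ]; b <- up[up$accession == "B", ]
  expect_equal(a$posterior, 0.9)
  expect_true(a$rescued)
  expect_equal(a$acc_pep, 1 - 0.9)
  expect_equal(a$score, confidence_score(0.1))
  expect_equal(b$posterior, 0.9)      # 0.9 > 0.7 from before: unchanged
  expect_false(b$rescued)
  ident <- rescue_update(ranked, c(A = 0, B = 0, DECOY_C = 0))
  expect_equal(ident$posterior, ranked$posterior)
  expect_false(any(ident$rescued))
})

test_that("rescue with no complexes runs one no-op iteration", {
  ranked <- rank_and_qvalues(make_scores(c("T1", "DECOY_X"), c(0.05, 0.7)))
  st <- iterate_rescue(ranked, list(), f = 0.5)
  expect_equal(st$iterations, 1L)
  expect_true(st$converged)
  expect_equal(st$reported_counts[1], st$reported_counts[2])
  expect_equal(st$proteins$posterior[order(st$proteins$accession)],
               ranked$posterior[order(ranked$accession)])
})

test_that("a weak complex partner of a confident protein is rescued across the FDR line", {
  # five confident targets, one weak target B sharing a complex with T1,
  # two decoys between them in the ranking
  scores <- make_scores(
    c("T1", "T2", "T3", "T4", "T5", "B", "D1", "D2"),
    acc_pep = c(0.01, 0.012, 0.014, 0.016, 0.018, 0.9, 0.5, 0.6),
    is_decoy = c(rep(FALSE, 6), TRUE, TRUE))
  ranked <- rank_and_qvalues(scores)
  expect_equal(length(report_at_fdr(ranked, 0.2)), 5L)  # B not reported
  st <- iterate_rescue(ranked, list(list(complex_id = "c1",
                                         members = c("T1", "B"),
                                         is_decoy = FALSE)),
                       f = 0.2, decoy_prefix = "DECOY_")
  expect_equal(st$reported_counts, c(5L, 6L, 6L))
  expect_equal(st$iterations, 2L)
  expect_true(st$converged)
  b <- st$proteins[st$proteins$accession == "B", ]
  expect_true(b$rescued)
  expect_equal(b$posterior, 0.99)   # max member posterior of c1
  expect_true(b$q_value <= 0.2)
})

test_that("posteriors rise monotonically and converge to a fixpoint", {
  set.seed(31)
  for (i in 1:40) {
    n_t <- sample(4:12, 1); n_d <- sample(2:6, 1)
    accs <- c(sprintf("T%02d", 1:n_t), sprintf("DECOY_T%02d", 1:n_d))
    ranked <- rank_and_qvalues(make_scores(
      accs, acc_pep = runif(n_t + n_d),
      is_decoy = startsWith(accs, "DECOY_")))
    cxs <- lapply(1:3, function(j)
      list(complex_id = paste0("c", j),
           members = sample(sprintf("T%02d", 1:n_t), sample(2:n_t, 1)),
           is_decoy = FALSE))
    st <- iterate_rescue(ranked, cxs, f = 0.3)
    key <- order(st$proteins$accession)
    p_before <- ranked$posterior[order(ranked$accession)]
    p_after <- st$proteins$posterior[key]
    expect_true(all(p_after >= p_before - 1e-12))
    expect_true(all(st$proteins$acc_pep[key] <= 1 - p_before + 1e-12))
    # one extra propagation round after convergence changes nothing
    again <- iterate_rescue(st$proteins, cxs, f = 0.3, max_iters = 1L)
    expect_equal(again$proteins$posterior[order(again$proteins$accession)],
                 p_after)
  }
})

test_that("rescue treats mirrored targets and decoys symmetrically", {
  ranked <- rank_and_qvalues(make_scores(
    c("A", "B", "DECOY_A", "DECOY_B"),
    acc_pep = c(0.05, 0.8, 0.05, 0.8),
    is_decoy = c(FALSE, FALSE, TRUE, TRUE)))
  st <- iterate_rescue(ranked,
                       list(list(complex_id = "c1", members = c("A", "B"),
                                 is_decoy = FALSE)),
                       f = 0.9, max_iters = 5L)
  p <- st$proteins
  expect_equal(p$posterior[p$accession == "B"],
               p$posterior[p$accession == "DECOY_B"])
  expect_equal(p$posterior[p$accession == "A"],
               p$posterior[p$accession == "DECOY_A"])
})

test_that("mean aggregation never reports more than max at a fixed FDR", {
  set.seed(57)
  sim <- simulate_dataset(seed = 101, n_proteins = 80L, n_complexes = 15L,
                          coherence = 1)
  fit_max <- accpep(sim$psms, sim$proteome, sim$complexes, aggregator = "max")
  fit_mean <- accpep(sim$psms, sim$proteome, sim$complexes, aggregator = "mean")
  expect_lte(length(report_at_fdr(fit_mean, 0.05)),
             length(report_at_fdr(fit_max, 0.05)))
})
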