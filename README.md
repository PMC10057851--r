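# accpep

Protein inference for shotgun proteomics: length-adjusted posterior
error accumulation with target-decoy q-values and protein-complex
rescue.

## The problem

In bottom-up mass spectrometry, a search engine matches spectra to
peptides and a rescoring tool (e.g. Percolator) attaches to every
peptide-spectrum match (PSM) a posterior error probability (PEP) — the
probability that the identification is wrong. Deciding which *proteins*
are present is then complicated by two things: many peptides map to more
than one database protein (*ambiguous* peptides), and genuinely present
proteins with low abundance or poor sequence uniqueness leave only weak
peptide evidence. Tools that simply discard ambiguous or low-confidence
peptides buy precision at a heavy cost in proteome coverage.

`accpep` keeps all of that evidence and controls the error rate
afterwards:

1. **Length-adjusted error accumulation.** A peptide with PEP
   $pep$ mapping uniquely to protein $P$ supports it with error $pep$.
   A peptide shared among $N$ candidates supports each candidate $h$
   with error $1-(1-pep)\,\phi_h$, where the length share

   $$\phi_h = \frac{1/\mathrm{len}(P_h)}{\sum_{i=1}^{N} 1/\mathrm{len}(P_i)}$$

   apportions the peptide among candidates inversely to protein length
   (longer proteins generate spurious matches more easily, so they get
   a smaller share; $\sum_h \phi_h = 1$). Assuming peptides support a
   protein independently, the protein's accumulated error is the
   product over its peptides,
   $\mathrm{accPEP} = \prod_j e_j$, computed in log space.

2. **Confidence scores and q-values.** Scores are decibans,
   $S = -10\log_{10}(\mathrm{accPEP} + 10^{-14})$, so perfect support
   (accPEP = 0) maps to $S = 140$. Proteins — targets and reversed-decoy
   entries alike — are ranked by $S$ and assigned q-values from the
   pseudocounted target-decoy FDR
   $\widehat{\mathrm{FDR}}(x) = \frac{|\{d \in D : S_d \ge x\}| + 1}{|\{t \in T : S_t \ge x\}| + 1}$,
   clamped at 1 and made monotone by a cumulative minimum from the
   bottom of the ranking.

3. **Complex rescue.** Proteins that form a stable complex tend to be
   co-present. Each curated complex receives the *maximum* posterior
   $p = 1-\mathrm{accPEP}$ of its scored members; every member's
   posterior is then raised to the best posterior among its complexes;
   scores and q-values are recomputed. Decoy twins of every complex
   (members replaced by their decoy counterparts) give decoy proteins
   the same chance of rescue, keeping the FDR estimate unbiased. The
   propagation iterates to its fixpoint.

A ground-truthed synthetic-data generator (proteome with reversed
decoys, PSMs with Beta-distributed PEPs for correct and incorrect
matches, shared peptides, coherent complexes) makes the whole pipeline
testable without any external download, and a calibration harness
measures the empirical false-discovery proportion against the truth.

## Worked example

```r
library(accpep)

sim <- simulate_dataset(seed = 7)          # 200 targets + 200 decoys, 120 present
fit <- accpep(sim$psms, sim$proteome, sim$complexes)
fit
#> Protein inference by accumulated PEP
#>   PSMs: 620 kept of 620 (PEP <= 0.999); peptides: 620
#>   candidates scored: 193 (139 targets, 54 decoys, 0 contaminants)
#>   complex rescue: 6 iteration(s), 117 protein(s) rescued
#>   targets reported at FDR 0.01: 121

evaluate_report(report_at_fdr(fit, 0.01), sim$validation)
#>    tp fp fn precision    recall        f1
#> 1 118  3  2 0.9752066 0.9833333 0.9792531
```

121 target proteins pass the 1% FDR threshold; checked against the
generator's ground truth, 118 of them are truly present (precision
0.975) and only 2 detectable present proteins are missed (recall
0.983). Without `sim$complexes` the same data yield fewer reported true
positives — the gain is exactly the weakly supported complex members
whose posteriors were raised by confident partners (`fit$proteins$rescued`).

Real data enter through `read_psm_table()` (Percolator-style TSV),
`read_fasta()` (target-decoy database; protein lengths feed the length
share), `read_complexes()` (CORUM-style or two-column TSV) and
`read_validation_list()`; `write_inference_tsv()` writes the ranked
result. The same pipeline is scriptable via `inst/cli/accpep`
(subcommands `infer`, `eval`, `simulate`, `sweep`).

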