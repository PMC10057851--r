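---
title: "Protein inference by accumulated PEP: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein inference by accumulated PEP: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accpep)
```

## The inference model

The unit of evidence is the peptide. PSMs are filtered at a PEP
threshold (default 0.999, i.e. essentially nothing is discarded) and
collapsed to peptides, each carrying its best (minimum) PEP over the
contributing PSMs and the union of the protein accessions its PSMs
mapped to. The minimum is the conservative standard for "best supporting
observation"; a peptide observed many times is represented by its
strongest observation, never by an average that a single bad match could
dilute.

For a peptide with PEP $pep$ and $N$ candidate proteins, the error of
using it to support candidate $h$ is

$$e_h = \begin{cases} pep & N = 1\\ 1-(1-pep)\,\phi_h & N > 1,\end{cases}
\qquad \phi_h = \frac{1/\mathrm{len}(P_h)}{\sum_i 1/\mathrm{len}(P_i)}.$$

The ambiguous branch reads: the support fails if the identification is
wrong ($pep$) or if it is right but the peptide originated from another
candidate ($(1-pep)(1-\phi_h)$). The share $\phi$ is inversely
proportional to protein length because longer proteins produce spurious
matches more readily; equal lengths reduce to the uniform share $1/N$,
and $N=1$ forces $\phi=1$, so the two branches agree on the boundary.
Shares always sum to one across a peptide's candidates — a peptide
contributes exactly one peptide's worth of (anti-)evidence no matter how
it is split.

A protein's accumulated error is the product of its peptides' support
errors (independence assumption), and its confidence score is
$S=-10\log_{10}(\mathrm{accPEP}+10^{-14})$. The spike makes $S$ finite
at accPEP $=0$ (an analytically forced endpoint: $S = 140$); proteins
with hundreds of peptides reach it through double-precision underflow,
which is why the product is accumulated as a sum of logs with $\log 0 =
-\infty$ short-circuiting to an exact zero.

Every candidate — target, reversed decoy, contaminant — is scored by the
identical rule; decoys must experience the same scoring (including
shares that mix target and decoy lengths when a peptide maps across the
boundary) or the decoy score distribution stops being a fair model of
false targets. The pseudocounted FDR
$(\#D_{\ge x}+1)/(\#T_{\ge x}+1)$, clamped at 1, is turned into
q-values by a cumulative minimum from the bottom of the ranking. At tied
scores the inclusive threshold makes q-values tie-invariant; only the
printed order is affected, and there decoys are placed first
(conservative). Contaminants are ranked and flagged but counted in
neither tally: they are neither decoys nor biologically meaningful
targets, and letting them inflate the target count would bias the FDR
downward. Proteins with no surviving peptide are absent from the result
rather than carried at accPEP 1.

## Complex rescue

Curated complexes act as a co-presence prior: the posterior of a complex
is the **maximum** posterior $p = 1-\mathrm{accPEP}$ of its scored
members, and each member's posterior is raised to the best posterior
among its complexes. The maximum (rather than a mean) is deliberate:
complex catalogues overlap incompletely with any one sample, and a mean
over largely unobserved members drags confident complexes down — the
`aggregator = "mean"` option is provided and, at a fixed FDR, reports at
most as many proteins in practice. Every curated complex has a decoy
twin whose members are the decoy counterparts; targets draw rescue only
from curated complexes and decoys only from twins, so rescue inflates
both score distributions symmetrically and the q-value machinery stays
honest. All complexes are used regardless of size by default
(`min_complex_size` exposes a filter; small complexes are where weakly
supported proteins live, so filtering them is a deliberate trade).

**Stopping rule.** Posterior propagation is iterated to its fixpoint:
each round recomputes complex posteriors from the current protein
posteriors, and the loop stops when no posterior changes. Because
posteriors only move upward through a finite set of values (maxima of
the initial posteriors), the fixpoint is reached in finitely many
rounds, and one further round is a no-op. A cheaper rule — stop as soon
as the count of targets reported at the working FDR stops increasing —
halts prematurely when rescues chain across overlapping complexes
(protein A lifts complex 1, which lifts B, which only in the next round
lifts complex 2 and C); running to the fixpoint subsumes that rule,
since at the fixpoint the reported count has necessarily stopped
changing. `max_iters` (default 100) is a safety net only.

Rescue deliberately trades precision for coverage: a complex member that
is truly absent while its partners are present will be pulled up with
them. The decoy twins keep the *estimated* FDR honest only insofar as
decoy complexes acquire scored members; on real data the empirical
false-discovery proportion after rescue can exceed the nominal level by
a small margin (the synthetic calibration below makes this visible), and
that is the price of recovering weakly supported true proteins.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pep_max` | 0.999 | PSM PEP retention threshold; near-1 keeps weak evidence for rescue to use |
| `fdr` | 0.01 | working FDR for reporting and the rescue trace |
| `aggregator` | `"max"` | complex posterior rule (`"mean"` is stricter, reports fewer) |
| `decoy_prefix` | `"DECOY_"` | accession prefix tagging decoys |
| `min_complex_size` | 1 | minimum complex size used |
| `max_iters` | 100 | rescue iteration cap |

Identifier matching deserves a note: search engines emit full header
tokens (`sp|P41182|BCL6_HUMAN`) while complex catalogues list bare
accessions (`P41182`). `accession_index()` maps every `|`-token of every
accession to its canonical form, drops tokens claimed by more than one
protein (`sp`, shared gene symbols), and resolves decoy-prefixed tokens
to decoy accessions, so complex membership works across the three input
files without configuration. Peptide strings keep modification
annotations and lose flanking-residue notation; isoleucine and leucine
are not merged — identity of the normalized string is the identity of
the peptide.

## What the synthetic generator emulates

`simulate_dataset()` produces the full input set with known ground
truth. Its defaults are the package's reference conditions, chosen once
as a plausible desk-scale image of a deep cell-line experiment:

* 200 target proteins plus reversed decoys, lengths log-normal with
  median 400 residues (sdlog 0.6) clipped to [50, 5000] — the shape of a
  reviewed proteome, scaled down in count;
* 60% of targets truly present (a deep experiment relative to a
  restricted search database);
* correct peptides from present proteins at 8 per 1000 residues
  (Poisson), PEPs from Beta(1, 19) (mean 0.05); spurious matches over
  all targets at 0.5 per 1000 residues with PEPs from Beta(8, 2) (mean
  0.8); decoy matches mirror the spurious channel 1:1;
* 15% of peptides shared with 1–3 extra proteins. Correct peptides
  share among *present* targets (co-expressed paralogs), spurious ones
  among all targets, decoy matches among decoys — sharing never crosses
  the target/decoy boundary, as with reversed decoys in practice;
* 40 complexes, sizes uniform on 2–10, members drawn from the present
  set with probability `coherence` (default 0.8; 1 models a perfectly
  co-present catalogue).

What it does **not** model: real enzymatic digestion (peptides are
synthetic tokens; only mapping topology and PEP distributions matter to
the method), peptide-level score correlation within a protein, absent
homologs sharing peptides with present ones, intensity or
retention-time structure, and contaminants. The last two gaps matter
for interpretation: passing calibration here shows the target-decoy
machinery is self-consistent when decoys are a fair null — it does not
certify calibration on real data, where shared peptides between present
and absent paralogs are a known source of protein-level FDR optimism
for any accumulation-style scorer.

`calibration_experiment()` runs the pipeline over independent seeds and
reports the empirical false-discovery proportion among targets at the
nominal FDR, and the true targets reported with and without rescue. At
the reference conditions (20 seeds, nominal 1%) core inference holds the
mean FDP well under the nominal level, and rescue with coherent
complexes adds reported true targets at no FDP cost; with partially
incoherent complexes (coherence 0.8) the post-rescue FDP rises above
the nominal level by a few percent — the precision/coverage trade
described above, now with a number attached (the acceptance script
reports both FDP figures). The test suite asserts these on 20
seeds; the problem size (200 targets per seed) keeps a full calibration
under ten seconds while leaving ~100 present detectable proteins, enough
for a 1% FDR threshold to be attainable under the pseudocounted
estimator ($q \ge 1/(T+1)$ caps how small a q-value few targets can
reach).

## Numerical choices and degenerate inputs

* accPEP accumulates as $\exp\sum\log e_j$; an exact zero error yields
  exactly zero (absorbing), not a denormal.
* FDR clamps at 1 (the raw ratio exceeds 1 when decoys outnumber
  targets); q-values are in $(0, 1]$ by construction.
* Zero targets in the candidate list is an error (FDR undefined), as is
  an empty peptide list after proteome restriction ("no mappable
  peptides"); a complex with no member in the candidate list has
  posterior 0 rather than an undefined max.
* Ties in score receive identical q-values; ranking prints decoys
  first within a tie.
* Round-tripping a result through TSV preserves numerics to at least 12
  significant digits (15 digits written).

## Known limitations

No protein grouping or parsimony: proteins sharing all peptides are
reported separately with identical scores, not merged into groups.
Peptide-level FDR is out of scope (PEPs are taken as given from the
rescoring tool). The spectral-count matrix counts an ambiguous PSM once
per reported protein it maps to (a `"unique"`-only mode exists);
downstream differential-expression modelling is intentionally left to
dedicated count-based tools.
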