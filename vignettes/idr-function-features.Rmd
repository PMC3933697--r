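---
title: "Predicting protein function from disordered-region sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function from disordered-region sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrfunc)
```

## The problem and the model

Intrinsically disordered regions (IDRs) lack stable tertiary structure, show
low sequence complexity and conserve poorly, which makes them awkward inputs
for homology-based function prediction. Yet their residue composition is
known to track the function of the proteins that carry them. `idrfunc`
implements a descriptor-based route: each IDR is summarised by fixed-length
numeric vectors, and the multi-label problem of assigning GO Slim terms to
the parent protein is decomposed one-vs-rest into one binary classifier per
term. Every IDR of a protein inherits the protein's full term set — the
working assumption is that all IDRs within a protein contribute to its
overall function and are classified independently.

Seven descriptor families are implemented, with fixed dimensions:

| family | dimension | what it encodes |
|---|---|---|
| `chemical_composition` | 5 | fractions of positive (R,K,H), negative (D,E), polar (S,T,N,Q,Y,C), hydrophobic (A,V,L,I,M,F,W), special (P,G) residues |
| `aa_composition` | 20 | per-residue fractions |
| `composition_dubchak` | 125 | composition + CTD blocks over 5 physicochemical properties |
| `occurrence_dubchak` | 125 | residue counts + the same CTD blocks |
| `sequence_bigrams` | 400 | adjacent ordered residue-pair frequencies |
| `alternate_bigrams` | 400 | one-gap ordered residue-pair frequencies |
| `profile_bigrams` | 400 | PSSM transition products `T[m,n] = sum_i E[i,m] E[i+1,n]` |

The chemical classes as usually quoted cover only 19 residues; histidine is
assigned here to the positively charged class, its standard chemical
grouping, so that the five fractions always sum to 1.

Each CTD (composition–transition–distribution) block maps a sequence onto a
three-group property partition and emits 21 values: 3 group compositions, 3
boundary-crossing transition frequencies normalized by $L-1$, and, per
group, the scaled positions of its first, 25%, 50%, 75% and last occurrence
(ceiling quantile indices, $0$ for an absent group). The five shipped
partitions (hydrophobicity, normalized van der Waals volume, polarity,
polarizability, and helix/strand/coil former classes standing in for
predicted secondary structure) are the standard fold-recognition groupings;
they are configuration, not constants — `default_property_partitions()`
returns an editable list, and an external secondary-structure assignment can
be substituted by replacing the fifth partition.

Bigram vectors are counts divided by the window count ($L-1$ adjacent,
$L-2$ gapped), so they are probability vectors independent of IDR length;
this is the standard reading of "occurrence probabilities" where no
denominator is stated. All 400-vectors share one flattening convention —
first residue varies slowest over the fixed alphabet
`ACDEFGHIKLMNPQRSTVWY` — so sequence- and profile-derived bigrams are
column-compatible; on a one-hot profile the profile bigrams equal
$(L-1)\times$ the sequence bigrams exactly.

## Classification and evaluation

Each GO Slim term gets a Gaussian naive Bayes classifier over one feature
family. Per-component class-conditional means and variances are estimated
with empirical class priors; variances are floored at $10^{-9}$ of the
component's global variance (absolute floor $10^{-12}$ for globally
constant components) because sparse bigram components routinely have zero
within-class variance. Posteriors are computed in log space and a term is
called present at posterior $\ge 0.5$ — the tie is inclusive, treating 0.5
as an operating point rather than a strict threshold.

Annotation sets are expanded by one ancestor step before anything else:
each term's immediate parent joins the label set (not the transitive
closure). The expanded vocabulary defines the classifier set, so parents
are themselves predicted terms.

Cross-validation is 10-fold, seeded, and stratified by the term's binary
label: shuffled positives are dealt round-robin into folds, negatives
continue the deal, giving per-class and total fold sizes that differ by at
most one. Stratification is a deliberate choice — rare terms would
otherwise produce folds with no positive instances. Terms with fewer than
`min_positives = 10` members in either class are reported as skipped rather
than evaluated on vacuous splits. Folds are assigned per IDR, not per
protein: IDRs of one protein may land in different folds, the literal
counterpart of treating IDRs as independent instances.

Per term, the held-out calls accumulate into TP/FP/TN/FN counted in IDRs,
from which sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, precision
$TP/(TP+FP)$ and the Matthews correlation coefficient are computed. A ratio
with a zero denominator is reported as 0 and flagged `undefined` instead of
propagating NaN; an MCC with a zero denominator factor is defined as 0.
Family-level summaries are unweighted means over evaluated terms. A term
classifier counts as better than random when its true positive rate
strictly exceeds its false positive rate.

The precision–recall analysis holds out 105 randomly chosen IDRs (seeded;
repeated draws under different seeds are supported), trains on the rest,
and scores every trained term on every test IDR. At each threshold $p$ on a
default grid of 0.05 steps over $[0,1]$, an IDR's predicted set is every
term scored at $p$ or higher; against its expanded known set this gives
per-IDR recall and precision. The curve reports overall precision
$N_{correct}/N_{total}$ ($N_{correct}$ = test IDRs predicting at least one
known term at $p$ or higher) and average recall (mean per-IDR recall over
the whole test set, IDRs with empty prediction sets contributing 0). Mean
per-IDR precision is computed alongside as a companion column, since both
quantities are informative and the overall-precision definition alone
discards the per-IDR denominator.

## The synthetic study conditions

Real genome-scale IDR datasets (tens of thousands of IDRs, >100 GO Slim
terms, PSI-BLAST profiles against nr) are not shippable or recomputable at
desk scale, so the package carries a seeded generator whose defaults define
the study conditions used throughout the tests:

* 250 proteins with 1–3 IDRs each (≈500 IDRs, emulating the ≈1.7
  IDR/protein ratio of genome-scale human sets), IDR lengths uniform on
  30–300 residues;
* 12 leaf GO Slim terms under 4 parents (two levels — sufficient to
  exercise one-step ancestor expansion), 1–6 leaf terms per protein, all
  IDRs of a protein sharing its labels;
* residues drawn i.i.d. from a disorder-like background (elevated P, S, E,
  K; depleted W, C, F, I; D+E at 12%);
* one planted signal: IDRs of proteins annotated with the first term have
  their D+E mass enriched to 30%, a strong but realistic compositional
  shift of the kind that links acidic IDRs to their functions;
* per-IDR noisy profiles: row $i$ of a PSSM is a Dirichlet draw with
  concentration `20 * onehot(residue_i) + 2 * background`, concentrating on
  the true residue while smearing substitution-like mass elsewhere.

What the generator does **not** emulate: positional sequence structure
(motifs, linear ordering — residues are i.i.d. given composition), real
GO DAG topology beyond two levels, homology structure between proteins,
PSI-BLAST's coverage gaps and e-value behaviour, or the extreme label
imbalance of real 130-term annotation. Passing tests therefore demonstrate
that the machinery recovers compositional signals and is calibrated under
the null; they do not certify real-data performance, where bigram and
profile features draw on exactly the positional information the generator
lacks.

Under these conditions the test suite checks, among else, that the
end-to-end pipeline (aa_composition → naive Bayes → 10-fold CV) recovers
the planted term with MCC > 0.3 while unsignaled terms stay below |MCC| <
0.15 (the signal term's own parent is excluded from the unsignaled set —
ancestor expansion makes its label correlated with the signal by
construction), and that with labels permuted across IDRs the mean per-term
MCC lies within ±0.05 of 0 with roughly half the terms on either side of
the random line (asserted as 20–80% of ~16 terms, ±2.4 binomial standard
deviations).

## Numerical and design choices

* **PSSM probabilities.** PSI-BLAST ASCII matrices carry both log-odds and
  weighted observed percentages. The default reading divides the percentage
  block by 100 and renormalizes rows (all-zero rows become uniform with a
  warning); a `logodds_sigmoid` mode maps log-odds through the logistic
  function instead, since which block a "relative probability" denotes is a
  genuine ambiguity of the format. Column order is taken from the file
  header and mapped to the canonical alphabet, so the PSI-BLAST ordering
  never leaks into feature space.
* **Short sequences.** Bigram extractors return all-zero vectors with a
  warning for $L<2$ (adjacent) or $L<3$ (gapped) instead of failing, so
  protein-level collation stays total; the zero rows then participate as
  ordinary instances.
* **Ambiguous residues** (B, Z, X, U, O) are dropped at input with a
  per-record count, as every descriptor is defined over the 20-letter
  alphabet only.
* **Determinism.** Every stochastic step (dataset generation, fold
  assignment, test-set sampling, PSSM noise) runs under an explicit seed in
  an isolated RNG scope, so identical seeds reproduce the full output
  bundle byte-identically.
* **Problem sizes in tests.** Oracle-equivalence suites use 100 random
  sequences of lengths 3–200; the statistical suites use the default ≈500
  IDR conditions; file round trips and pipeline smoke tests use 8–40
  protein datasets. These sizes were chosen as the smallest at which the
  asserted statistical properties are stable.

## Known limitations

Gaussian class-conditionals are a crude density model for probability-simplex
features; the classifier is used exactly because the scheme under study uses
it, not because it is optimal. Feature families are never combined, and no
per-term feature selection is performed — the design evaluates each family
separately. Protein-level fold grouping (keeping all IDRs of a protein in
one fold) is deliberately not applied; with many multi-IDR proteins the CV
estimates are therefore mildly optimistic for protein-level generalisation.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_proteins = 100, seed = 1)
ds  <- generate_dataset(cfg)
res <- run_pipeline(dataset = ds,
                    families = c("aa_composition", "sequence_bigrams"),
                    cv_seed = 1, pr_seed = 1)
res$averages
subset(res$metrics, term_id == names(ds$truth)[1])
plot(res$pr_curves$aa_composition)
```
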