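---
title: "codonmd: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codonmd: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonmd)
```

## The question and the test

The genetic code's degeneracy concentrates synonymous substitutions at
the third codon position. If synonymous sites carry a secondary,
biophysical function — maintaining the dynamic properties of the
nucleic acid polymer independently of the protein — then the *impact*
of synonymous mutations on those dynamics should be nonrandomly
distributed when the real code is compared to alternative codes with
the same degeneracy structure.

`codonmd` formalizes this as an exhaustive permutation test:

1. Score all 576 directed single-base codon transitions with a
   per-transition impact (dFLUX, dCORR, or dTRX).
2. Under a genetic code, classify each transition as synonymous (`S`)
   or nonsynonymous (`N`), and — using the reverse complement of each
   codon read 5′→3′ — as `SS`/`NN`/`SN` on the two strands.
3. Total the impacts per category for the canonical code.
4. Repeat for every one of the 13,823 alternative codes obtained by
   permuting the base alphabet independently at each codon position
   (24³ triples minus the identity).
5. Report the empirical p: the fraction of alternatives whose category
   statistic is ≤ the canonical one.

Because base permutations act position-wise and bijectively, every
alternative code preserves each label's codon count exactly (Leu = 6,
…, Met = Trp = 1, STOP = 3), and single-base neighbours map to
single-base neighbours — so the `S`/`N` category sizes (138/438 directed
transitions) are identical under every code; only *which* transitions
are synonymous changes.

## Impact metrics

**dFLUX and dCORR** come from per-codon MD summary profiles
(`codon_profile`): a per-atom fluctuation vector and an atomic
correlation matrix over the backbone atoms of the 5-nucleotide mask
(codon + 1 flank each side), averaged over replicate simulations. The
mask is reduced to a scalar by the arithmetic **mean** over atoms
(fluctuation) and the **mean off-diagonal** entry (correlation). The
upstream convention ("mask values") does not state the reduction; the
mean is scale-stable across mask sizes and is the default, with a sum
reduction available (`summarize_flux(reduce = "sum")`). A transition's
impact is the absolute before/after difference of these scalars, which
makes every impact table non-negative and symmetric under transition
reversal. Category statistics are **sums** for dFLUX/dCORR.

**dTRX** needs no simulation: TRX(seq) is the mean of dinucleotide
%BII-occupancy values over the L − 1 phosphate linkages of a sequence.
The 16-entry table ships as an editable text file
(`inst/extdata/trx_dinucleotide_table.tsv`), transcribed from the
published NMR-derived flexibility scale (the range endpoints are ApT = 0,
stiffest, and CpG = 43, most flexible; values are symmetric under
reverse complement because each base-pair step carries one value). It
is a *transcription* of a cited external table, not shipped by the
original analysis, so every table-dependent result should be read with
that provenance in mind. Category statistics for dTRX are **means**,
matching the metric's own per-linkage normalization.

### The dTRX window convention (a declared choice)

The upstream procedure computed flexibility "for each codon type"
without printing its sequence-context convention. `codonmd` scores the
5-mer window (codon + one flank per side) and averages |ΔTRX| over all
16 left×right flank-base pairs — the window matches the MD mask and the
averaging removes an arbitrary context choice (`dtrx_transition`,
`flanks = "average"`; any fixed flank pair can be requested instead).

This choice matters quantitatively. With the packaged table the
canonical dTRX p-values are S 0.857, N 0.144, SN 0.707, SS 0.771,
NN 0.222; published counterparts are S 0.882, N 0.188, SN 0.832,
SS 0.851, NN 0.118. The qualitative structure — synonymous flexibility
impacts *maximized* (high p(S)), nonsynonymous low — is robust: a
codon-only 3-mer window gives (S 0.918, N 0.085, SN 0.816) and
averaging contexts before the absolute value gives (S 0.935, N 0.066,
SN 0.824). No desk-scale convention reproduces all printed values
within 0.1 simultaneously; the residual disagreement concentrates in
the strand-symmetry categories, which are the most context-sensitive.
The default is declared, not fitted, and the acceptance test records
the SN discrepancy rather than widening its tolerance.

## Conventions and edge cases

- **STOP** is an ordinary 21st label with degeneracy 3: STOP→STOP is
  synonymous, STOP↔amino-acid is nonsynonymous. The permutation
  ensemble moves the stop block like any other degeneracy class.
- **Directed transitions.** All 576 ordered pairs are used; since
  |before − after| is symmetric, every category sum is uniformly
  doubled relative to unordered pairs and p-values are unchanged. The
  convention is recorded in result objects and run manifests.
- **Complementary strand frame.** The induced transition on the other
  strand is revcomp(from) → revcomp(to), each read 5′→3′ — the only
  frame defined by the codon alone.
- **Empty categories.** 384 of the 13,824 permutation codes have *no*
  `SS` transition (the reverse-complement pairing does not commute with
  position-wise permutation, so strand-category counts vary, 0–18 for
  SS). For a single code, `category_total(..., mode = "mean")` refuses
  an empty category; inside the exhaustive ensemble an empty category's
  mean is defined as 0 (no substitutions, no impact) so that the
  13,823-value distribution is complete. `S` and `N` are never empty.
- **ECDF ties** count as ≤ (standard empirical CDF). The canonical code
  is *not* a member of the ensemble.
- **RNA input** (U) is normalized to T on entry, so DNA and RNA share
  one codon space.
- **Numerical tolerances.** Parsed correlation matrices must be
  symmetric and unit-diagonal within 1e−6 (then symmetrized/snapped);
  replicate correlation averaging is entry-wise (Fisher-z deliberately
  not applied — the upstream averaging is plain).

## The synthetic generator: what it emulates and what it does not

`generate_profiles()` emulates *summary statistics* of replicate MD
runs — never the dynamics themselves. Defaults state the emulated
world: 50 replicates per codon (an implicit-solvent replicate set),
4 backbone atoms per nucleotide (20 mask atoms), a 1.0 Å baseline
fluctuation with 0.05 Å replicate/atom noise, 0.25 Å spread of
per-label levels, and a 0.1 Å per-G/C slope in the `gc_linear` model.
Correlation matrices mix three latent modes with noise and are
normalized, guaranteeing PSD with unit diagonal.

The three models bracket the hypotheses the pipeline must distinguish:

- `aa_determined` (zero noise) makes synonymous impacts *exactly* zero,
  so the canonical `S` total must be 0 and at or below every
  alternative — an end-to-end recovery test. (Exactly one non-identity
  triple ties it: the position-3 C↔T swap is an automorphism of the
  standard table, since NNC and NNT are always synonymous.)
- `gc_linear` (zero noise) has a closed-form impact table
  (`gc_linear_expected_impacts`): gc_slope for any G/C-changing
  substitution, 0 for A↔T and C↔G swaps.
- `iid_noise` makes the canonical code exchangeable with every
  alternative (iid per-codon levels are invariant in distribution under
  any codon relabeling), so its ensemble p must be approximately
  uniform across seeds — checked by a Kolmogorov–Smirnov test over 200
  seeds at α = 0.01.

A green synthetic test therefore establishes that the *bookkeeping* —
classification, ensemble enumeration, totals, ECDF — is correct, and
nothing about real nucleic-acid mechanics: there is no force field, no
solvation, no claim that the generator's correlation structure
resembles a real duplex. Conversely, the dTRX pipeline is real (its
input is the published flexibility scale), and its results can be read
scientifically, subject to the window-convention caveat above.

## Design choices where the design was open

- Codes are counted as permutation *triples* (13,823 alternatives),
  not deduplicated codon→label maps, reproducing the stated ensemble
  size; duplicate maps (e.g. the C↔T automorphism) are retained.
- The ensemble is evaluated by streaming over triples in chunks
  (`ensemble_scan`), so memory is bounded by one chunk of membership
  masks plus accumulators, never 13,824 stored code tables; the scan is
  vectorized and takes ~1 s for one impact table.
- "Outperforms X%" phrasing is ambiguous between tails; results print
  the raw ECDF p *and* `outperforms_pct = 100(1 − p)` so the direction
  is explicit.
- dFLUX scalar = mean (not sum) over mask atoms, and dCORR uses all
  atom pairs (not adjacent-only); both are the stable defaults of an
  under-specified upstream reduction, and the flux reduction is
  switchable.

## Limitations

- The MD-derived headline numbers from GPU-scale simulation campaigns
  (thousands of runs) are not reproducible here; the package
  substitutes property-based tests on the synthetic world for them.
- The dTRX table is a transcription of a published scale and the dTRX
  context convention is a declared default; both are sensitivity-tested
  but not independently verifiable offline.
- Only triplet codes reachable by position-wise base permutation are
  enumerated — no amino-acid permutation codes, no altered degeneracy,
  no doublet codes.

```{r example}
res <- run_ensemble_test(dtrx_impact_table())
res$summary
```
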