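---
title: "Models and methods behind miredit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind miredit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miredit)
```

## The analysis problem

Dual-sgRNA CRISPR/Cas9 editing of a miRNA locus in a tetraploid crop such as
potato produces a cascade of questions that this package answers
computationally, stage by stage:

1. **What was edited?** Cloned genotyping amplicons are aligned against up to
   four natural alleles, natural SNPs are masked, and each clone's
   difference operations are typed into the repair spectrum observed after
   paired Cas9 cuts: short deletions (1–6 nt), single-base T/G insertions,
   excision of the fragment between the two cut sites, and longer deletions.
2. **How much was edited?** A mixed direct Sanger read over a mosaic template
   is deconvolved into candidate-sequence proportions (an ICE-style
   knock-out score).
3. **Can the edited precursor still be processed?** Each mutated pre-miRNA is
   folded, and processing competence is predicted from the minimal folding
   free energy index (MFEI) and the miRNA/miRNA\* duplex geometry.
4. **What small RNAs does it actually make?** sRNA reads are trimmed,
   quality-filtered and mapped exactly; templated and non-templated (tailed)
   miRNA variants are called and filtered by a reciprocal exclusion rule.
5. **Do the variants still work?** Variant–target complementarity is scored
   with a penalty-based expectation score and a central-mispairing rule.
6. **What happened to expression?** miRNA, *Cas9* and target-transcript
   abundances are quantified by the relative standard-curve qPCR method
   against an endogenous control and the non-transgenic (NT) baseline.

Every wet-lab input has a seeded synthetic counterpart
(`make_locus()`, `simulate_edits()`, `simulate_amplicon_clones()`,
`simulate_sanger_trace()`, `simulate_srna_reads()`, `simulate_qpcr()`),
each of which returns a machine-readable ground truth, so the entire pipeline
is testable end to end without any external data.

## Genotyping

Clones are globally aligned (affine gaps) against every allele with
match +2, mismatch −3, gap opening 6 and gap extension 1 per gap base, a
scoring chosen so a 126-nt excision is represented as one long gap rather
than scattered fragments; ties go to the lowest allele index. Applying the
reported difference operations to the winning allele must reconstruct the
clone exactly — this invariant is asserted on every call.

Natural polymorphism is handled in two layers. First, best-allele alignment
absorbs most allelic variation. Second, any remaining substitution whose
coordinate and base match the NT panel (control-clone alignments plus, when
available, the locus's ground-truth SNP table) is masked. Indels are never
masked because natural alleles differ by SNPs only. Substitutions that
survive masking are retained in the difference table but are not typed as
mutation calls: the NHEJ repair spectrum modelled here contains no
substitutions, and typing them would inflate the mutated-clone counts with
sequencing artefacts.

Class assignment is span-based: deletions of 1–6 nt are `short_deletion`;
deletions at least as long as the inter-cut distance minus 4 nt that reach
within 4 nt of both cut sites are `inter_guide_excision`; remaining deletions
longer than 6 nt are `large_deletion`; insertions are typed with their base.
The 4-nt slack makes the excision call robust to alignment gap-sliding inside
sequence repeats, and the same predicate labels the simulator's ground truth,
so a 25-nt deletion that happens to span both cut neighbourhoods is an
excision on both sides of the comparison.

The knock-out score solves a non-negative least-squares problem: the observed
4×L base-proportion trace is approximated as a mixture of one-hot candidate
profiles (the unedited alleles plus deletions of 1–15 nt ending within ±4 nt
of either cut, single-base insertions at each cut, and the inter-guide
excision). Candidates indistinguishable over the window are collapsed; if an
edited and an unedited candidate collapse together the editing rate is
unidentifiable and a widen-window error is raised instead of a silent guess.
When the candidate set omits genuine natural alleles, part of the SNP signal
is absorbed by edited candidates and the score inflates — the documented
behaviour of trace-deconvolution screening on polymorphic controls,
reproduced in the test-suite.

## Folding and the impaired-processing rule

The internal folding engine is a Zuker-style dynamic program over a
nearest-neighbour model: Turner-2004 stacking free energies for Watson–Crick
and G:U pairs, hairpin/bulge/internal-loop initiations with
Jacobson–Stockmayer logarithmic extrapolation (hairpin 5.4 kcal/mol at 3 nt,
bulge 3.8 at 1 nt, internal 1.7 at 4 nt; 1.75·RT·ln extrapolation beyond),
an internal-loop asymmetry penalty of 0.6 kcal/mol per nt capped at 3.0, an
affine multiloop term (9.3 kcal/mol initiation, −0.9 per branch, free
unpaired bases), a 30-nt cap on two-sided loop size, minimum hairpin 3 nt,
and no dangling ends, coaxial stacking, or special tetraloop bonuses. All
arithmetic uses integer decacalories, so the traceback and the independent
loop-decomposition re-scorer (`structure_energy()`) agree exactly; the
test-suite verifies the engine against exhaustive enumeration of all
structures on hundreds of short random sequences. Ties between co-optimal
structures are broken deterministically (pairs preferred at the leftmost
opening position).

The engine is not intended to byte-match any external folding program —
`fold(engine = "vienna")` delegates to `RNAfold` when present as a validation
backend, and the two structures may differ in detail while feeding the same
downstream classifier. The classifier-relevant quantities (MFE level, MFEI,
duplex loops) are what the engine is accountable for.

MFEI is `(|MFE|/L × 100) / GC%` with GC on the 0–100 scale, so the classical
0.85 threshold applies directly. Processing is called impaired when
MFEI < 0.85 (strictly), when the miRNA/miRNA\* duplex contains an internal
loop larger than 5 nt (strictly), or when the precursor or its mature span
has been excised. Loop size is the total number of unpaired nucleotides on
both strands of one contiguous interior loop bounded by duplex pairs; because
usage in the field is ambiguous between per-strand and summed measures, the
per-strand maximum is also reported for sensitivity analysis but does not
enter the call. The star span is inferred from the pairing partners of the
miR-5p bases plus the canonical 2-nt 3′ overhang, with an annotated miR-3p
span taking precedence when provided. A mature span shorter than 16 nt is
treated as excised: canonical plant miRNAs are 20–24 nt, so a precursor that
has lost more than a few mature bases cannot produce one, and simulated
processing of such precursors yields no reads.

## sRNA variant discovery

Preprocessing removes the 3′ adapter at its leftmost anchored occurrence
(≥6-nt prefix match), then truncates each read at the first base with
phred ≤ 20 — so every retained base exceeds the quality threshold — and keeps
reads of 18–30 nt (whole-read discard is available by configuration).
Mapping is exact-substring, sense strand only, no mismatches, backed by a
hashed substring index; every matching precursor is recorded and a variant is
`unambiguous` only when it has exactly one source. Mapped reads are
`canonical` or `templated` (end-shifted); unmapped reads that become exact
substrings after stripping ≤3 nt from one end are `non_templated` with the
tail recorded (longer matching core preferred, ties to the 3′ end, mirroring
single-end isomiR modification classes). cpm uses the per-sample clean-read
total as denominator. Variants totalling 1–2 reads are kept but flagged
`low_abundance` rather than silently dropped.

The exclusion filter reports a variant for a line group only when it has at
least one read in the group and exactly zero reads in every control sample
(NT plants and lines edited at the reciprocal locus, where the tested locus
is untouched). This guarantee is asserted, not estimated: the test-suite
checks zero control-sample leaks on every run.

## Target scoring

Complementarity is scored per miRNA position against the antiparallel target
site: mismatch 1, G:U wobble 0.5, gap 2 per gapped position, positions 2–13
double-weighted; the summed penalty is the expectation score (0 = perfect
complement) and hits are reported up to a cutoff of 3, the strict setting for
plant miRNA target screening. One bulge of at most 2 nt is allowed per site,
reflecting the near-perfect complementarity of plant targets and keeping the
transcript scan quadratic; the scan itself uses cumulative penalty sums so
every single-bulge placement costs O(1). A hit is non-functional regardless
of score when three or more consecutive mispaired positions intersect miRNA
positions 12–14 — mispairing in the central region abolishes
cleavage guidance. The exact psRNATarget weight schema is not published in
full; these weights live in `target_weights()` so the cutoff semantics can be
recalibrated.

## qPCR quantification

`fit_curve()` is ordinary least squares of Cq on log10 quantity;
amplification efficiency is `10^(−1/slope) − 1`, so the canonical −3.3219
slope gives 100%. `quantify()` inverts the per-assay curve per well,
corrects for dilution, averages duplicate wells and the two dilutions (10-
and 50-fold) on the quantity scale, flags wells disagreeing by more than
0.5 Cq, normalises by the endogenous control, and scales to the arithmetic
mean of the NT samples. Undetected reactions must be recorded as missing,
never zero; samples lacking a control Cq are skipped with a record rather
than imputed.

## What the synthetic data does and does not emulate

The generator reproduces the statistical structure the analysis relies on:
up to four alleles differing by ~1% SNPs over an 800-nt amplicon; a stem-loop
precursor whose miRNA/miRNA\* duplex carries two single-base mismatches
(real duplexes are imperfect; the wild type is validated to classify as
processable at construction); dual guides with NGG PAMs cutting 3 bp 5′ of
the PAM at the mature-miR boundaries; an edit spectrum dominated by short
deletions with 1-nt T/G insertions, inter-guide excisions and longer
deletions, jittered uniformly within ±4 nt of the cut; mosaic lines with
several distinct outcomes; 50-bp single-end reads with adapters, phred ~30
qualities, end-shifted templated variants and 1–3-nt non-templated tails;
and Cq tables with Gaussian noise over duplicate wells and two dilutions.

It does not emulate chromatogram files (the base-proportion trace matrix is
the surrogate), transformation efficiency, phenotypes, position-dependent
sequencing error, PCR amplification bias, or genome-scale backgrounds (the
unrelated-sRNA background is uniform random sequence). Passing tests
therefore demonstrate the correctness and calibration of the analysis logic
under the modelled conditions, not robustness to every artefact of real
libraries.

Defaults worth knowing (all configurable): amplicon 800 nt; edit-class
probabilities 0.15/0.45/0.10/0.10/0.10/0.10 for
none/short-deletion/insT/insG/excision/large-deletion; jitter ±4 nt;
mosaicism 4 outcomes per line; 10 clones per line; trace noise 0.02; read
depth per library and a 30% background fraction; tailing probability 0.1 in
read simulations; leaky processing of impaired precursors 0 (exposed because
residual expression is observed in fully mutated lines); qPCR slope −3.3219,
intercept 35, noise 0.1 Cq; NT baseline averaged over ten samples. The
line-truth coupling used by the simulator sets a line's canonical-miRNA
quantity to its processable clone fraction (plus leak) and its target
quantity to `1 + 0.8 × (1 − miRNA)`, a simple monotone de-repression model
sufficient to express the expected anti-correlations.

## Numerical and engineering choices

- 0-based half-open coordinates everywhere internally (cut sites fall
  between bases, so interval arithmetic is exact); 1-based conversion only in
  rendered reports.
- Integer decacalorie energies eliminate floating-point equality hazards in
  the folding traceback and oracle comparisons.
- All generators are pure functions of their seed (`withr::with_seed`);
  pipeline stages derive per-stage seeds from the single top-level seed, so
  a config is exactly reproducible and artifact TSVs are byte-identical
  across reruns.
- Degenerate inputs fail with classed conditions (`miredit_bounds_error`,
  `miredit_widen_window_error`, `miredit_degenerate_duplex`, ...) rather
  than producing silent NA results.
- Problem sizes in the shipped tests were chosen to exercise the claimed
  error rates meaningfully: 200 sequences for the folding oracle, 1000
  clones per edit class for genotyping recovery, a proportion grid at 2%
  trace noise for deconvolution, and 10^5 reads per library across six
  libraries for variant precision/recall.

## Known limitations

- The energy model omits dangles, coaxial stacking and tetraloop bonuses, so
  absolute MFEs differ from full Turner implementations by a few percent;
  threshold-adjacent MFEI decisions on real data should be cross-checked
  with the external backend.
- Only terminal non-templated additions are modelled and called; internal
  editing classes of isomiR pipelines are out of scope.
- The knock-out score's candidate grammar covers the repair classes the
  genotyping module can call; exotic outcomes (inversions, large insertions)
  would be absorbed by the closest candidate.
- Target scoring has no accessibility/energy term; it ranks complementarity
  only.
- The pipeline's abundance truth couples processing to expression through a
  deliberately simple monotone model; it supports qualitative sign tests,
  not effect-size claims.
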