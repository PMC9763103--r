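---
title: "Detecting IBD risk haplotypes in a deep founder pedigree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting IBD risk haplotypes in a deep founder pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderscan)
```

## The problem

In a genetic isolate, a deep pedigree densely affected by a heritable
disorder can descend from a handful of founder couples. When affected
individuals who are only distantly related — separated by six or more
meioses — nevertheless share a multi-megabase chromosomal segment
identical by descent (IBD), that sharing is improbable by chance and worth
investigating: rare variants riding on such a shared haplotype are
candidate risk variants. `founderscan` implements this strategy as a
reusable pipeline: phased genotypes go in, and a short table of putative
risk haplotypes and rare haplotype-specific deleterious variants comes
out. Because the motivating data type (whole-genome sequence from named
family members) is access-controlled, the package pairs the pipeline with
a gene-dropping simulator that generates data with the same structure and
a complete transmission ground truth, so every stage can be validated
quantitatively.

## Pipeline overview

1. **QC** (`apply_qc`): marker/sample filters before IBD detection —
   per-marker missingness < 0.01, per-individual missingness < 0.05, exact
   Hardy–Weinberg p ≥ 0.001, MAF > 0.05, removal of markers with Mendelian
   inconsistencies in genotyped parent–offspring pairs, then LD pruning
   (500 kb windows, 50-marker step, r² ≤ 0.6).
2. **Pairwise IBD** (`pairwise_ibd`): seed-and-extend detection on phased
   haplotypes, scored by a LOD — the log10 likelihood ratio of IBD versus
   non-IBD. Segments must exceed 1 Mb and LOD 3.
3. **Multi-IBD clustering** (`multi_ibd_clusters`): haplotypes carried by
   three or more haplotype copies, found as connected components of the
   pairwise-segment graph in 250 kb windows.
4. **Filter cascade** (`filter_cascade`): length > 1 Mb; at least three
   carriers descending from the same founder pair; absence from two
   array-genotyped population control cohorts; a tic-spectrum diagnosis in
   every carrier; boundary re-definition on the full phased data.
5. **Fine-mapping** (`fine_map`): the haplotype's full allele sequence —
   a backbone from the phased markers plus, for WGS-only sites, an allele
   inferred from the genotype contrast between carriers (respecting their
   IBD1/IBD2 copy number) and non-carriers; uninformative sites stay
   explicitly unassigned.
6. **Prioritization** (`prioritize_variants`): haplotype-specific variants
   (alternate allele absent from all non-carriers) are classified rare
   (MAF < 0.01) or ultra-rare (MAF < 0.001) in the reference population,
   then filtered for deleteriousness — coding: protein-impact consequence,
   SIFT deleterious, PolyPhen damaging and CADD > 20; non-coding:
   CADD > 10 and ncER percentile > 95.

## The LOD model

For a pair of haplotypes at a site with alternate-allele frequency $f$ and
allele-error rate $\varepsilon$,

$$
\mathrm{LOD} = \sum_i \log_{10}
\frac{\sum_{c}\, f_c\, q(a_i \mid c)\, q(b_i \mid c)}{f_{a_i} f_{b_i}},
\qquad q(x \mid c) = \begin{cases} 1-\varepsilon & x = c\\
\varepsilon & x \neq c \end{cases}
$$

the numerator marginalising over the latent shared allele $c$. The score
is additive over sites; a matching rare allele contributes up to
$\log_{10}(1/f)$, and $\varepsilon$ (default 0.0025) caps the penalty of
a mismatch so that isolated haplotype errors do not sink a long segment.
The published analysis used an HMM-based detector; this package specifies
its own transparent detector because only the thresholds (length > 1 Mb,
LOD > 3) and the LOD definition are contractual — agreement is assessed
by truth recovery, not score equality. Candidate segments are seeded by
runs of 64 identical non-missing alleles, extended while the cumulative
LOD stays within 2 of its running maximum, trimmed to the LOD argmax, and
segments of the same haplotype pair separated by less than 0.6 cM are
merged — isolated switch errors otherwise split long true segments, and a
companion merge step is standard practice for IBD detectors.

## What the simulator emulates — and what it does not

`simulate_study()` reproduces the *structure* of the study: six labelled
founder couples at generation 0; descent chains (with unlabelled
married-in founders) to 19 sampled individuals in the last two
generations, whose founder-pair ancestries mirror the published carrier
matrix and whose pairwise meiotic distances are at least 6; gene dropping
with Poisson crossovers (no interference) on a linear 1 cM/Mb map;
haplotype allele errors at rate 0.001; a planted multi-megabase risk
haplotype from founder pair B carrying one qualifying deleterious missense
variant and one sub-threshold intronic variant; a second planted haplotype
from pair D spiked into the controls as a population-common probe; and two
control cohorts of 49 and 42 array-genotyped individuals. The phenotype
model is penetrance/phenocopy Bernoulli (defaults 0.8 / 0.1) with optional
ascertainment matching that forces the published design count of 17
affected among 19 sampled; forced flips never override deterministic
settings (penetrance exactly 0 or 1), so validation scenarios with
`penetrance = 1, phenocopy = 0` keep the affected set identical to the
carrier set.

Two deliberate departures from naturalism matter for interpretation.
First, background markers are drawn i.i.d. from a Uniform(0.05, 0.5)
frequency spectrum with no linkage disequilibrium, so the LD-pruning stage
has little to remove in simulation; its correctness is instead established
by unit tests with planted correlation. Second, transmission to the
designated carriers is *steered*: at each meiosis along the descent chain
the (symmetric) starting-phase choice is conditioned so the planted
haplotype's midpoint is carried through. Without steering a planted
haplotype survives five independent meioses to three designated relatives
with probability about $2^{-15}$, so unconditioned simulation could not
emulate a study that by design ascertained carriers. Crossovers are still
drawn unconditionally, so segment ends erode naturally and the shared core
shrinks realistically. Consequently, passing tests demonstrate that the
pipeline recovers what the generator planted under realistic recombination
and error — not that real LD structure, real allele-frequency spectra or
real phasing errors are handled; on real data the phasing and QC stages
carry assumptions this simulator does not test.

Desk-scale defaults are two 50 Mb chromosomes with 100 markers/Mb
(WGS-like) and a 20 markers/Mb array subset: large enough that planted
~3.5 Mb haplotypes are detected with sub-window boundary error, small
enough that a full simulate–detect–filter–prioritize cycle takes seconds.

## Numerical and algorithmic choices

* **Exact Hardy–Weinberg test.** With 19 sampled individuals an asymptotic
  chi-square test is invalid, so the conditional exact test is used: the
  distribution of the heterozygote count given allele counts, computed by
  a mode-anchored recurrence; the two-sided p-value sums probabilities not
  exceeding the observed one. The test suite checks it against a direct
  factorial-formula enumeration for every genotype table up to n = 50.
* **LD pruning determinism.** Within a window the highest-r² violating
  pair is resolved first, removing the lower-MAF member (ties: the later
  position). Because a 50-marker step can leave adjacent-window pairs
  unexamined on sparse panels, a closing sweep guarantees that no retained
  pair within 500 kb exceeds the threshold; the result is idempotent and
  independent of marker labels.
* **Boundary refinement.** Clusters found on pruned markers are re-defined
  on the full phased data. Each member copy is compared with the member
  consensus and extended outward from the interval midpoint: isolated
  mismatches (the haplotype-error regime, about 1 per 1,000 markers) are
  crossed, but five mismatches within 20 markers — the density signature
  of the copy leaving the shared haplotype for its own background, where
  disagreement runs at 30–40% per marker — stop the extension, which is
  then trimmed back to the last run of 10 clean markers. The refined
  interval is the intersection of member boundaries. The strict
  `max_mismatches = 0` mode stops a member at its first flanking mismatch.
* **Fine-mapping contract.** The backbone assigns only unanimous phased
  alleles. `build_backbone()` errors on disagreement by default (the
  refinement contract), but `fine_map()` defers disagreeing sites to
  genotype-based assignment, because isolated backbone disagreements are
  the expected signature of haplotype error, and the genotype route
  handles them with an explicit discordant flag instead of a hard stop.
  `assign_allele()` assigns an allele only when every carrier's genotype
  can place it on the shared copies (IBD2 carriers must be homozygous),
  using non-carriers only to break two-sided ties; the suite verifies it
  against exhaustive enumeration of all diplotype configurations with up
  to four carriers and four non-carriers.
* **Control screen.** Controls are unphased array data, so the screen asks
  genotype consistency (dosage of the backbone allele ≥ 1 at every shared
  marker, at least 20 markers required) rather than phased identity, with
  zero tolerated inconsistencies by default. This is conservative in the
  published direction: any fully consistent control — including one
  matching a genuinely common haplotype by chance — removes the candidate.
* **Degenerate inputs.** Monomorphic sites get HWE p = 1; sites with
  allele frequency 0 or 1 are skipped in the LOD with a warning; markers
  with all alleles missing have undefined (NA) frequency; an empty
  post-QC panel, a carrier with empty founder ancestry, a cluster whose
  members disagree across most of their interval, and a control screen
  with under 20 shared markers are all hard errors rather than silent
  passes (inside the cascade, an unevaluable control screen removes the
  candidate conservatively instead of aborting the run — absence from
  controls cannot be demonstrated for it).

## Open design points, resolved

* *Which individuals enter the HWE test in a pedigree sample?* Default:
  all sampled individuals (the apparent published practice); a
  `hwe_samples` argument restricts the test to a founder-independent
  subset.
* *Does the carrier-phenotype filter admit probable diagnoses?* The
  affected predicate (confirmed or probable TS or chronic motor/vocal tic
  disorder) is used, since the published haplotype table retains a CMVT
  carrier; `confirmed_only = TRUE` gives the stricter reading.
* *PolyPhen acceptance.* "Possibly damaging" passes by default, because
  the published pass set contains such a variant; `strict_polyphen`
  implements the narrower text reading. Similarly, coding variants require
  CADD *and* the SIFT/PolyPhen predictors by default, with
  `cadd_or_predictors` for the disjunctive reading.
* *Two printed haplotype lengths disagree with their own coordinates.*
  The fixtures store the printed values verbatim and flag the two
  discrepant rows; nothing guesses the intended value.

## Validation scales

The replicate validation (the acceptance script and the heaviest test)
runs 20 simulated studies at the default desk scale — two 50 Mb
chromosomes, 19 sampled individuals, penetrance 1 and phenocopy 0 so the
haplotype/phenotype correlation is exact — and requires the planted
haplotype to survive the full cascade with refined boundaries within
0.25 Mb per end of the true shared segment, the planted deleterious
variant to be the unique prioritized variant, and the control-spiked
haplotype to be removed in every replicate. Boundary truth is the
intersection of the carriers' true founder-haplotype runs, which typically
extends beyond the planted interval because carriers share the founder
chromosome around it. The kinship check simulates third cousins on an
18-chromosome, 1,800 cM genome, where expected sharing (~4–5 segments)
makes the degree estimate stable. These sizes were chosen so the whole
suite runs in minutes on one CPU while keeping every planted signal well
above the detection thresholds.

## Known limitations

No background linkage disequilibrium or coalescent realism; no interference
in the crossover model; sex chromosomes and multi-allelic sites are out of
scope; IBD detection requires phased input and does not re-phase; the
deleteriousness scores (SIFT, PolyPhen, CADD, ncER) are consumed as given —
the package never computes them — and ncER values missing from unstable
assembly conversion simply fail the non-coding branch with a reason code.
The published genome-wide cluster count (339 on the real data) depends on
the protected genotypes and is not reproducible at desk scale; the package
reproduces the logic of the cascade, the table arithmetic, and the planted
recovery statistics instead.
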