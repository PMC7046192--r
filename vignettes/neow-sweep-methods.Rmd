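---
title: "Models and methods behind neowsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neowsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system being modelled

In the African monarch butterfly (*Danaus chrysippus*) a contact-zone
population carries a *neo-W chromosome*: an autosome (chromosome 15, which
harbours the BC colour-pattern supergene) fused to the female-limited W.
Because female meiosis in Lepidoptera is achiasmatic, a female transmits
whole chromosomes intact, so the fused chromosome 15 travels mother to
daughter as a single non-recombining haplotype — together with the
mitochondrion and a maternally inherited, male-killing *Spiroplasma*
endosymbiont. The three molecules are physically unlinked but strictly
co-transmitted: as the male-killer spreads, the particular chromosome 15
haplotype captured by the fusion hitchhikes to high frequency, carrying one
supergene allele and any mildly deleterious variants that happened to sit
on it.

`neowsweep` implements, end to end, the analyses by which such a sweep is
discovered and characterised from whole-genome resequencing data — window
differentiation scans, genotype-phenotype association, supergene haplotype
painting, diagnostic-site detection with haploid neo-W reconstruction and
dating, frequency-stratified Pn/Ps, and a Procrustes test of host-symbiont
genealogical congruence — and couples them to a forward simulator of the
whole inheritance system, so that every inference stage can be validated
against ground truth without any external data.

## The forward simulator

### Inheritance model

Each generation is non-overlapping. An offspring's sex is decided by which
sex chromosome its mother transmits: daughters receive the W side and with
it, when the mother carries the fusion, the fused chromosome 15 haplotype,
intact; sons receive the Z-side copy. Fathers transmit chromosome 15 and a
control autosome with Poisson-distributed crossovers (default 1 per
chromosome per meiosis); crossover breakpoints are suppressed inside the
supergene interval, reflecting the recombination suppression that defines a
supergene. The mitochondrion is clonally maternal. The symbiont passes from
mother to offspring with fidelity `transmission` (default 1); infected sons
die with probability `mk_penetrance` (default 1 — broods of infected
mothers are effectively all-female); mothers of infected broods receive a
fitness weight `1 + brood_advantage` (default `s = 0.1`) when daughters are
drawn, the resource-compensation advantage that lets the male-killer
invade. Each offspring's father is an immigrant from a source pool with
probability `migration` (default 0.8, "most males are immigrants"), and the
pool is fixed for the dorippus supergene allele.

Every transmitted haplotype gains `Poisson(mu * L)` new mutations at
uniform positions (infinite-sites; new positions are rejected against the
standing-site registry, leaving a residual new-vs-new collision probability
of order 1e-3 which we accept as recurrent mutation). Mutations are stored
as position sets, never sequence arrays.

### Standing variation and the burn-in

The focal deme is a small sample of a species whose effective size is
enormous (background differentiation near zero; autosomal diversity around
0.023/bp, among the highest known in animals). A desk-scale deme cannot
carry that diversity by its own mutation-drift balance, so founder and
immigrant haplotypes are seeded from a neutral 1/f frequency spectrum
calibrated to `source_pi` (default 0.0228/bp, the empirical autosomal
value), with sites in linkage equilibrium — the signature of a huge,
panmictic, freely recombining source. The focal deme is then burned in
forward for `burn_in` generations (default `10 * (n_females + n_males)`);
with heavy male immigration the deme sits at immigration-mutation balance
and retains source-level diversity indefinitely. Setting `source_pi = 0`
recovers a pure forward-mutation run from a monomorphic start, which the
test suite checks against Watterson's expectation.

Inside the supergene interval the three alleles (chrysippus/alcippus,
dorippus, orientis) are modelled as old, diverged, low-diversity clades:
per-allele private fixed differences at density `sg_div` (0.005/bp) and
within-allele polymorphism at `sg_within_pi` (0.004/bp). This is what makes
per-window distance-based painting meaningful, and reproduces the empirical
pattern of differentiation islands confined to the supergene.

Coding genes (stop-free random reading frames, default 900 bp spaced every
30 kb) tile the colinear part of chromosome 15 and the control autosome.
Standing variants falling on 0-fold degenerate positions carry a purifying-
selection footprint: only a fraction `del_keep` (0.25) of candidate sites
segregate, and their frequencies are capped at `del_max_freq` (0.05). No
per-generation fitness is computed from them — over the century-scale sweep
the relevant consequence of purifying selection is simply that
non-synonymous standing variants are rare, and the hitchhiking of the rare
variants sitting on the foundress haplotype follows from co-transmission
alone. Setting `del_keep = 1, del_max_freq = 0.99` gives a fully neutral
genome, used as the null in the Pn/Ps tests.

### The fusion event and conditioning

At `t_fusion` a single random female becomes the foundress: she turns
infected, receives a founding symbiont genome, and her maternal chromosome
15 is replaced by a fresh source-drawn haplotype carrying the
`foundress_allele` (default chrysippus — the neo-W carries the recessive
colour allele, so infected females are heterozygous against the dorippus
haplotypes their immigrant fathers supply, the transiens configuration) and
flagged as fused to the W. A single new copy is usually lost by drift, so
by default `run_simulation()` retries the post-fusion phase (from the saved
fusion-time state, with a fresh random foundress) until the lineage
survives to the end of the run — the generator models the invasion we
observe, exactly as sweep simulations condition on establishment. The
neutrality checks in the test suite disable this conditioning.

With complete male killing and perfect transmission the deme's females fix
for infection and resident males disappear; reproduction continues through
immigrant fathers. The default cohort design therefore draws its uninfected
comparison individuals (and its males) from the allopatric populations.

### Cohorts, fragments, and what the generator does not emulate

`sample_cohort()` draws a 42-individual, multi-population design by
default: 15 infected neo-W females from the contact zone plus three
9-individual allopatric subspecies samples synthesised from the source
spectrum with their population's supergene allele fixed. It emits diploid
genotypes (phase lives only in the ground truth), simulated per-call depth
and quality, phenotype scores (0/0.5/1 per colour locus, with dorippus
heterozygotes expressing the intermediate transiens phenotype with
penetrance 0.5), and phased fragments over chromosome 15 — geometric
length (mean 500 bp), uniform placement, expected per-haplotype depth 10 —
the desk-scale stand-in for read pairs used by the neo-W reconstruction.
Fragments are error-free and perfectly phased: they exercise the
linked-variant rescue logic, not sequencing noise. Likewise the generator
has no genotyping error, no missingness (beyond what a filter policy
introduces), no spatial structure beyond one deme plus a source pool, and
no selection on individual mutations; passing tests therefore demonstrate
the correctness of the inference machinery under the stated inheritance
model, not robustness to every artefact of real sequencing data.

## Analysis conventions and numerical choices

* **Coordinates** are 0-based half-open internally; VCF positions convert
  at the file boundary. Sliding windows (default 100 kb, step 20 kb) start
  at 0 and only full-width windows are emitted.
* **Genotype filters**: calls need depth >= 8; heterozygous and
  alternate-homozygous calls additionally need GQ >= 20;
  reference-homozygous calls survive any quality (the asymmetric
  convention of the original genotyping). Calls lacking a DP/GQ tag pass by
  default (`missing_tag_passes`). Missingness is first-class and never
  imputed.
* **pi / dXY / FST**: per-site expected heterozygosity without replacement;
  cross-population mismatch probability; Hudson's `1 - pi_within / dXY` as
  a ratio of window sums (robust to sample-size imbalance). Windows with
  fewer than 20,000 genotyped sites are null-flagged. For simulator output
  every reference position is callable, so denominators are per base pair;
  for a plain variant VCF they are per genotyped variant site.
* **Association**: biallelic SNPs genotyped in >= 40 individuals, minor
  allele count >= 2, heterozygous in <= 75% of individuals, thinned greedily
  left-to-right to >= 100 bp spacing; ordinary least squares of the 0/0.5/1
  score on allele dosage, Wald statistic `(beta/SE)^2` with a t reference;
  top hits at the 0.9999 nearest-rank quantile with ties kept and
  nearest-gene annotation by midpoint distance.
* **Painting**: each 20-kb window is analysed separately (the real-data
  workflow does this to contain phasing switch errors); a haplotype joins
  the reference group whose mean distance is strictly less than 0.8 times
  the mean of the other two group means (the "mean of the two group means"
  reading of the ambiguous rule; a pooled alternative is provided).
  Distances need >= 100 pairwise-complete sites. The assignment is
  scale-invariant, and the strict inequality is guarded against
  floating-point ties so an exact-boundary case stays unassigned.
* **Diagnostic sites** must be heterozygous in every carrier and absent
  from every genotyped non-carrier and outgroup; by default no missing
  non-carrier is tolerated (a flag relaxes this). Note that sites
  satisfying the rule are of two kinds — mutations that arose on the fused
  lineage, and foundress-private standing variants — and both genuinely
  mark the neo-W; the phase-truth validation counts both as correct.
* **Reconstruction** attributes a fragment to the neo-W when it covers a
  diagnostic site and carries its allele; calls need support >= 3 (the
  haploid minimum-depth rule). The per-carrier >= 3x mask is kept so that
  haploid diversity is a per-base-pair quantity directly comparable with
  window pi.
* **Divergence test**: non-overlapping 100-kb windows over the colinear
  region (>= 11 Mb on the real chromosome; the simulated colinear interval
  otherwise), per-window mean heterozygosity of carriers vs wild-type,
  two-sided Wilcoxon signed-rank on the paired differences with zeros
  dropped; exact below 25 non-zero differences, normal approximation
  otherwise.
* **Dating**: the moment estimator `T = pi / (2 mu)` under a star-genealogy
  approximation, with 12 generations per year for unit conversion. It
  deliberately replaces Bayesian genealogy dating and is validated by
  simulation recovery, not against any posterior summary. Two caveats are
  inherent: it estimates the mean pairwise coalescence time, a lower bound
  on the root age under non-star genealogies; and in a small matrilineal
  deme sampled long after fixation, ongoing drift re-coalesces the neo-W
  copies and erodes the signal — the recovery tests therefore use demes
  large relative to the sweep duration sampled near fixation, which is
  also the empirical regime (effective size of order 1e6 against a
  26,000-generation sweep).
* **Pn/Ps**: 0-fold and 4-fold positions classified only when the other
  two codon positions are invariant across the entire dataset; counts
  restricted to sites genotyped in every cohort member; folded
  minor-allele-count classes 1..N for N diploid samples; ratios normalised
  by classified site totals. The bootstrap resamples genes (sites would
  ignore linkage; 100-kb blocks are a switchable alternative), reports the
  one-sided direction p-value `1 - k/n` bounded below by `1/n`, and treats
  a zero observed difference as having arbitrary direction.
* **Congruence**: missing-aware mismatch distance matrices (sites missing
  in > 20% of taxa dropped first — the automated stand-in for manual
  exclusion of inconsistently covered regions); neighbor joining and
  principal coordinates through ape (Cailliez correction when any
  eigenvalue is below -1e-8, since mismatch matrices need not be
  Euclidean); the Procrustes statistic m2 is the normalised residual of the
  least-squares superimposition after centring and unit-trace scaling, so
  it is invariant to rigid motions and rescaling of either configuration;
  the permutation p-value uses the add-one convention so perfect congruence
  reports a bound, never zero.
* **Copy-number genotyping** classifies the median normalised depth against
  anchors 1 / 0.5 / 0 with a +/-0.2 call band; outside the bands the sample
  is a no-call.
* **Mitochondrial clades** are single-linkage clusters cut at 10% of the
  mean pairwise distance: matrilines are separated by deep standing
  divergence, within-matriline distances by the handful of mutations of the
  sweep's timescale, so any cut in the wide gap between the two scales
  recovers the matrilines.

## Problem sizes

The package's own validation runs at deliberately small scale: the shared
simulated cohort uses a 60-individual deme with 200-kb chromosomes over
~200 generations; property checks average 10 replicates of a 48-individual
deme with 150-kb chromosomes; the root-age and congruence positive
controls use 5 replicates of a 300-individual deme sampled near fixation;
the end-to-end demonstration and the acceptance computation run the full
default configuration (200-individual deme, 1-Mb chromosomes, 2,000
burn-in generations, 150 post-fusion generations, 42-sample cohort). The
scaled configurations preserve the dimensionless quantities the inferences
depend on — diversity-to-divergence ratios, diagnostic-site counts, and
the deme-size-to-sweep-duration ratio where it matters (above).

## Design choices on open points

* The generator's undocumented rates default to `s = 0.1` for the
  infected-brood advantage and `tau = 1` for transmission fidelity;
  neither is an empirical estimate.
* The reader's policy for calls lacking DP/GQ tags defaults to passing.
* Thinning keeps the first passing SNP scanning left to right.
* The heterozygote fraction in the association filter is taken among
  non-missing calls.
* "Genotyped site" for window thresholds means a site with calls in every
  population involved in the statistic.
* The per-window minimum of 100 pairwise-complete sites for painting
  distances, and the 0.1 depth fraction for the symbiont infection call,
  are package defaults where the source workflow states none.
* Reference groups for painting are used as given; putative recombinants
  are flagged downstream rather than excluded upfront.

## Known limitations

Real-data use requires externally phased haplotypes for painting (the
package consumes phase; it does not infer it) and alignment-derived
fragments for the neo-W reconstruction (an adapter, not core). The moment
estimator dates the mean pairwise coalescence, not a posterior root age.
The simulator's single-deme, male-immigration geography cannot represent
clines or multiple contact zones, and its error-free fragments make the
reconstruction's accuracy ceiling 100% rather than coverage-limited.
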