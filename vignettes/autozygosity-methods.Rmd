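---
title: "Pedigree and genomic inbreeding from runs of homozygosity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree and genomic inbreeding from runs of homozygosity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

This vignette documents the models behind `autozyg`, the parameters that
matter and their defaults, the numerical conventions, and what the
simulation-based validation does and does not establish.

## Pedigree inbreeding

Wright's inbreeding coefficient $F$ of an individual is the probability that
its two alleles at a locus are identical by descent; it equals the kinship
coefficient of its parents. `compute_f_ped()` evaluates $F$ exactly by a
tabular recursion over a topological order of the pedigree. For each
non-founder with parents $s$ and $d$ it accumulates, over the ancestor set,
the within-family gene contributions $L_j$ of a virtual progeny of $(s, d)$
together with the Cholesky diagonal terms
$D_j = \tfrac12 - \tfrac14(F_{s(j)} + F_{d(j)})$ of the additive
relationship matrix, giving $1 + F$ as the progeny's relationship diagonal.
This is algebraically the same quantity every exact pedigree algorithm
computes; the recursion is $O(n \cdot |\text{ancestors}|)$ with $O(n)$
memory, comfortably handling the deep multi-generation pedigrees produced by
the simulator.

Conventions, chosen where registries differ and applied consistently:

* Unknown parents make an individual a founder with $F = 0$; an animal with
  exactly one known parent also gets $F = 0$ (its parents cannot share
  recorded ancestry). No phantom-parent grouping or unknown-ancestor
  imputation is attempted.
* Parents named in the file but never defined as rows are appended as
  founder records, so every pedigree validates or fails loudly (cycles are
  reported with an individual on the cycle).
* $F$ is stored as a proportion everywhere; only presentation functions
  (`trend_delta()`, plots) multiply by 100.

Two independent oracles guard the implementation: `wright_path_oracle()`
literally enumerates common-ancestor paths and sums
$(1/2)^{n_s + n_d + 1}(1 + F_A)$, and the test suite carries a recursive
kinship oracle; both must agree with the recursion to $10^{-12}$ on
hundreds of randomly looped pedigrees.

Per-year trends default to the **median**, the robust choice for skewed $F$
distributions; `summarize_f_by_year()` accepts `"mean"` as well, and
`trend_delta()` simply differences the chosen statistic between two years on
the percent scale. When both statistics are of interest they should be
reported side by side, since in strongly skewed years they can differ
noticeably.

## Genotype quality control

Panels genotyped on different arrays are merged on the *triplet* (SNP name,
chromosome, position); a SNP whose name appears in both panels with
conflicting coordinates or alleles is excluded and logged rather than
silently harmonised, and non-autosomal SNPs (anything outside chromosomes
1–31, the equine autosome set) are dropped at merge time. Allele orientation
is cosmetic — the reference allele is the alphabetically first observed
allele — because every downstream statistic (MAF, call rate, the HWE test,
genotype correlation) is orientation-invariant.

Filters run in the conventional order: individuals with more than 15%
missing calls first, then SNPs, each removed SNP counted under the first
criterion it fails (MAF, then HWE, then call rate). All thresholds are
**strict** inequalities — a SNP survives only with MAF $> 0.01$, HWE exact
$p > 10^{-4}$ and call rate $> 0.95$. One pass of each filter is applied;
the pair of passes is idempotent on its own output, which the tests check.

The Hardy–Weinberg test is the plain two-sided exact test conditional on the
allele counts: with $n$ individuals and $n_A$ copies of the rarer allele,
the probability of $n_{AB}$ heterozygotes is evaluated by the stable
recurrence from the distribution mode, and the p-value sums all outcomes no
more probable than the observed one (no mid-p correction). The suite
verifies the recurrence against direct log-multinomial enumeration for every
configuration with $2n \le 200$ and confirms type-I control at the
$10^{-4}$ screening threshold on HWE-consistent simulated genotypes.

LD pruning parameters are not dictated by any standard; the defaults —
window 50 SNPs, step 5, $r^2 > 0.5$ removes the *later* SNP of a pair — are
ordinary array-QC practice, deterministic, and recorded in the grid file
whenever a pruned setting is used.

## ROH calling

The caller is the classic sliding-window procedure with all eight grid
parameters exposed in `roh_params()`:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 50 | window size in SNPs |
| `het` | 1 | heterozygous calls allowed per window |
| `missing` | 5 | missing calls allowed per window |
| `hit_threshold` | 0.05 | fraction of covering windows that must be homozygous to flag a SNP |
| `min_kb` | 500 | minimum segment length |
| `min_snps` | 100 | minimum SNPs per segment |
| `density_kb` | 50 | maximum mean spacing (kb per SNP, "1 SNP per 50 kb") |
| `max_gap_kb` | 100 | maximum gap between adjacent SNPs of a run |

The defaults are the grid point that, in our estimator comparisons, shows
the strongest agreement with pedigree inbreeding; permissive het/missing
allowances matter because even a small genotyping error rate scatters
spurious heterozygotes into long true ROH, and zero-allowance settings
shred them (the simulator reproduces this: with 1% genotyping error the
allowance setting recovers at least as much ROH per individual as the
zero-allowance one).

Numerical conventions worth stating explicitly:

* **Windows at chromosome ends.** A SNP within `window_snps` of an end is
  covered by fewer windows; the flagging proportion uses only windows that
  physically fit. A chromosome shorter than one window has no windows and
  therefore no flagged SNPs. No phantom windows are invented.
* **Allowances are window-level.** Het/missing tolerances apply to windows,
  so a called segment may contain heterozygous calls; this matches the
  sliding-window formulation in which the per-ROH allowance names map onto
  window parameters.
* **Coordinates and lengths.** 1-based inclusive throughout; segment length
  is `end - start + 1` with endpoints at the first/last flagged SNP. The
  density filter compares `length_bp / n_snps` against `density_kb`, after
  the length and SNP-count filters.
* **Determinism.** Output is ordered by (sample, chromosome, start); ties
  cannot occur within an individual because segments are disjoint.

$F_{ROH}$ divides an individual's summed segment length by the SNP-covered
genome length, which `genome_extent_from_map()` operationalises as the sum
over chromosomes of (last − first SNP position + 1) — the natural
denominator when the extent must come from the map itself; a published
assembly length can be supplied through `genome_extent()` instead, and with
a fixed cohort the choice only rescales all individuals identically.

The entire caller is validated segment-for-segment against a brute-force
implementation that enumerates every window and every maximal run, across
five grid settings and hundreds of random chromosomes with random
heterozygote/missing placement.

## Estimator comparison

`grid_compare()` reports Pearson correlations of each setting's $F_{ROH}$
with $F_{PED}$ (two-sided $t$ on $n-2$ df), all pairwise paired t-tests
among settings ($n-1$ df), and the count of setting pairs with no
significant difference. The significance threshold defaults to
$\alpha = 0.05$, two-sided, **uncorrected** — the comparison is descriptive,
raw counts only, so no multiplicity adjustment is applied. Two identical
columns are "not different" by convention ($t = 0$, $p = 1$), avoiding a
0/0; a constant non-zero difference returns a signed infinite $t$ with
$p = 0$.

## Consensus regions and QTL overlap

Carrier counts change only at segment starts (+1) and one base past ends
(−1), so a sweep over the sorted unique breakpoints yields the carrier
count on every inter-breakpoint interval in one pass. Maximal runs of bases
with count $\ge \lceil f \cdot N \rceil$ become consensus regions,
annotated with the *minimum* carrier count they attain; adjacent qualifying
intervals are merged. No minimum-length filter is applied — single-base
regions are legitimate, arising wherever one individual's segment boundary
clips a shared interval. The sweep is checked region-for-region against a
literal per-base counting oracle at fractions 0.5/0.9/0.95/1.0.

Interval overlap with the packaged QTL table uses any-overlap semantics on
1-based inclusive coordinates (`max(starts) <= min(ends)`); adjacency is not
overlap. BED export converts to 0-based half-open, the interchange
convention of bedtools-family tools, alongside a 1-based CSV twin. The
packaged `qtl_table4.tsv` transcribes 35 published equine
health/reproduction QTL intervals; its one reproduction-class entry is the
motile-sperm-count QTL on chromosome 1, and the osteochondrosis symbols
(OSTEO, OSTD) account for 48.6% of the table — both facts recomputed, not
stored, by the test suite and acceptance script.

## The gene-dropping simulator

The generator exists because real registry genotypes of this kind are
access-restricted: it provides inputs with *known* autozygosity so the whole
pipeline can be validated quantitatively.

* **Pedigree.** Discrete generations; each offspring draws its sire
  uniformly from the top `sire_pool_fraction` (default 0.15) of the previous
  generation's males and its dam uniformly from the females. This is the
  simplest mechanism that reproduces the defining feature of harness-racing
  breeds — a few elite sires dominating each generation — and it drives
  median $F$ upward by roughly a percentage point per generation at the
  default pool size, the magnitude seen in such breeds. Sex alternates
  deterministically so both pools are always non-empty; one generation maps
  to one birth year to exercise the trend machinery (real generation
  intervals of 7–9 years are deliberately not emulated).
* **Recombination.** Haldane model: per chromosome, a Poisson number of
  crossovers with mean `length_bp × rate / 1e8` (1 cM/Mb default), placed
  uniformly, no interference. Interference changes segment-length
  *variance* slightly but none of the properties validated here.
* **Truth.** Autozygosity is read directly off the two founder-label
  mosaics: IBD wherever the labels agree. Its expectation equals $F_{PED}$,
  which the tests confirm ($E[\text{truth}] = F$ per individual; cohort
  means agree within drift noise).
* **Genotypes.** SNPs are placed on a regular grid (spacing
  `length_bp / snps_per_chromosome`), emulating the engineered spacing of
  array designs; with the validation density of 2,000 SNPs per 100 Mb the
  50-kb spacing keeps the max-gap (100 kb) and density (1 SNP/50 kb)
  criteria meaningful rather than stochastically self-defeating, which
  uniform-random placement would make them (a 100-kb gap would then occur
  with probability $e^{-2}$ at every interval). Alternate-allele
  frequencies are uniform on [0.05, 0.5]; genotyping error replaces a call
  with a uniformly chosen different call (symmetric — no error-mode model
  is implied by array data of this kind), and missingness is independent.
  Individuals are split into two cohorts (default 84%/16%) typed on panels
  sharing 90% of SNPs by default, so the merge path is exercised.

### Validation study and problem sizes

The headline validation (`scripts/acceptance.R`, also a test) simulates 40
founders, 10 generations of 200 offspring, sire pool 0.15, 5 chromosomes of
100 Mb with 2,000 SNPs each, 0.2% genotyping error and 1% missingness —
about 2,000 pedigree records and a 200 × 10,000 genotype matrix, sized to
run in seconds while leaving Monte-Carlo noise well below the tolerances
tested. ROH are called directly on the simulated genotypes without the
MAF/HWE screen: QC is validated separately, and a MAF filter applied to
drift-fixed simulated SNPs would punch holes in the map that have nothing
to do with the estimator under study. Three properties are checked:

1. mean $|F_{ROH} - \text{truth}| < 0.03$ at the default calling setting
   (observed ≈ 0.015 at seed 1);
2. $r(F_{PED}, F_{ROH}) > 0.4$ across the 200-individual cohort
   (observed ≈ 0.43);
3. with the recorded pedigree truncated to three generations, mean
   $F_{ROH}$ exceeds mean $F_{PED}$ — the direction expected whenever the
   recorded pedigree is shallower than the true ancestry, since founders
   assumed unrelated are in fact related.

### What the simulation does *not* show

The generator is neutral: no selection on genotype, no selective sweeps, no
mutation, no population structure beyond the sire bottleneck, and no
realistic equine linkage map. Consequently ROH *islands* — intervals shared
by ≥95% of a population, the signature of directional selection — do not
arise under it; the consensus machinery is therefore validated against
per-base counting oracles on constructed fixtures, not against emergent
simulation output. Likewise the genotyping-error model is symmetric and
unstructured, so passing tests demonstrate correctness of the algorithms
and calibration under the stated model, not robustness to array-specific
artefact patterns (batch effects, cluster-calling failures, reference
bias). Real-data headline figures from restricted datasets are out of
reach by construction and are nowhere asserted.
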