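---
title: "Methods: two-statistic selection scans with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-statistic selection scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sweepscan` locates candidate regions of recent positive selection by
comparing two populations' diploid genotype calls with two complementary
window statistics. This vignette describes the statistical model, the
conventions and tunable parameters, the synthetic-data generator used for
validation, and the limitations a user should keep in mind.

## The two statistics

**Per-SNP weighted F_ST.** At each biallelic SNP with allele frequencies
$p_1, p_2$ in the two populations, the differentiation estimator is

$$F_{ST} = \frac{s^2}{\bar p(1-\bar p) + s^2/r}, \qquad
\bar p = \frac{p_1+p_2}{2}, \quad
s^2 = \frac{\sum_i (p_i-\bar p)^2}{r-1} = \frac{(p_1-p_2)^2}{2},$$

with $r = 2$ populations. The statistic lies in $[0,1]$: it is 0 when the
populations share a frequency and 1 at a fixed difference. Sites
monomorphic in *both* populations have a zero denominator and are
unevaluable; they are excluded from window means rather than treated as
zero, because they carry no differentiation information.

**Window pooled heterozygosity H_P.** Within a window and population,

$$H_P = \frac{2\,\Sigma n_{Maj}\,\Sigma n_{Min}}
            {(\Sigma n_{Maj}+\Sigma n_{Min})^2},$$

where $n_{Maj}$ and $n_{Min}$ are the major- and minor-allele counts at a
locus among that population's non-missing calls (major = the locally more
frequent allele; at a 50/50 tie the assignment is irrelevant because only
the two sums enter). $H_P$ is computed from the *window-summed* counts —
not as a per-SNP average — which is what the $\Sigma$ inside the formula
denotes; the two orderings differ, and the pooled form damps the influence
of individual low-information sites. $H_P \in [0, 0.5]$, with the maximum
at equal sums and 0 at fixation, so a selective sweep pulls it towards 0.

**Z-transformation and outlier rules.** Each window track is standardised
genome-wide, $Z = (x-\mu)/\sigma$, with $\mu$ and $\sigma$ taken over all
evaluable windows of that track (per population for $H_P$, per population
pair for $F_{ST}$; if several pairs are scanned each is standardised
separately, since their raw scales need not be comparable). Outliers are
then

- $ZF_{ST}$: the top fraction (default 1%) of windows, flagging
  $k=\lceil f N \rceil$ windows among $N$ evaluable ones, ties at the
  cutoff broken deterministically by (chromosome, start);
- $ZH_P$: windows at or below a fixed threshold (default $-4$). The
  boundary is included ($\le$) by default and configurable — published
  analyses print both conventions, and a boundary-exact window is
  indistinguishable in practice.

A gene is a **candidate** when its body (1-based GTF span, optionally
extended by a flank, default 0) shares at least one base pair with a
flagged window of *each* statistic. The two supporting windows need not
coincide; when no single jointly-flagged window overlaps the gene the
candidate is reported with `split_support = TRUE` so the stricter reading
can be recovered by filtering. Per-gene statistics are reported from the
most extreme supporting window of each statistic, mirroring the one-row-
per-gene convention of published candidate tables.

## Input filtering

Sites are retained when they are biallelic SNPs on configured autosomes
with

- `depth_min < mean depth < depth_max` (defaults 3 and 30, strict on both
  sides, mean of the per-sample `DP` values over called individuals);
- pooled minor allele frequency strictly `> 0.05`;
- missing-call fraction strictly `< 0.1`.

Conventions adopted where a published pipeline usually leaves them
implicit:

- depth comes from per-sample `DP` averaged over called samples; a VCF
  without `DP` passes the depth criterion and the filter report notes it;
- MAF is computed on the sample pooled across all mapped individuals (the
  filters are applied to one merged call set before the scan);
- each removed site is attributed to the *first* criterion it fails, in
  the order structural (non-SNP/multiallelic), non-autosomal, depth, MAF,
  missingness — cheap structural checks first, which makes the filter
  report deterministic and its counts sum to the number removed;
- a site with zero called genotypes has no defined allele frequency; it
  is not counted as a MAF failure and falls through to missingness;
- the autosome set defaults to chromosomes 1–29 in both bare and
  `chr`-prefixed spelling and is configurable for other genomes.

## Coordinates and windows

Internally everything is 0-based half-open: a VCF position $p$ maps to
$p-1$, a GTF span $[s,e]$ (1-based inclusive) to $[s-1,e)$. Windows tile
each chromosome from 0 with the configured step (defaults 100 kb / 50 kb,
so each SNP contributes to two windows); a trailing window is emitted
whenever its start precedes the chromosome end, truncated to the
chromosome length. Abutting intervals therefore do not overlap, and the
candidate-gene rule requires a genuine shared base pair.

Windows with fewer than `min_snps` contributing SNPs (default 10:
evaluable per-SNP $F_{ST}$ values for the differentiation track, typed
sites for each $H_P$ track) are unevaluable and are excluded from the
Z-transform instead of being zero-filled — zero-filling would deflate
$\sigma$ and inflate every other window's $|Z|$.

## Numerical conventions

- $s^2$ divisor: $r-1$ (so a fixed difference gives $F_{ST}=1$,
  standard for this estimator family); exposed as an argument.
- $\sigma$: the sample standard deviation ($n-1$ divisor) by default,
  with a population ($n$) option; all package invariants are stated under
  the active convention. With hundreds of windows the two differ
  negligibly.
- Degenerate inputs error loudly: fewer than two evaluable windows or a
  constant statistic cannot be Z-transformed ("degenerate statistic
  distribution"); an empty window table cannot be plotted; outlier calling
  on a table without evaluable windows is an error, while an *empty
  outlier set* (no window passes the threshold) is a legal result.
- All outputs are written with deterministic formatting; rerunning the
  pipeline on identical inputs yields byte-identical TSV/BED files.

## The synthetic-data generator

`simulate_sweep_data()` emulates the data structure the scan assumes,
at desk scale:

- per SNP, an ancestral frequency $q \sim \mathrm{Beta}(a,b)$ (default
  $(1,1)$, i.e. uniform);
- each population drifts independently under a Balding–Nichols model:
  $p \sim \mathrm{Beta}\!\big(q\tfrac{1-F}{F},\,(1-q)\tfrac{1-F}{F}\big)$,
  with mean $q$ and variance $Fq(1-q)$; the default $F = 0.05$ is a
  moderate livestock-breed divergence;
- inside a planted sweep interval the swept population's frequency is
  replaced by `target_freq` (default 0.98) for the locally major allele —
  reduced heterozygosity in that population, elevated differentiation
  between populations — while the other population keeps its drifted
  frequency. The replacement is deterministic; sweep strength is
  controlled by `target_freq` alone, not by a trajectory model;
- genotypes are $\mathrm{Binomial}(2,p)$ per individual, calls are
  dropped at `missing_rate` (default 0.02) and per-sample depths are
  Poisson with mean `depth_mean` (default 16, a realistic mean
  resequencing depth);
- sample sizes default to 12 and 11 diploids — the two-population design
  the scan targets;
- the default genome is 2 chromosomes × 5 Mb with 5,000 SNPs each
  (1 SNP/kb, so ~100 SNPs per 100-kb window) and five 150-kb sweeps. The
  150-kb width guarantees that at least one 100-kb window lies entirely
  inside each sweep regardless of grid alignment; the positions spread
  the sweeps across both chromosomes.
- a toy GTF places one 30-kb gene in the middle of each sweep and three
  to four 40-kb background genes per chromosome away from the sweeps, so
  candidate reporting and its negative controls are both exercised.

Identical configuration and seed give byte-identical output files; the
seed is mandatory.

**What the generator does not emulate.** Sites are independent: there is
no linkage disequilibrium, no recombination map, no coalescent genealogy,
no demographic history, and no sequencing error model beyond missingness
and Poisson depth. Passing tests on this generator therefore demonstrate
that the estimators, window bookkeeping, Z-transforms, outlier rules and
annotation logic are correct — not that the scan's detection power on
real, LD-structured genomes matches any particular published figure.

## Validation design and problem sizes

The test-suite checks run at deliberately small scale, chosen so the whole
suite completes in minutes on one core while each check still has clear
resolution:

- estimator oracles: 1,000 random frequency pairs against a brute-force
  evaluation of the $F_{ST}$ formula (tolerance $10^{-12}$), 1,000 random
  count pairs against the $H_P$ closed form (exact);
- null calibration: 20 seeds × 20,000 SNPs on a 1-Mb chromosome
  (20 windows) at $F=0.05$ with no sweeps — no $ZH_P \le -4$ window in at
  least 95% of seeds, and a pooled Wald–Wolfowitz runs test on the
  positions of the top-1% $ZF_{ST}$ windows (pooled across seeds, because
  a single seed flags only $\lceil 0.2 \rceil = 1$ window, for which a
  per-seed runs test is degenerate);
- sweep recovery: the default 10-Mb, five-sweep configuration across 20
  seeds, scored by `truth_recovery_report()` (sensitivity = fraction of
  planted intervals overlapped by a jointly-flagged window; FDR =
  fraction of jointly-flagged windows overlapping no planted interval).

## Known limitations

- **Top-fraction rules need many windows.** Flagging the top 1% of $N$
  windows yields $\lceil 0.01N \rceil$ windows; at desk scale
  ($N \approx 200$) that is two windows, so at most two distinct sweeps
  can ever be recovered jointly, however strong the signal. Genome-scale
  data (tens of thousands of windows) do not have this constraint. For
  small simulated genomes, either raise `fst_fraction` or read the
  $ZH_P$ track alone.
- **Z-thresholds are relative to the scanned genome.** When sweeps occupy
  a non-trivial fraction $w$ of all windows they inflate $\sigma$
  themselves; the most extreme attainable $|Z|$ is about
  $\sqrt{(1-w)/w}$, so a fixed $ZH_P \le -4$ cutoff needs swept windows
  to be rare (roughly $w \lesssim 6\%$) — which they are in real genomes
  but need not be in small simulations.
- **Finite-sample $F_{ST}$ bias.** The estimator uses realized sample
  frequencies, so with $n_1, n_2$ diploids its null expectation is
  approximately $\tfrac12\big(\tfrac{1}{2n_1}+\tfrac{1}{2n_2}\big)
  \approx 0.044$ at 12/11 diploids rather than 0. The Z-transform
  absorbs this genome-wide offset, but raw window means should not be
  read as unbiased differentiation estimates at small sample sizes.
- Haplotype-based statistics (iHS, XP-EHH), more than two populations,
  kinship correction and enrichment analysis are out of scope.
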