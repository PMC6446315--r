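---
title: "Methods and design of popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popgenscan is a windowed population-genomics toolkit for multi-sample
diploid variant calls: diversity and differentiation scans, a
joint-outlier selective-sweep caller, ABBA-BABA introgression tests,
isochore GC segmentation, an allele-frequency-differential screen, and LD
decay curves — together with a simulator that produces cohorts whose true
parameters are known, so that every statistic in the package can be
validated quantitatively rather than by eyeball. This vignette explains
the models, the defaults, and the design choices that were genuinely open.

## Data model and coordinates

The central container is the `genotype_matrix`: biallelic sites × samples
with alternate-allele dosages 0/1/2 and `NA` for missing genotypes. SNPs
and indels share one matrix with a per-site class flag, because the
isochore analyses need both classes against one coordinate system.
Multi-allelic records are dropped by default (every statistic here is
defined on biallelic sites); `read_variants(drop_multiallelic = FALSE)`
splits them instead. Sites use 1-based VCF positions; windows, regions,
segments and all BED output are 0-based half-open. Every written table
states its convention in a header comment.

Missing genotypes enter every statistic through the local (per-site) count
of non-missing chromosomes. `read_variants()` additionally removes sites
with more than `max_site_missing = 0.2` missing genotypes; the threshold
is exposed because there is no universally right value and callers
working with trusted upstream filtering can set it to 1.

## The simulator

Population allele frequencies follow the Balding–Nichols model: given an
ancestral frequency $p$ and divergence $F \in (0,1)$, each population
draws its frequency from $\mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$, so $\mathrm{E}[p_i] = p$,
$\mathrm{Var}[p_i] = F\,p(1-p)$, and the expected Weir–Cockerham FST
between two populations equals $F$ in closed form. That closed form is the
reason this model was chosen over a coalescent engine: parameter-recovery
tests have an exact target. The price is exchangeability — there is no
shared genealogy, no demography, and site frequencies are independent
unless the mosaic model (below) is switched on. Passing tests therefore
demonstrate correctness of the estimators under their own assumptions, not
robustness to realistic chicken demography.

Ancestral frequencies come in two modes: `uniform` (Uniform(0.05, 0.95),
convenient for differentiation statistics) and `neutral`, which draws a
derived count $i$ with probability $\propto 1/i$ over a notional panel
(default 200 chromosomes) — the neutral site-frequency spectrum, used when
Tajima's D must be centred near zero.

Haplotypes are drawn i.i.d. Bernoulli per site by default. This is exact
Balding–Nichols sampling; a founder-mosaic alternative
(`founder_haps = K`, per-bp switch rate `rho`, default $10^{-6}$) builds
each haplotype as a recombining mosaic of K founders, creating
distance-decaying LD for the r² analyses. The mosaic is deliberately *not*
the default: resampling through K founders adds roughly $(1-F)/K$ of extra
drift to realized FST, which would silently bias parameter-recovery
checks.

Selective sweeps are implanted as local fixation: within the interval, in
the target population, each segregating site is driven to its locally
major allele with probability `fixation_prob`. The scan consumes only the
resulting diversity/differentiation footprint, so a forward selection
simulation would add cost without adding validity. Introgression copies
donor-haplotype tracts (geometric lengths, mean `tract_length`) onto a
fraction `f` of recipient haplotypes, which produces exactly the excess
ABBA sharing the D-statistic measures; tract coordinates are recorded as
truth. An optional `z_contig` has its site count scaled (default 0.5) to
emulate the reduced diversity of a Z chromosome. The outgroup is emitted
fixed for the ancestral (= reference) allele at every site, making
polarization exact by construction.

The validation scenario for introgression power was designed from the
expectation $D \approx \alpha\,F_{donor}\,\mathrm{E}[pq] /
(2\,\mathrm{E}[p^2q])$, where $\alpha$ is the fraction of the recipient
genome that is introgressed: two 5-Mb contigs with 30,000 sites, sister
populations at $F = 0.1$, a more diverged donor at $F = 0.25$, and
$f = 0.3$ of recipient haplotypes carrying two tracts of mean 1.5 Mb.

## Windowed statistics

Per-site diversity uses the unbiased estimator
$\hat\pi_s = 2\hat p\hat q\, n/(n-1)$ with $n$ the site's non-missing
chromosome count; windows report both the sum and the per-bp value.
Tajima's D uses the standard $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$
constants with $S$ the number of sites segregating in the population
within the window. Because $n$ varies per site under missingness, the
constants use the window-median $n$ — the paper-trail default, documented
here because no published convention exists; with little missingness the
choice is immaterial.

Windows below `min_snps` (default 20) keep their counts but carry `NA`
statistics and a `low_snps` flag. Truncated terminal windows are retained
but flagged, and are excluded from downstream quantile computations — a
partial window's statistic is on a different scale. The default frame is
40-kb windows with a 20-kb step; `select_window_size()` reproduces the
saturation procedure that justifies it: among non-overlapping tilings, the
size with the highest proportion of windows holding ≥ 20 SNPs wins, ties
broken toward the smaller size since shorter windows retain power for
short sweeps.

The heterozygosity scan counts heterozygous genotypes per (default 500-kb)
window, pooled and optionally per sample; the Z-vs-autosome contrast
offers both the two-tailed t-test (default) and Mann–Whitney U. When every
value in both groups is identical the tests return p = 1 by convention
(the normal approximation is 0/0 there).

## The sweep caller

Weir–Cockerham variance components $a$ (among populations), $b$ (among
individuals) and $c$ (within individuals) are computed per site with
per-site sample sizes; the window estimate is the ratio of sums
$\sum a / \sum(a+b+c)$ — standard practice, stable in low-diversity
windows, unlike averaging per-site ratios. Negative per-site components
are retained so sums stay unbiased. zFST is
$(F_{ST} - \mu)/\sigma$ with the sample ($n-1$) standard deviation,
computed over autosomal windows only, since sex chromosomes have different
effective population sizes.

A window is called when it lies in the top tail (default 5%) of **both**
the window-FST distribution and the $\log_2(\pi_{ref}/\pi_{target})$
distribution. Quantiles use the "higher" order statistic so the flagged
fraction per criterion never exceeds $1-q$; they are computed per pairwise
comparison over non-missing, non-truncated autosomal windows, and the
caller refuses to run with fewer than 20 usable windows. Flagged windows
that overlap or abut merge into regions (with a 20-kb step, adjacent
flagged windows share 20 kb and merge). The absolute Tajima's D difference
between target and reference is attached to regions as annotation only —
it is plotted alongside in the source analyses but is not part of the
calling rule. `background_contrast()` provides the Mann–Whitney contrast
of in-region windows against the genome, and `annotate_regions()` joins
genes by ≥ 1 bp half-open overlap, with `shared_gene_counts()` tallying
genes recurrent across population scans.

Windows where the target population has zero diversity produce a missing
ratio with reason `zero_target_pi` rather than an infinite value; a
pseudo-floor is available but off by default, because silently flooring
zeros moves real sweep windows *out* of the tail.

## The D-statistic

With derived-allele frequencies $\hat p_{i1}, \hat p_{i2}, \hat p_{i3}$
polarized against an outgroup that must be fixed at each used site,

$$D = \frac{\sum_i (1-\hat p_{i1})\hat p_{i2}\hat p_{i3} -
            \hat p_{i1}(1-\hat p_{i2})\hat p_{i3}}
           {\sum_i (1-\hat p_{i1})\hat p_{i2}\hat p_{i3} +
            \hat p_{i1}(1-\hat p_{i2})\hat p_{i3}}.$$

The outgroup enters only through polarization (sites where it is
polymorphic or fully missing are dropped and counted), matching the
frequency form of the statistic. Significance uses a delete-one block
jackknife over contiguous genomic blocks (default 1 Mb), which is robust
to linkage among nearby sites; the source analyses report no significance
procedure for D, so the jackknife is this package's clearly-labelled
addition, with the standard error flagged unreliable below 5 non-empty
blocks. IBD inference itself is out of scope — `ibd_summary()` consumes
BEAGLE-style tract tables and reports per-population-pair counts and
length statistics, with an optional per-recipient-sample normalization.

## Isochores

The reference is classified in fixed windows by GC over non-N bases;
consecutive windows of the same family merge into segments whose GC is the
mean weighted by informative bases. Family boundaries follow the isochore
literature: L1 < 37%, 37–41% L2, 41–46% H1, 46–53% H2, ≥ 53% H3
(left-closed bins, overridable). Windows at least half N become
unclassified gap segments so segments always tile the contig.
`choose_gc_window()` implements the plateau rule: the SD of per-window GC
(over windows in segments of ≥ 4 windows) is computed for each candidate
size, and the smallest size whose relative SD decrease to the next size
falls below 5% is chosen; with no plateau the largest candidate is
returned — on a homogeneous reference the SD is pure binomial noise and
keeps shrinking as $1/\sqrt{w}$, so no finite candidate plateaus.
`variant_gc_correlation()` reports Pearson r between segment GC and
variant density per Mb, per class, plus each family's share of variants.

## The AFD screen

A site is a hit when the alternate-allele frequency is strictly above 0.8
in one group and strictly below 0.2 in the other (strict, following the
"greater than / less than" reading), *and* Pearson's chi-squared on the
2×2 allele-count table gives p < 0.001. Allele counts — not genotype
counts — form the table because the screen is about allele frequencies; no
continuity correction is applied by default (configurable). A
Benjamini–Hochberg q over all tested sites is reported alongside, but the
raw-p filter remains the default criterion. Consequence annotations are
consumed from a keyed table, never computed.

## LD decay

On phased haplotypes $r^2 = (p_{AB}-p_Ap_B)^2/(p_Aq_Ap_Bq_B)$; the
simulator provides phase, so this is the primary path. For unphased
genotype input the squared Pearson correlation of dosages is the
documented surrogate, flagged in the output metadata. Sites below MAF 0.05
are excluded (denominator stability; configurable), pairs are capped at 40
kb, and `decay_curve()` averages r² in distance bins, emitting empty bins
as missing rather than zero so curves from concatenated pair tables add
exactly.

## Pipeline and determinism

`run_pipeline()` executes the configured stages in dependency order from a
single config (R object or YAML), writes TSV/BED plus `summary.json` and
`run_metadata.json`, and is byte-identical under a fixed seed — every
random draw flows from the one seed recorded in the metadata. One YAML
quirk is handled for users: YAML 1.1 resolves a bare `n` key to a boolean,
so the reader restores it.

## Validation scale and limitations

The shipped checks run at desk scale, chosen as the smallest sizes at
which the theory gives tight expectations: FST recovery uses 2 × 50
diploids × 20,000 sites over 20 seeds (tolerance ±0.02 around F = 0.10);
Tajima's D neutrality uses ≥ 200 windows (mean within ±0.3 of 0); sweep
recovery uses a 200-kb implant at fixation probability 0.9 in 4-Mb
genomes over 20 seeds; D-statistic calibration uses 40 null and 20
introgressed cohorts of 30,000 sites. What passing shows is that the
estimators recover the generating parameters of their own model; it does
not show robustness to demography, linked selection, mutation-rate
variation, genotyping error, or reference bias, none of which the
generator emulates. Absolute results from real cohorts (region totals,
gene lists, genome-wide correlation coefficients) depend on the input data
and are outside what synthetic validation can certify.
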