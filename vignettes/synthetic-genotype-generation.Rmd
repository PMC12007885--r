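---
title: "Generating balanced synthetic genotype benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating balanced synthetic genotype benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genosynth)
```

# Why this package exists

Benchmarking association, kinship-inference and outsourced-computation
verification methods requires genotype data with three properties that
real cohorts rarely combine: balanced representation of ancestry groups,
known ground truth (which SNPs are causal, who is related to whom, what a
correct GWAS must return), and freedom from privacy restrictions.
`genosynth` produces such data by perturbing real (or simulated) genotypes
rather than fitting a generative model: every synthetic sample is a
noised copy of a real one, which keeps allele-frequency structure and
ancestry geometry by construction and makes every design choice auditable.

This vignette documents the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and the limits of
what the simulated founders can show.

# The founder simulator

Real multi-ancestry cohorts are access-controlled, so the package ships a
Balding–Nichols founder simulator as its default input source. Each SNP
draws an ancestral alternate-allele frequency $p \sim U(\ell, u)$; each
ancestry group $g$ with divergence parameter $F_g$ draws its own frequency

$$p_g \sim \mathrm{Beta}\!\left(\frac{p(1-F_g)}{F_g},
                                \frac{(1-p)(1-F_g)}{F_g}\right),$$

which has mean $p$ and variance $p(1-p)F_g$ — the standard
FST-parameterized divergence model. Genotypes are $\mathrm{Bin}(2, p_g)$
draws; missingness is applied independently per cell.

Defaults (six groups of 500, $F = 0.1$, ancestral MAF in $[0.05, 0.5]$,
1% missingness) were chosen once as typical of continental-scale array
data: $F \approx 0.1$ separates groups cleanly in PC space without making
them disjoint, and 500 founders per group keeps the default
three-generation relatives schedule (which consumes 400 founders)
feasible. Equal group sizes are the default because the package's purpose
is balanced output; unequal real-world proportions can be configured.

What the simulator does **not** emulate: linkage disequilibrium (sites are
independent), realistic site-frequency spectra, admixed individuals, and
genotyping batch effects. Tests passing on these founders therefore
demonstrate correctness of the generation machinery, not realism of any
particular downstream analysis on real data.

# Quality control

`apply_qc()` applies four filters in a fixed order: samples with missing
rate $> 5\%$, SNPs with missing rate $> 5\%$, SNPs with MAF $< 0.01$, SNPs
with exact Hardy–Weinberg $p < 10^{-6}$. The sample filter runs first,
mirroring common PLINK practice (`--mind` before `--geno/--maf/--hwe`).
The HWE test is the exact conditional test (standard $p$, not mid-$p$),
computed with the numerically stable recurrence over heterozygote counts;
the test suite checks it against an independent log-factorial enumeration
for every genotype configuration with up to 50 samples.

Two consequences worth knowing:

- Pooling diverged ancestry groups deficits heterozygotes (the Wahlund
  effect), so on multi-group input the HWE stage removes a real share of
  SNPs. This is faithful to running PLINK-style QC on a combined cohort.
- After filtering, residual missing genotypes are **imputed to the
  per-SNP modal genotype** (ties toward the lower value). This is an
  artifact decision, made because every downstream stage — perturbation,
  phenotypes, watermarks, Mendelian transmission, KING — assumes complete
  data. Mode imputation slightly sharpens genotype modes; at the default
  missingness (1%) the effect on allele frequencies is negligible.

# Stratification and the ancestry filter

`fit_pca()` centers columns and keeps the top $K$ components
($K = \min(200, n-1, p)$ by default, so small runs stay valid). Signs are
fixed by forcing each component's largest-magnitude loading positive,
making results reproducible across platforms.

The qualitative requirement that synthetic samples must not "deviate from
their ancestry group" is operationalized geometrically: each group gets
the centroid of its member scores and the 97.5th-percentile radius of
member distances to that centroid. A candidate is ancestry-consistent when
its projected distance is within `slack` (default 1) times the radius.
This rule is scale-free, cheap to evaluate per candidate, and calibrated:
by construction about 97.5% of the group's own members satisfy it. Both
the percentile and the slack are configurable; all fitted components are
used, since nothing in the construction argues for a subset.

# The perturbation mechanism

Standard $d$-ary randomized response flips a value to any other state with
probability $1/(e^\varepsilon + d - 1)$, which for genotypes permits
$0 \to 2$ transitions — a biologically drastic double-allele change. The
constrained variant used here forbids them:

- state 0 or 2 $\to$ 1 with probability $q_e = 2/(e^\varepsilon + d - 1)$;
- state 1 $\to$ 0 with probability $q_h = 1/(e^\varepsilon + d - 1)$ and
  $\to$ 2 with the same $q_h$.

With $d = 3$ all three states share the stay probability $1 - 2q_h$, and
the flip mass from the heterozygote splits evenly. At the default
$\varepsilon = 6$, $q_e \approx 0.49\%$: roughly one genotype in 200 is
modified, which preserves allele frequencies and PC geometry while
guaranteeing that (after the identity filter) no synthetic record equals
its source. The privacy interpretation is deliberately modest: the
mechanism gives randomized-response-style plausible deniability per
record; no composition accounting over rejected candidates is attempted.

Per group, candidates are drawn by sampling a source uniformly **with
replacement** (so groups smaller than the target still reach it),
perturbing the whole row, and accepting iff the candidate differs from its
source and passes the ancestry filter. The identity filter compares
against the candidate's own source by default (`identity_filter = "all"`
checks against every original). The loop is capped at `max_attempts`
(50×) times the target and reports the acceptance rate on failure, which
signals $\varepsilon$ too small or a radius too tight. Accepted samples
receive unique random integer IDs (default range 1,000,000–9,999,999),
sorted ascending, and the rows are randomly permuted before ID assignment
so row order carries no group information.

# Phenotype simulation

A random `causal_fraction` (default 10%) of SNPs receives logit
coefficients $\beta_k \sim N(0, \sigma^2)$ with $\sigma = 0.5$, giving
per-allele odds ratios mostly between 1.1 and 3 — the range typical of
complex-trait hits. Each sample's liability is its genetic score plus
standard-logistic noise; labels are assigned by thresholding the
liability at its `case_fraction` quantile, so exactly
$\mathrm{round}(0.5\,n)$ samples are cases (ties resolved by sample
order). Exact balance by thresholding — rather than independent Bernoulli
draws from the logistic probabilities — was chosen because the output
contract promises equal representation; the cost is that the intercept is
implicit (recorded as 0) and labels are a monotone transform of
liability, which is exactly what a liability-threshold model assumes. The
coefficient distribution and the absence of an explicit intercept are
artifact choices; both are recorded in the returned object so benchmark
users have full ground truth.

By default the phenotype is simulated on the combined original + synthetic
matrix (the realistic use when real data are present) and only the
synthetic samples' labels are exported; `include_originals_in_phenotype =
FALSE` restricts simulation to the synthetic cohort, in which case the
exported labels are exactly balanced.

# Watermark SNPs

A watermark column is built in four steps: copy the phenotype vector;
split indices into cases and controls; compute the within-arm genotype
counts; re-randomize each arm to genotypes realizing those counts. The
counts are the Hardy–Weinberg expectations $n p^2,\; 2np(1-p),\;
n(1-p)^2$ at allele frequency $p = z_0 + \mathrm{eps}$ (cases) and
$p = z_0 - \mathrm{eps}$ (controls), rounded by largest remainder so each
arm's counts sum exactly to its size. Quotas are pre-rounded at $10^{-9}$
so exact ties break toward the lower genotype deterministically rather
than by floating-point noise. At the defaults ($\mathrm{eps} = 0.3$,
$z_0 = 0.49$, 20 columns) the two arms differ by 0.6 in allele frequency,
an effect so large that the likelihood-ratio logistic test returns
p-values below $10^{-100}$ for realistic cohort sizes — the point of a
watermark is to be unmissable. The LRT was preferred to the Wald test
because near-separation (which these columns approach) destroys Wald
standard errors; fits hitting the iteration cap are flagged, and p-values
that underflow double precision are floored at the smallest positive
double so the reported value stays in $(0, 1]$.

Watermark SNP IDs are random `rs`-style identifiers kept disjoint from the
data SNP IDs by rejection.

# Synthetic relatives and kinship

Relatives are generated from the **synthetic** samples of each group.
Founders (default 400) are split uniformly into father/mother halves and
paired without replacement; each of the first 200 pairs produces one
offspring by per-SNP Mendelian transmission (a parent with genotype $g$
transmits an alternate allele with probability $g/2$). The offspring are
re-paired for the next generation (100, then 50). Because every pair
produces exactly one child and no parent is reused within a generation,
the pedigree contains no siblings or collateral relatives; every related
pair is an ancestor–descendant pair, and the emitted degree label is the
meiosis distance (1–3; deeper links are not emitted). Under the default
schedule this enumeration yields 1,700 pairs per group. Sibling-free
pedigrees are a simplification: degree labels map one-to-one onto meiosis
counts, which is convenient for benchmarking kinship estimators but does
not exercise the sibling/avuncular ambiguity real data present.

Each recorded pair is scored with the KING robust coefficient exactly as
defined,

$$\phi(i,j) = \frac{2n_{11} - 4(n_{02} + n_{20}) - n_{*1} + n_{1*}}
                   {4\,n_{1*}},$$

including its asymmetric normalization by $i$'s heterozygosity ($i$ is the
descendant in emitted records). Identical sequences score exactly 0.5 and
simulated parent–offspring pairs average ≈ 0.25, halving per meiosis; the
estimator is undefined (and errors) when $i$ has no heterozygous site,
which does not occur at realistic SNP counts.

# Pipeline, determinism and scale

`run_pipeline()` chains QC → PCA → per-group synthesis → ID assignment →
phenotype → watermark → relatives → kinship and returns a
`dataset_bundle`; `write_bundle()` emits the five CSV files (the
watermark file carries one trailing row of p-values; the kinship file's
second column is the related sample's ID). A single global seed
deterministically derives one seed per stage, so identical configurations
reproduce byte-identical CSVs; this is asserted in the test suite.

All stages are vectorized over matrices. The test and validation runs in
this package use desk-scale problem sizes — hundreds of founders, a few
hundred SNPs, up to 30,000 synthetic samples — chosen so the whole suite
runs in minutes on a laptop; sample-count arithmetic (group totals,
relatives per schedule, watermark column counts, exact balance) is
independent of SNP width, which is why the full-scale sample design can
be, and is, verified at reduced width.

# Known limitations

- No linkage disequilibrium anywhere: founders are simulated per-SNP and
  Mendelian transmission is per-SNP, so LD-aware methods see white-noise
  haplotypes.
- The privacy property is per-record randomized response with a
  constrained support, weaker than unconstrained LDP at the same
  $\varepsilon$; no formal accounting over the rejection loop is claimed.
- Mode imputation after QC biases residual missing calls toward the major
  genotype.
- Pedigrees are sibling-free chains; kinship benchmarks needing collateral
  relatives must extend the pairing scheme.
- The exported phenotype covers the synthetic cohort; when simulation
  includes originals, the exported subset is balanced only approximately.
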