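---
title: "Genotype discordance for sample identity QC: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype discordance for sample identity QC: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtcomp)
```

## The measurement

`gtcomp` measures, for every unordered pair of samples in a cohort, the
fraction of mutually well-called panel positions at which their diploid SNV
genotypes differ — the *discordance rate*. At a panel of common inherited
variants this statistic separates two regimes sharply: technical replicates
or other same-individual samples sit near zero (bounded below by genotyping
error), while samples from unrelated individuals sit near one half. That
separation is what makes the all-vs-all matrix useful for identity QC: a
pair in the wrong regime is a mislabelled, duplicated or contaminated
sample, and the *best* match of a mislabelled sample usually names its true
partner, resolving swaps rather than merely flagging them.

### Encoding

Each sample's genotypes over the panel are one byte per position:

* homozygous calls — the base itself (`A`, `C`, `G`, `T`);
* heterozygous calls — the IUPAC two-base ambiguity character for the
  unordered allele pair (`R`=A/G, `Y`=C/T, `S`=C/G, `W`=A/T, `K`=G/T,
  `M`=A/C), so allele order and phase are irrelevant by construction;
* anything else — the ASCII NUL byte (value 0): missing GT, half-calls,
  calls failing an enabled quality or depth threshold, non-SNV alleles
  (indels, symbolic alleles), `N`, and ploidy other than 2 (counted and
  warned about).

Every called code is an uppercase ASCII letter, so it has bit 6 (value 64)
set; NUL is the only byte in the alphabet without it. This is the load-bearing
invariant of the comparison below and is asserted property-style in the test
suite over all 10×10 code pairs.

### Comparison

For genotype strings $a, b$ of common length $L$, three bytewise Boolean
operations are applied and only **zero result bytes** are counted:

1. $a \oplus b$ (XOR): zero exactly where bytes are identical → *Position
   Matches* $P$, which includes positions where both are missing;
2. $a \lor b$ (OR): zero exactly where both bytes are NUL → *Missing
   Matches* $M$;
3. $a \land b$ (AND): zero exactly where at least one byte is NUL (by the
   bit-6 invariant) → *Positions Missing* $D$.

Then

$$Q = L - D, \qquad G = P - M, \qquad C = Q - G, \qquad r = C / Q,$$

i.e. queryable positions, genotype matches, discrepancy count, and the
discordance rate. These four identities, together with the order
constraints ($M \le P$, $D \ge M$, $0 \le Q \le L$, $C \ge 0$,
$r \in [0,1]$), are enforced in the constructor of every comparison record,
so an algebraically impossible result cannot be represented.

In R the three operations are the native raw-vector operators — `xor(a, b)`,
`a | b`, `a & b` on `raw` vectors are per-byte loops in C — so the pairwise
cost is a handful of vectorised passes over $L$ bytes. An explicit
per-offset R loop (`naive_compare_pair`) implements the identical contract
and serves two purposes: it is the independent correctness oracle (the test
suite demands field-for-field identity on hundreds of random panels spanning
lengths 1–5,000 and missingness 0–100%), and the speed baseline (the bitwise
path is required to be at least 5× faster on 200 samples × 20,000 positions;
on this package's development machine the observed ratio is ~6×).

One deliberate semantic: byte equality is genotype equality, so a
heterozygote and a homozygote sharing an allele (`R` vs `G`) count as a
discrepancy. This is what a one-byte encoding implies and is the right
behaviour for identity QC; it also means tumour/normal pairs with loss of
heterozygosity show small but non-zero discordance, which the all-vs-all
distribution makes easy to distinguish from the unrelated regime.

### Degenerate cases and numerical choices

* **$Q = 0$** (no mutually called position): the rate is *undefined* —
  reported as `NA` with a warning, sorted last in the pair table, flagged
  low-confidence. Reporting 0 would fabricate a perfect match; aborting
  would hide the rest of the cohort.
* **Low-confidence flag**: a rate over a handful of positions is
  statistically meaningless, so pairs with fewer than `min_queryable`
  (default 50) mutually called positions are flagged. The threshold only
  flags; it never drops a pair, and it is recorded in the object and run
  log.
* **Diagonal**: self-discordance is analytically 0 whenever a sample has at
  least one called genotype, and `NA` for an all-missing sample.
* **Ordering**: the matrix rows/columns follow manifest order exactly — no
  clustering — because the heatmap's interpretation (same-individual blocks
  on the first off-diagonal) depends on the input grouping. Pair-table ties
  are left in comparison order (row-major $i<j$), which is deterministic.
* **Empty panels** (zero loci) and single-sample cohorts are errors, not
  empty results.

## VCF ingestion

The converter fills the panel from VCF with conservative defaults:

* **Absent loci** default to missing (`absent_policy = "missing"`). A
  variants-only VCF does not distinguish "homozygous reference" from "no
  data", and guessing hom-ref would deflate discordance between unrelated
  samples sharing missingness patterns. For force-called VCFs (every panel
  site present, hom-ref records included — what the bundled simulator
  emits), `absent_policy = "homref"` fills absent loci with the reference
  homozygote, taking the reference base from any ingested record at that
  locus or a supplied lookup.
* **"Low quality"** is operationalised as site `QUAL < min_site_qual` and
  per-sample `FORMAT/DP < min_depth`, both *disabled* by default: no
  universally correct cut exists across callers, and silent data loss is
  worse than reported noise. `FILTER` is likewise ignored unless
  `pass_only = TRUE`.
* **Duplicate records** at one locus: the first record passing the
  site-level filters wins; extras are tallied as duplicate-record warnings
  in the run log. Deterministic and auditable.
* **Contig names** are matched verbatim between BED and VCF. A file whose
  records hit zero panel loci triggers a loud warning rather than a silent
  all-missing sample; `normalize_contigs = TRUE` strips a leading `chr`
  from both sides when the dialects genuinely differ.
* **Multiallelic records** are used as-is (GT indices into the REF+ALT
  list); an index beyond the allele list is a malformed-record error naming
  chromosome, position and sample. Variant normalisation (left-alignment,
  decomposition) is out of scope.

Ingestion is deterministic, and a multi-sample VCF yields byte-identical
strings to the same data split into per-sample files (both are asserted in
the tests).

## The synthetic cohort generator

`simulate_cohort()` exists so every downstream module is testable with no
external data, and so the package's claims are checkable against closed
forms. Per site it draws a minor-allele frequency $p$ (default uniform on
$[0.15, 0.30]$ — the common-variant regime an identity panel targets, where
sites are maximally informative); each individual's genotype is the
alt-allele dosage $\sim \mathrm{Binomial}(2, p)$, i.e. Hardy–Weinberg
($q^2, 2pq, p^2$). Every sample (all replicates of an individual alike)
then independently applies:

* **genotyping error** (default 1%): with probability $e$ the genotype is
  replaced by one of the *other two* states, uniformly. The simplest
  symmetric choice, picked because it makes expectations derivable: a
  replicate pair is discordant with probability $2e(1-e) + e^2/2 = 2e -
  1.5e^2$ (`expected_replicate_discordance()`), ≈ $2e$ for small $e$;
* **missingness** (default 2%): the genotype becomes NUL.

Two unrelated HWE genotypes at frequency $p$ agree with probability
$q^4 + 4p^2q^2 + p^4$, so
`expected_unrelated_discordance()` returns
$\mathbb{E}_p[1 - (q^4 + 4p^2q^2 + p^4)]$, numerically integrated over the
MAF distribution (≈ 0.508 for Uniform[0.15, 0.30]; 0.625 at $p = 0.5$;
0.4125 at $p = 0.15$). The simulation is required to land within these
expectations in the tests, and the 40–55% / 0–3% regimes the method is used
to separate emerge from exactly these defaults.

Label swaps are planted *after* generation by exchanging the data carried
by two sample names; the truth record keeps both the labelled and the
actual individual per sample, plus applied error/missing counts.

Sites sit on two synthetic chromosomes at 1 kb spacing (enough structure to
exercise chromosome-coloured allele-fraction plots); VCFs are force-called
with GT, DP (Poisson, mean 40), AD (binomial split at heterozygous sites)
and constant QUAL. A fixed seed makes all outputs byte-identical across
runs.

What the generator deliberately does **not** emulate: linkage
disequilibrium, population structure and realistic site-frequency spectra
(sites are i.i.d.), read-level error processes, caller-specific QUAL/FILTER
behaviour, related individuals, or contamination mixtures (the test suite
builds a two-sample read-depth mixture from the simulated AD fields where
needed). Passing tests therefore demonstrate the comparison algebra, the
regime separation and the plumbing — not robustness to cohort structure or
caller idiosyncrasies in real data, where panel choice and relatedness can
move the unrelated mode.

## Reports

The three report surfaces mirror what an analyst inspects: the pooled
discordance histogram (default bin width one percentage point) with an
optional count-axis-zoomed companion panel — the same-individual mode is
invisible next to $\binom{N}{2}$ unrelated pairs otherwise; the
manifest-ordered heatmap with low discordance mapped to the hot (dark red)
end and undefined cells grey (the colour scale is this package's choice, not
a claim about any other tool's); and per-sample variant-allele-fraction
scatter plots coloured by chromosome, where a clean diploid bands at 0, ½, 1
and intermediate bands flag contamination or copy-number change. Every plot
function returns its plotted data invisibly, and the drivers also write it
as TSV, so tests assert on numbers, never pixels. The matrix TSV round-trips
at fixed six-decimal precision with `NA` for undefined cells.

## Problem sizes

The test suite and acceptance script run entirely on generated data at desk
scale, chosen to keep the full run in tens of seconds while leaving the
statistics sharp: oracle-equivalence sweeps over 200 random string pairs up
to length 5,000; regime simulations at 10,000 sites with 20 (unrelated
regime, 190 pairs), 20 (10 individuals × 2 replicates) and 24 (swap
resolution) samples; and one 200-sample × 20,000-position panel for the
speed comparison. At these sizes the standard error of a replicate-pair
rate is ≈ 0.14 percentage points and of the unrelated mean well under 0.1,
so the acceptance bands are comfortably non-trivial.

## Known limitations

* Discordance is a fingerprint statistic, not a kinship estimator: no IBD,
  pedigree or relatedness-degree inference (first-degree relatives sit
  between the regimes and must be interpreted by the analyst).
* The comparison is single-threaded by design; the point of the method is
  that byte-level operations make desk-scale all-vs-all cheap without
  parallel machinery. Sub-quadratic strategies (clustering, sketching) are
  out of scope.
* One byte per locus cannot represent ploidy > 2, partial calls, or
  genotype likelihoods; such calls degrade to missing.
* `absent_policy = "homref"` is only as good as the reference lookup it is
  given; loci never seen in any record and absent from `reference` remain
  missing.
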