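---
title: "The daisydrive model: genotype-frequency recursion for daisy-chain gene drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The daisydrive model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daisydrive)
```

## What the model is

`daisydrive` tracks the frequencies of diploid genotypes through discrete,
non-overlapping generations in one or two panmictic populations. It is a
deterministic recursion: given a drive design and a parameter set, the
trajectory is exact and bitwise reproducible. The unit of state is a
diploid genotype — an unordered allele pair at each unlinked locus —
augmented with a *deposition tag* recording whether each parent carried a
nuclease (Cas9 markers, paternal and maternal) and which gRNAs the mother
co-deposited with her Cas9. Tags matter because maternally deposited
nuclease acts in the embryo of offspring that may not have inherited any
transgene.

Six allele classes exist: the cuttable wild-type target `T`; type-1 (`R1`)
and type-2 (`R2`) resistance alleles; and three drive classes — `E`
(cargo only), `G` (gRNA only), `N` (nuclease, optionally with a gRNA).
gRNA-bearing alleles are annotated with their target locus (`N^A` cuts
locus A). A design assigns one drive allele per locus; presets cover the
self-perpetuating drive (`_A_N^A`), the split drive, and three
three-element daisy chains (`drive_preset()`).

## Life cycle and stage algebra

Each generation applies, in order:

1. **Zygote formation** `z = pbar (x) p`: the outer product of the paternal
   and maternal gamete pools, accumulated onto canonical states. The
   paternal Cas9 marker comes from the father's gamete; the maternal marker
   and deposited-gRNA set from the mother's. This is the one point per
   generation where the frequency vector is renormalised to sum 1.
2. **Embryo stage** `e = z D`, per sex. `D` combines the embryonic
   (deposition) conversion matrix `K` with fitness: `D_ij = K_ij * w_i`,
   where `w_i = sum_j K_ij * theta_j` is the *mosaic fitness* of zygote i.
   Deposition cuts tissues of one developing individual, so the genotype
   fractions in row i belong to a single mosaic organism and survival is
   applied uniformly at their frequency-weighted mean fitness — not
   per-outcome, which would let tissue fractions live or die independently.
3. **Germline stage** `g = e C`: expression-based cutting with the genomic
   eligibility rule (below), per sex (the matrix is sex-independent;
   sex-specific selection lives in `theta`).
4. **Migration** between the populations, applied to the post-selection
   adult vectors.
5. **Meiosis** `p = g H`: independent per-locus Mendelian segregation.
   Every gamete of a nuclease-carrying parent gets Cas9 marker 1, and
   carries a flag for each gRNA the parent expressed alongside that Cas9 —
   even when the gRNA gene itself is not inherited. Markers never change
   segregation probabilities.

Generation 1 seeds the embryonic vectors directly from the release
scenario (by default drive homozygotes replacing a fraction of
population-one males), so released individuals pass through selection
before their first mating; population two starts all wild-type.

### Where normalisation happens, and why it matters

Only the zygote vector is normalised. Downstream vectors keep their mass,
which after selection equals the cohort's mean survival. The practical
consequence is confined to migration: pools mix *in proportion to their
surviving mass*, so a drive-laden population (mean fitness below 1)
contributes proportionally fewer migrants than a wild-type one. We adopted
this after comparing the two variants: per-stage renormalisation inflates
the drive's spread into the neighbouring population by one to two
percentage points in the daisy-chain scenarios (it is invisible for the
single-element drive), and only the once-per-generation scheme reproduces
all the package's benchmark outcomes simultaneously. Migration itself acts
on adults; because the germline conversion matrix is linear and shared by
both populations, placing migration just before or just after meiosis is
algebraically identical, and we fix it after conversion for clarity.

## Cutting and repair

A locus can be cut in an individual only if three things are present
together: a gRNA targeting it, at least one `T` allele there, and a
nuclease. In the **germline** both gRNA and nuclease must be genomically
encoded. In the **embryo** they come from the mother: either the
co-deposited Cas9:gRNA complex, or deposited Cas9 protein paired with a
gRNA expressed from the zygote's own genome (typically paternally
inherited). A gRNA is only deposited in complex with Cas9 — a mother
expressing a gRNA but no nuclease deposits nothing.

An eligible `T` is cut with probability `kappa` (`kappa_dep` in the
embryo). A cut resolves to interhomolog HDR with fraction `alpha` — the T
converts to *whatever allele sits on the homologous chromosome*, which is
how resistance alleles, not just drive elements, get copied ("biased") —
or to `R1` with fraction `(1 - alpha) * beta`, or to `R2` with the rest.
At a neutral insertion locus every loss-of-function mutation is silent, so
the type-1 fraction is forced to 1 there. Early embryos are assumed unable
to perform HDR (`alpha_dep = 0`), so deposition only ever produces
resistance alleles; the `shadow_drive` flag relaxes this for the
deposited-Cas9 + genomic-gRNA combination, which then borrows the germline
HDR rate (co-deposition of the gRNA takes precedence and stays HDR-free).

Doubly wild-type (`TT`) loci — reachable by machinery expressed from
*another* locus, the phantom-cutting configuration — are handled by
`tt_mode`:

* `"no_hdr"` (default): each `T` is cut independently at `kappa` with HDR
  disabled, since the only homologous template is another (possibly
  simultaneously cut) `T`.
* `"sequential"`: the alleles are cut one at a time; the first repair can
  HDR-copy the still-intact `T` homolog (regenerating `T`), the second
  uses the first allele's post-repair state as its template. One round
  each, no recursion. This variant is our reading of "cut one by one" and
  should be treated as qualitative; the two modes bracket the plausible
  behaviours and lead to the same ranking of designs.

Loci convert independently within one germline; chromosomal abnormalities
from simultaneous double-strand breaks are not modelled.

## Fitness

Fitness is multiplicative over cost-bearing alleles, each dominant value
applied once regardless of copy number, optionally sex-specific. A locus
can carry a recessive value triggered when both alleles are
loss-of-function (its drive allele or `R2`). Defaults
(`fitness_preset("fig_defaults", design)`): A-locus drive 0.90 (imperfect
rescue of the haploinsufficient target gene plus general costs), B and C
drives 0.95 each, `R2` at A dominant lethal (0), everything else neutral —
a triple-element carrier has fitness 0.90 x 0.95 x 0.95 = 0.81225.
Suppression presets replace the A rescue with a recessive (optionally
female-limited) lethal. Parameters are dimensionless probabilities and
relative viabilities throughout; migration rates are per-generation
fractions.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `kappa` | 1.0 | germline cut probability per eligible T |
| `alpha` | 0.95 | HDR fraction of germline cuts |
| `beta` | 0.1 | type-1 fraction of non-HDR repair (haplolethal locus) |
| `kappa_dep` | 0 | embryonic (maternal deposition) cut probability |
| `alpha_dep` | 0 | embryonic HDR fraction |
| `beta_dep` | 0.1 | embryonic type-1 fraction |
| `m12 / m21 / m2w` | 0.01 / 0.005 / 0.005 | migration fractions (from pop 2; from pop 1; wild-type influx) |
| release | 25% of pop-1 males (0.25% for the single-element drive) | drive-homozygote fraction at generation 1 |
| generations | 100 | simulation length |

The state space is modest: 10 diploid genotypes for the single-element
drive, 180 for a three-locus chain, 1800 when deposition tags are
enumerated (tags collapse to one null tag whenever `kappa_dep = 0`). A
100-generation, two-population run takes well under a second; the full
benchmark set in `scripts/acceptance.R` runs in seconds.

## Design choices worth knowing about

* **Canonical states.** Within a locus the allele pair is unordered, but
  states whose parental tags differ are distinct: paternal-Cas9-only and
  maternal-Cas9-only mirrors of the same genotype behave differently in
  the embryo. Zygote-stage reporting sums over tags and over functionally
  equivalent genotypes — tags are developmental bookkeeping, not genetics.
* **Paternal bookkeeping.** The paternal Cas9 marker is carried even
  though no preset uses paternal deposition, keeping the state space ready
  for such configurations. Paternally contributed gRNA *genes* need no tag
  at all: they are ordinary inherited alleles, visible in the genotype,
  which is exactly how the shadow-drive eligibility rule finds them.
* **Deposited gRNA with zygotic Cas9** (the reverse of shadow drive) is
  disallowed: an isolated gRNA is assumed too unstable to persist until
  zygotic nuclease expression.
* **Tag enumeration** is the full cross-product of the structural
  possibilities (maternal gRNA sets crossed with Cas9 markers), not pruned
  to reachable combinations; unreachable states simply keep zero
  frequency. This costs a constant factor in matrix size (10x for a
  three-locus chain with two gRNAs) and buys index stability across
  parameterisations.
* **Migration in generation 1** follows the same per-generation order as
  every other generation; at the default 1% rates the alternative
  (starting exchange at generation 2) changes peak frequencies by well
  under a tenth of a percentage point. Migration is sex-symmetric.
* **Generation indexing**: the release generation is generation 1, and
  peak timings are reported in that convention.

## Numerical behaviour

Transition-matrix rows are validated to sum to 1 within 1e-12 at
construction; reported zygote vectors sum to 1 within 1e-9 over a full
run. The recursion involves only non-negative linear maps and one
normalisation per generation, so there is no step-size or convergence
tuning anywhere. A configuration whose every genotype is inviable stops
with a population-collapse error rather than dividing by zero. Sweeps
(`run_sweep()`) are cell-independent and deterministic; a failing cell is
recorded in an `error` column without aborting the grid.

## Validation, and what it does not show

The test suite checks the engine against independent oracles rather than
against itself: an exhaustive per-allele enumeration of cut/repair
outcomes for single conversion rows; a closed-form recursion
`q' = 1 - (1 - q)^2` for an ideal cost-free drive, which the engine matches
to machine precision; equivalence of the direct and indirect chains when
no type-1 alleles can arise and type-2 is lethal (their difference is
driven entirely by phantom-cut biasing of `R1`); and an individual-based
Wright–Fisher simulator with 10^6 individuals over 10 generations, whose
trajectory must stay within three binomial standard errors of the
recursion, inflated by the square root of elapsed generations because each
generation injects fresh, independent sampling noise.

These checks validate the recursion's internal correctness, not its
biological realism. The model is deliberately spare: panmictic demes with
constant exchange fractions, no population-size dynamics (suppression
scenarios track genotype frequencies only), no age structure, no linkage
or recombination distance between chain elements, no paternal deposition,
single-draw germline conversion (no within-germline mosaicism), and
deposition treated as uniform across progeny. Conclusions about relative
design performance — direct versus indirect chains, deposition versus
cut-rate sensitivity — are the intended use; absolute frequencies in any
real release will depend on the ecology this model omits.
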