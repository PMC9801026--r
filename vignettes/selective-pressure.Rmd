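---
title: "Estimating selective pressure on coding and non-coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating selective pressure on coding and non-coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaksr)
```

## The model and its assumptions

All estimators in `kaksr` work on a *pair* of aligned homologous sequences
and assume (i) a correct alignment, (ii) independent evolution of sites (or
codons) under a time-reversible Markov substitution process at stationarity,
and (iii) no insertions/deletions after the cleaning step — gap columns are
removed, codon-column-wise for coding pairs (to preserve the reading frame)
and single-column-wise for non-coding pairs. Stop-codon columns are removed
from coding pairs; the estimators themselves never see a stop codon, and
substitution paths through stop codons carry zero rate (approximate methods
exclude stop-passing mutation pathways, falling back to including them only
when *every* pathway is blocked, so that synonymous plus nonsynonymous
differences always add up to the observed nucleotide differences).

### Coding sequences: omega = Ka/Ks

`Ka` and `Ks` are nonsynonymous and synonymous substitutions *per site of
the respective kind*. The counting methods differ in how they count sites
and differences and in the multiple-hit correction:

* **NG** enumerates all single-nucleotide mutations of every codon
  (mutations creating stops are excluded from the per-position divisor),
  averages difference classifications over all orderings of multi-step
  codon changes, and applies the Jukes–Cantor correction to both
  proportions.
* **LWL / LPB** classify each codon position as 0-, 2- or 4-fold degenerate
  (3-fold isoleucine sites are binned as 2-fold, the classical convention)
  and apply Kimura-2-parameter corrections per class. When the two codons
  of a pair disagree about a site's class, the difference is attributed to
  the more degenerate class if synonymous and to the less degenerate class
  otherwise — the classical attribution rule; an symmetric half-half split
  was evaluated and found to bias omega downward by several percent at
  high omega because nonsynonymous transitions leak into the synonymous
  2-fold distance.
* **MLWL / MLPB** additionally (a) estimate the transition/transversion
  rate ratio kappa from the pooled K2P distance components and let a
  2-fold site count as synonymous for the fraction `kappa/(kappa+2)` of
  mutations (LWL's 1/3 is the kappa = 1 special case), and (b) classify
  2-fold differences by their *actual* synonymity, which handles the
  arginine (CGA↔AGA-type, synonymous transversion) and isoleucine
  (ATA↔ATT/ATC, plus the nonsynonymous transition ATA↔ATG) codon families
  in both directions.
* **YN / MYN** iterate: codon frequencies are estimated by F3x4; kappa (or
  the separate purine/pyrimidine ratios kappa_R, kappa_Y for MYN) is
  estimated from the unconstrained 0- and 4-fold site classes by closed-form
  moment inversion of the K2P (respectively TN93) model; sites are counted
  with mutation-opportunity weights `kappa^ts * pi(target codon)`;
  differences are counted with pathway weights that include the current
  omega; synonymous and nonsynonymous proportions are corrected by K2P
  (TN93) and omega is updated until `|delta omega| < 1e-6` (at most 100
  iterations, flagged as non-converged past that). Starting values are
  omega = 0.5 and a kappa fallback of 2 when the moment estimators leave
  the log domain.

The maximum-likelihood family uses the Goldman–Yang codon model: a 61×61
generator with `q_ij = 0` for multi-nucleotide changes, `r_xy pi_j` for
synonymous and `omega r_xy pi_j` for nonsynonymous single-nucleotide
changes, scaled to one expected substitution per codon per unit divergence
`t`. The pair likelihood is `sum_columns log(pi_i P(t)_ij)` with
`P(t) = expm(Q t)` computed by symmetric eigendecomposition (the chain is
reversible), in compiled code. `Ka` and `Ks` are derived from the fitted
generator as `t * rho_S / (3 * S_prop)` and `t * rho_N / (3 * N_prop)`,
where `rho` are the synonymous/nonsynonymous flux fractions of the fitted
matrix and the `prop` terms the mutational-opportunity fractions of the
same matrix at omega = 1.

### Model selection and averaging

The candidate set is fixed and ordered: JC, F81, K2P, HKY, TNEF, TN, K3P,
K3PUF, TIMEF, TIM, TVMEF, TVM, SYM, GTR — ten exchangeability structures,
the symmetric ones twice (equal base frequencies vs F3x4). Codon
frequencies are *held fixed* at their F3x4 estimates during optimization,
keeping the search 3–8 dimensional. The information criterion is
`AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)` with `n` the number of aligned
codons (one observation per codon column) and `k` counting `t`, `omega`,
the free exchangeability parameters *and the nine F3x4 position-specific
base frequencies* for unequal-frequency models. Counting the data-estimated
frequencies matters: without it the F3x4 variants beat the true
equal-frequency structure on pure fit noise at zero penalty. Ties are
broken by fewer parameters, then candidate order. MA averages Ka and Ks
with Akaike weights and reports `omega = mean(Ka)/mean(Ks)` so the MA row
is internally consistent with its own columns.

### Non-coding sequences: xi = Kn/Ks

`Kn` corrects the observed transition (S) and transversion (V) proportions
for multiple hits under JC, K2P, or HKY; HKY is the default because it is
the most general of the three, weighting the four base frequencies (taken
as the average over both sequences of the pair — the pair is the only
frequency information available). At equal frequencies HKY collapses
exactly to K2P; outside the log domain (saturation) all three report `NA`
rather than an arbitrary cap. The neutral rate Ks comes either from the
user or from adjacent coding pairs; with several neighbours each yields
its own Ks, so one xi is reported per (non-coding, coding) combination —
neighbouring genes genuinely disagree and the choice is the user's. The
positive/negative selection call is the exact inequality `xi > 1`
(equivalently `Kn > Ks`), with no tolerance band.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `code_table` | 1 | NCBI translation table (1–33 supported by data table) |
| `model` (coding ML) | HKY | exchangeability structure for single-model `GY` fits |
| `model` (non-coding) | HKY | multiple-hit correction for Kn |
| `cds_method` | MYN | coding method supplying Ks in adjacent-CDS mode |
| omega iteration | 1e-6, 100 | YN/MYN convergence threshold and cap |
| ML bounds | t, omega in [1e-6, 50] | box constraints, optimized in log space |
| multi-starts | (0.1, 0.5, 2), (1, 1, 2), (0.5, 0.1, 5) | fixed (t, omega, kappa) initial points |

All thresholds are fixed constants rather than user-visible knobs; they are
reported here so results are reproducible from the description alone.

## The simulator, and what passing tests show

`simulate_pair()` draws an ancestor from the model's equilibrium
distribution and evolves two independent descendants for `t/2` each using
exact transition probabilities `expm(Q t/2)` — matrix-exponential sampling
rather than event-by-event simulation, so it is exact at any divergence.
Seeds are mandatory and echoed into fixture names. The simulator emulates
homogeneous, stationary, reversible substitution without indels or
across-site rate heterogeneity; real alignments violate all of these to
some degree, so parameter-recovery results bound estimator *correctness
under the assumed model*, not field accuracy. Recovery tests pair each
estimator with its own assumed generator (JC-structure simulations for
NG/LWL/LPB, kappa = 2 K2P simulations for the kappa-aware methods and the
ML fits); this matched-model design is deliberate — mismatched-model
behaviour is a property of the model, not a defect of the estimator.

Problem sizes used by the test suite were chosen to keep Monte-Carlo error
well under the asserted tolerances: 5,000-codon pairs and 50 replicates for
omega recovery (median within ±15%, sign of omega − 1 correct in ≥90% of
replicates), 100-kb pairs and 20 replicates for Kn recovery (bias < 2% at
d = 0.05, 0.2, 0.5), 800-codon pairs and 50 replicates for the
model-selection study (the generating K2P structure, an equal-frequency
structure nesting it, or anything within 2 AICc units must lead in ≥80% of
replicates). The acceptance script reports reduced-size analogues of these
studies so a full reproduction stays fast.

## Numerical choices and degenerate inputs

* Undefined ratios are `NA`, never `Inf`: omega requires `Ks > 0`, xi
  requires a positive neutral rate.
* Saturated distance arguments (JC proportion ≥ 3/4, non-positive K2P/HKY
  or TN93 log arguments) yield `NA` fields, not errors.
* Identical pairs short-circuit to `Ka = Ks = 0` with an undefined ratio;
  ML fits drive `t` to its lower bound.
* Site counts are averaged arithmetically between the two sequences; F3x4
  frequencies are floored at 1e-8 and renormalized so observed codons never
  carry zero equilibrium mass.
* Batch processing never aborts: per-pair failures become `NA` rows with a
  warning, and the tab-delimited writer renders missing values as `"NA"`
  with 6 significant digits for stable textual diffs.
* Kappa moment estimators are clamped to [0.01, 99] and fall back to fixed
  constants (1 for the LWL family, preserving the classical behaviour; 2
  for YN/MYN) when the observed proportions leave the log domain.

## Known limitations

Only pairwise comparisons are supported — no phylogeny-aware, branch or
site models, no sliding windows, and no codon-frequency maximum-likelihood
estimation. Ambiguity codes are stripped rather than resolved. The
published comparison table for the three human–mouse lncRNA loci can only
be reproduced at the arithmetic level (ratios of the printed rates): the
underlying RefSeq alignments and the exact method/model used for the
printed Kn and Ks values are not part of this package's inputs.
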