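---
title: "Auditing FDR control with entrapment experiments: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing FDR control with entrapment experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrapbench)
```

## The estimation problem

A search tool reports discoveries at a nominal FDR threshold, but the
realized false discovery proportion (FDP) of any one report is
unobservable. An entrapment experiment makes part of it observable:
the original target database $\mathcal{T}$ is augmented with entrapment
sequences $\mathcal{E^T}$ known to be absent from the sample, and the
tool is run on $\mathcal{T}\cup\mathcal{E^T}$, blinded to the labels.
Every entrapment discovery is then a certified false positive, and with
$N_\mathcal{T}$, $N_\mathcal{E}$ the original-target and entrapment
discovery counts and $r$ the effective entrapment-to-target database
ratio, the package computes:

* **combined**: $N_\mathcal{E}(1 + 1/r)/(N_\mathcal{T}+N_\mathcal{E})$ —
  an upper bound, in expectation, on the FDP of the pooled discovery
  list. The $1/r$ term accounts for the false original-target
  discoveries that the entrapment discoveries imply; dropping it (a
  common mistake in the literature) turns the estimate into the lower
  bound below.
* **lower bound**: $N_\mathcal{E}/(N_\mathcal{T}+N_\mathcal{E})$ —
  always a lower bound, because it counts only the *certified* false
  discoveries. It can expose invalid FDR control, never establish valid
  control.
* **sample**: $(N_\mathcal{E}/r)/N_\mathcal{T}$ — an attempt to estimate
  the FDP among the original-target discoveries only. It is not a bound
  in either direction, so the package flags its output as `"not a valid
  bound"`; it exists for comparison with published analyses that used
  it.
* **paired**: with each original target bound to a unique shuffled
  entrapment ($r=1$),
  $(N_\mathcal{E} + N_{\mathcal{E}\ge s>\mathcal{T}} +
  2N_{\mathcal{E}>\mathcal{T}\ge s})/(N_\mathcal{T}+N_\mathcal{E})$,
  where $s$ is the discovery cutoff score,
  $N_{\mathcal{E}\ge s>\mathcal{T}}$ counts discovered entrapments whose
  paired target scored below $s$, and
  $N_{\mathcal{E}>\mathcal{T}\ge s}$ counts those whose paired target
  was discovered but beaten. The head-to-head comparison sharpens the
  inference about how many original-target discoveries are false,
  yielding an upper bound that is tighter than the combined one
  (particularly at small $r$ and large native fractions) while keeping
  its averaged upper-bound nature.

The sample and lower-bound estimators answer about the same list only in
opposite failure directions; a practitioner arguing *for* FDR control
needs the combined or paired estimate, and one arguing *against* needs
the lower bound. All estimates are capped at 1 for reporting (FDP is a
proportion); the uncapped value is retained in the `"raw"` attribute.

### The k-matched generalization

When each target is uniquely associated with $k$ entrapments ($r=k$),
the package computes

$$\widehat{\mathrm{FDP}}_k \;=\;
\frac{N_\mathcal{E} + \bigl(N_{\mathcal{E}\ge s>\mathcal{T}} +
2N_{\mathcal{E}>\mathcal{T}\ge s}\bigr)/k}
{N_\mathcal{T}+N_\mathcal{E}}.$$

The design question here was genuinely open: the paired numerator terms
infer, from each entrapment-versus-target comparison, false-discovery
mass for the *target*; with $k$ entrapments per target that mass would
be counted up to $k$ times, so the implementation averages it over the
$k$ comparisons. This reduces exactly to the paired estimator at $k=1$,
always dominates the lower bound, and its averaged upper-bound direction
is verified by the Monte-Carlo oracle below (500 null-only replicates in
the test suite). The weighting is recorded in the `"weighting"`
attribute of the result.

## Database construction

**Digestion.** Trypsin without proline suppression: cleavage after every
K and R, including before P. The peptide-level database uses one missed
cleavage and a 7–35 residue window; protein-level entrapment
construction digests with zero missed cleavages and no length filter.
The C-terminal peptide is kept whether or not it ends in K/R, and
N-terminal methionine is never clipped (the audited pipelines disable
clipping). I/L are treated as distinct letters everywhere: distinctness
checks use literal string identity.

**Shuffling.** An entrapment peptide is a uniform random permutation of
its target with the C-terminal residue fixed, so tryptic boundaries are
preserved; an ISB18-style variant also fixes the N-terminus. At the
peptide level a candidate must differ from *all* original target
peptides and all previously accepted entrapments (global distinctness);
each target gets $20+r$ total attempts to accumulate $r$ distinct
entrapments and is removed from the database (and logged) on failure —
the low-complexity fixture `"AAAAAAK"` is removed after exactly 21
attempts at $r=1$. At the protein level distinctness is checked
per-peptide (a candidate must differ from its own original), because the
protein-level fallback — an unshufflable peptide keeps its original
sequence so protein length is preserved — is incompatible with a global
requirement. If only $0<n<r$ distinct shuffles are found, the remaining
$r-n$ are drawn with replacement from the $n$. Entrapment protein $j$
concatenates every digested peptide's $j$-th entrapment in original
order, and a peptide shared between proteins is swapped identically
everywhere. Because only the C-terminal residue of each peptide is
pinned, shuffling can relocate internal K/R and create new cleavage
sites; the original cleavage boundaries nonetheless survive, which the
tests verify by re-extracting the swapped peptides at the original
boundary positions.

Peptides containing non-canonical residues (B, Z, X, U, O) survive
digestion but are excluded from shuffle pairing and logged: permuting
them is not meaningful and comparing them to canonical sequences is
unsafe.

**Foreign mode.** Both databases are digested with the peptide-level
settings, foreign peptides equal to any target peptide are removed, and
the remainder is sampled without replacement to reach
$r\times$(surviving targets); at the protein level whole foreign
proteins are sampled. Foreign databases carry no pairing, so only the
combined, lower-bound and sample estimators apply; requesting an
unattainable $r$ is an error that states the achievable maximum.

Builds process targets in sorted order under a single seeded generator,
so a database depends only on the seed, not on input ordering.

## Reference FDR procedures

Target-decoy competition sorts the (score, label) pairs by decreasing
score and rejects at the largest $k$ with
$(D_k+1)/\max(T_k,1)\le\alpha$; `tdcQvalues()` inverts the rule into
per-discovery q-values by a cumulative minimum from the bottom of the
ranking, so thresholding the q-values reproduces the rejection set at
every $\alpha$ — the suite checks this equivalence exhaustively on random
tables, with the same seeded tie-shuffle on both paths. The
PSM-and-peptide procedure applies the double competition (best PSM per
spectrum, max score per peptide, winner per target–decoy pair, unmatched
peptides at $-\infty$, all ties randomly broken). Decoy-based empirical
p-values use the literal decoy-proportion definition
$p(t)=\#\{d\ge t\}/\#d$, which can return 0; an add-one variant is
available but off by default (fidelity first, robustness opt-in). BH
adjustment delegates to `stats::p.adjust`; Storey q-values are computed
in-package with the standard smoother defaults ($\lambda$ grid 0.05–0.95
step 0.05, cubic spline with 3 df evaluated at the largest $\lambda$,
$\hat\pi_0$ capped at 1 and falling back to 1 with a warning on
degenerate inputs), and the estimated $\hat\pi_0$ is attached to the
result.

## The simulator and what it does (not) show

The simulator operationalizes the *equal-chance* assumption that the
estimators' guarantees rest on: absent original targets, foreign
peptides, all entrapments and all decoys draw i.i.d. scores from one
shared null distribution, while truly present peptides draw from a
signal distribution and are observed at all with probability
`detectProb`. Each database peptide competes against its own decoy, and
the winners receive TDC q-values. Defaults: 1,000 native and 4,000
absent database peptides, $r=1$, signal $N(3,1)$, null $N(0,1)$,
`detectProb = 0.7`, 500 replicates — sizes at which the Monte-Carlo
checks resolve the bound directions comfortably on a single CPU in
seconds. The score model is Gaussian by default with a Gumbel option
(search-engine score nulls are extreme-value-like); the estimators'
guarantees are distribution-free, so any exchangeable null is a valid
test bed. A generator audit in the suite confirms exchangeability by
rank tests between the null populations.

`boundExperiment()` redraws every null score in each replicate
(emulating independently rebuilt decoy and entrapment databases),
averages each estimator and the true FDP over replicates, and evaluates
the directional checks with a two-standard-error allowance on the
per-replicate differences: mean lower $\le$ true $\le$ mean combined,
mean paired $\ge$ true, mean paired $\le$ mean combined, and TDC's mean
FDP $\le \alpha$. In double-entrapment mode (`nForeign > 0`, emulating a
controlled mixture spiked into a much larger foreign "original" target
database) it additionally compares the averaged paired estimate with the
direct estimate that counts every foreign or entrapment discovery as
false; agreement is declared when the mean direct estimate lies within
two standard errors of the averaged paired estimate — the same
$\pm 1.96\,\sigma_n/\sqrt{n}$ coverage-band construction used for
replicate-averaged curves. A per-replicate-difference standard error
would be far smaller than either estimator's own Monte-Carlo error
(the two are strongly correlated within a replicate) and would flag the
paired estimator's inherent, sub-discovery-count conservative bias as
disagreement. The double-entrapment test conditions are 500 native
peptides inside 5,000 foreign ones (all absent), $r=1$, 200 replicates.

On the coverage band itself: the band of a replicate-averaged FDP
estimate is reported as $1.96\,\sigma_n/\sqrt{n}$ (standard error of the
mean over $n$ replicate estimates), which is the construction consistent
with a 95% band for an average; the literal $\sigma_n/n$ variant is
available behind the `literal` flag for comparability.

What passing these tests shows — and does not. The simulator validates
the *logic* of the estimators (bound directions, pairing arithmetic,
reduction identities) under exactly the exchangeability the theory
assumes. Real search engines violate pieces of that picture: scores of
distinct peptides are correlated through shared spectra, homologous or
"neighbor" peptides make shuffled (and foreign) entrapments imperfect
proxies for false matches, machine-learned rescoring can leak label
information, and real q-values arrive from the tool rather than from the
package's TDC. Passing the Monte-Carlo checks therefore certifies the
estimators, not any particular search engine; auditing an engine means
feeding its own report through `parseReport()`.

## Numerical and interface choices

* Discovery sets are defined by tool-reported q-values
  ($q\le$ threshold), matching how the audited tools' report columns are
  consumed; when only scores exist, an FDR procedure must be run first.
  The paired cutoff $s$ is the minimum score among the discoveries at
  each threshold.
* Score ties between an entrapment and its paired target, in TDC
  ranking, and in all competitions are broken by a seeded fair coin, so
  results are reproducible and unbiased under exchangeability.
* An original target absent from a report is treated as scoring
  $-\infty$ in the paired classification.
* Protein groups are labeled original if *any* member comes from the
  original target database; entrapment only if all members are
  entrapments. Duplicate report ids collapse to lowest q-value, then
  highest score.
* Default curve grid: 200 logarithmic points from $10^{-4}$ to the
  largest reported q-value.
* Estimates are capped at 1 for reporting; raw values retained in
  attributes.

## Problem sizes used by the test suite

The Monte-Carlo blocks run 500 replicates of the 1,000 + 4,000 default
configuration (bound directions and TDC control), 500 null-only
replicates at $k=r=2$ (k-matched direction), and 200 double-entrapment
replicates at 500 + 5,000 ($r=1$); oracle-equivalence blocks use 100
random tables/vectors each. These sizes resolve every directional check
at two Monte-Carlo standard errors and complete in well under a minute
on one CPU.

## Known limitations

* The paired estimator requires shuffled mode ($r=1$, or $r=k$ for the
  k-matched variant); foreign databases support only the unpaired
  estimators, and the package refuses the paired method there rather
  than guessing a pairing.
* The exact k-matched weighting is this package's construction (the
  considerations above); alternatives satisfying the same $k=1$
  reduction and bound direction exist.
* Spectrum-level simulation (peaks, retention time, chromatograms) and
  engine-specific score calibration are out of scope; scores are taken
  as given.
* PSM-level FDP estimation is deliberately not a headline output;
  peptide-, precursor- and protein-group-level analyses are.
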