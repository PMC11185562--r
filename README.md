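# entrapbench

Entrapment-based auditing of false discovery rate (FDR) control in tandem
mass spectrometry analysis.

## The problem

Proteomics search engines report discoveries — precursors, peptides,
protein groups — at a user-chosen FDR threshold, but the tool's own FDR
estimate can be wrong, and the realized false discovery proportion (FDP)
of a given report cannot be observed directly. An *entrapment experiment*
audits a tool from the outside: the original target database 𝒯 is
augmented with entrapment sequences ℰ𝒯 that are known to be absent from
the sample (shuffled copies of the targets, or a foreign proteome), the
tool is run on the combined database, and every entrapment discovery is a
certified false positive. From the counts of original-target discoveries
N<sub>𝒯</sub> and entrapment discoveries N<sub>ℰ</sub>, with r the
effective entrapment-to-target database ratio, the package computes four
estimates of the FDP in the reported list:

- **combined** (upper bound on average):
  N<sub>ℰ</sub>(1 + 1/r) / (N<sub>𝒯</sub> + N<sub>ℰ</sub>)
- **lower bound** (always a lower bound):
  N<sub>ℰ</sub> / (N<sub>𝒯</sub> + N<sub>ℰ</sub>)
- **sample** (not a valid bound in either direction; reported for
  comparison): (N<sub>ℰ</sub>/r) / N<sub>𝒯</sub>
- **paired** (tighter upper bound; needs each target paired to a unique
  shuffled entrapment, r = 1):
  (N<sub>ℰ</sub> + N<sub>ℰ≥s&gt;𝒯</sub> + 2·N<sub>ℰ&gt;𝒯≥s</sub>) /
  (N<sub>𝒯</sub> + N<sub>ℰ</sub>), where s is the discovery cutoff
  score, N<sub>ℰ≥s&gt;𝒯</sub> counts discovered entrapments whose paired
  target fell below the cutoff, and N<sub>ℰ&gt;𝒯≥s</sub> counts those
  whose paired target was discovered but scored lower. A k-matched
  generalization handles k entrapments per target (r = k).

A tool controls the FDR if its reported threshold stays above the lower
bound and, ideally, above a (paired/combined) upper bound; the package
also computes FDP-versus-threshold curves, 95% coverage bands over
replicate databases, discovery-inflation rates, and the "direct" FDP
estimate available in double-entrapment designs.

The package is aimed at developers and assessors of proteomics /
metabolomics search engines and FDR procedures. It builds the entrapment
databases (in-silico tryptic digestion, C-terminal-fixed shuffling at any
ratio r, peptide or protein level, shuffled or foreign mode), parses
search-tool reports into a common discovery-table format, provides
reference FDR procedures to audit (target-decoy competition,
PSM-and-peptide double competition, decoy-based empirical p-values with
BH or Storey adjustment), and ships a calibrated simulator with known
ground truth so every directional guarantee is testable without any
external data.

## Worked example

Build a paired entrapment database from a synthetic proteome, simulate a
search with known ground truth, and audit TDC's FDR control:

```r
library(entrapbench)
set.seed(42)
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
prots <- vapply(1:30, function(i)
  paste(sample(aa, 120, replace = TRUE), collapse = ""), character(1))
names(prots) <- sprintf("SYN%02d", 1:30)

targets <- buildPeptideDb(prots)    # trypsin, 1 missed cleavage, 7-35 aa
targets
#> PeptideSet with 447 unique peptides from 30 proteins

db <- generatePairedPeptideDb(targets, r = 1, shuffleConfig(seed = 42))
db
#> PairedEntrapmentDB (peptide-level, shuffled mode)
#>   r = 1; 447 surviving targets; 447 entrapment entries; 0 removed

search <- simulateSearch(simConfig(nNative = 300, nAbsent = 1200,
                                   seed = 42))
fdpCurve(search$table, thresholds = c(0.01, 0.05, 0.1))
#>   threshold n_target n_entrap  lower combined paired
#> 1      0.01        0        0 0.0000   0.0000 0.0000
#> 2      0.05      117        4 0.0331   0.0661 0.0661
#> 3      0.10      140        8 0.0541   0.1081 0.1081

trueFdp(search, 0.05)
#> [1] 0.0661157
```

At the 5% threshold the list of 121 discoveries contains 4 entrapments:
the lower bound (3.3%) and the paired/combined upper bound (6.6%) bracket
the realized FDP (6.6% here, known only because the data are simulated),
so the audit is consistent with TDC controlling the FDR at this level; at
the 1% threshold this small simulation yields no discoveries at all. A
single realization is noisy — `boundExperiment()` averages the estimates
over hundreds of replicate databases and checks every bound direction
with Monte-Carlo standard errors, and `coverageBand()` reproduces the
±1.96·σ<sub>n</sub>/√n bands used for replicate-averaged curves.

A thin command-line front end covers the same workflow
(`inst/scripts/entrapbench` with subcommands `build-db`, `fdr`,
`estimate`, `simulate`, `demo`).

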