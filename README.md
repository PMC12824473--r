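# y90profiler

Tools for linking in-vitro yttrium-90 (⁹⁰Y) microsphere dose–response
phenotypes to baseline transcriptomic signatures in liver cancer cell-line
panels. Transarterial radioembolization delivers ⁹⁰Y-loaded microspheres to
hepatic tumors; why genetically distinct tumors respond so differently to
the same absorbed dose is largely unexplained. This package implements the
in-vitro analysis chain for that question — viability phenotyping, feature
selection against the phenotype, and transcriptomic subtype assignment —
together with a synthetic-data generator that provides ground truth for
every stage, so the whole pipeline is testable without access to raw assay
data.

## What it computes

**nAUC phenotype.** Each line's surviving-fraction curve over an activity
ladder A ∈ {0, 0.1, 0.5, 1, 2, 4, 10, 20} MBq/mL is normalized to its
untreated control, integrated by the trapezoid rule (AUC_Δ), and divided by
the flat-100%-survival reference area AUC_R = A_max − A_min:

    nAUC = AUC_Δ / AUC_R ∈ [0, 1],   1 = fully resistant, 0 = fully sensitive.

Lines are grouped by the Z-score of their mean nAUC (defaults: z ≥ 0
resistant, z ≤ −0.45 sensitive), and between-line differences are tested by
one-way ANOVA with Tukey HSD.

**Bootstrap elastic-net stability selection.** Baseline log-CPM expression
(genes standardized to mean 0, SD 1) is regressed on the per-line nAUC with
an elastic net, refit on B = 100 bootstrap resamples of the lines (penalty
chosen by inner 3-fold cross-validation per resample). Each gene's EN score
is its sign-consistency frequency, score = max(freq₊, freq₋), and genes
with score ≥ 0.7 are retained.

**Nearest template prediction.** Each sample is assigned the subtype whose
marker template (unit-normalized ±1 pattern over the marker genes) is
nearest in cosine distance, with significance from a marker-label
permutation null and BH FDR across samples; subtype–phenotype association
is tested by Kruskal–Wallis.

**Dosimetry utilities.** MIRD-style absorbed dose from activity
concentration (complete decay, local absorption: 20 MBq/mL ≈ 994 Gy, i.e.
the ladder spans ~0–1,000 Gy), radioactive decay, half-life counting, and
qPCR ΔCt/ΔΔCt conversions.

**Surrogate differential expression.** A deliberately transparent Welch
test on log-CPM between resistant and sensitive groups, the strict
FDR < 0.05 & |log₂FC| > 2 filter, and gene-set mean log₂FC summaries.

## Worked example

The `analysis/` scripts run the whole chain on a simulated ten-line cohort
(`Rscript analysis/01_simulate_cohort.R` through `05_de_pathways.R`).
Stage 02 prints the phenotype table:

```
 cell_line mean_nauc     sem         z        group
       L02     0.902 0.05014  1.216306    resistant
       L01     0.868 0.05640  1.009816    resistant
       ...
       L09     0.556 0.00365 -0.888888    sensitive
       L10     0.357 0.01142 -2.104633    sensitive

One-way ANOVA across lines: F = 32.83, P = 4.66e-10
Top of ladder (20 MBq/mL) = 994 Gy absorbed dose
10-day exposure spans 3.74 half-lives
```

mean nAUC is each line's replicate-averaged normalized viability area (1 =
no response at any activity); the ANOVA confirms the lines' phenotypes
differ far beyond replicate noise. Stage 03 then recovers the
phenotype-linked genes planted by the simulator:

```
 gene  score mean_coefficient pearson_r
G0456   0.79         -0.00381    -0.915
G0415   0.77         -0.00444    -0.950
G0342   0.75         -0.00443    -0.943
G0098   0.72          0.00485     0.957

Recovery vs planted truth: recall 0.80, precision 1.00
```

Each retained gene entered the bootstrap elastic net with a consistent
coefficient sign in ≥ 70% of resamples; the sign agrees with the gene's
full-data Pearson correlation with nAUC. Stage 04 assigns every line to
its true simulated subtype (accuracy 1.00) and finds nAUC differs across
subtypes (Kruskal–Wallis H = 7.85, P = 0.0197).

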