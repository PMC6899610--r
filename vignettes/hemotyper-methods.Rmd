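---
title: "Methods: carrier inference, combinatory genotyping, and the HbF scan"
author: "hemotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carrier inference, combinatory genotyping, and the HbF scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemotyper)
```

This vignette is the package's account of its science: the models and
procedures implemented, the assumptions behind them, the parameters a
user may want to tune, and the choices made where the design was
genuinely open.

## The diagnostic problem

Hemoglobinopathy diagnosis integrates three signals. First, red-cell
indices: thalassemia carriers are microcytic (low MCV) and hypochromic
(low MCH), and the HbA2 fraction separates β- from α-thalassemia traits.
Second, genotype: β-thalassemia alleles are classed by residual β-globin
output (β⁰ none, β⁺ reduced, plus the structural variants Hb E, Hb S and
dominant alleles), while α-thalassemia is mostly copy-number variation —
whole named haplotype alleles deleting one (-α3.7, -α4.2) or both
(--SEA, --THAI, --FIL) α genes, nondeletional alleles such as Hb
Constant Spring, and the multi-copy ααα/αααα alleles. Third, modifiers:
variants that raise fetal hemoglobin (XmnI/HBG2, BCL11A, HMIP) or act on
erythroid transcription (KLF1) shift the clinical course of biallelic
β-thalassemia between transfusion-dependent major (TM) and intermedia
(TI), and biallelic KLF1 zinc-finger genotypes produce an atypical
microcytic hypochromic anemia of their own.

## Carrier-inference decision tree

`infer_trait()` implements the routine screening cascade as a
deterministic threshold tree:

| parameter | default | unit | meaning |
|---|---|---|---|
| `mcv` | 82 | fL | microcytosis cut-off |
| `mch` | 27 | pg | hypochromia cut-off |
| `hba2_low` / `hba2_high` | 2.5 / 3.5 | % | HbA2 discrimination window |
| `hbf` | 5 | % | elevated-HbF rule for screen-negative samples |
| `ferritin` | 12 | ng/mL | iron-deficiency caveat |

The defaults are the internationally standard screening cut-offs used in
routine thalassemia programs; they are deliberately exposed in
`screening_thresholds()` because laboratories calibrate them locally, and
the result object echoes the configuration used so that every call is
auditable. Age and sex are recorded but do not alter the default
cut-offs; a per-age threshold table can be supplied by constructing a
different configuration per stratum. Two caveats are structural rather
than optional: a `normal` call always carries
`silent_carrier_not_excluded`, because silent thalassemia (single-gene α
deletions, mild β⁺ alleles) presents with normal or borderline indices;
and a low ferritin adds `iron_deficiency_caveat` with a recommendation
to re-screen when iron-replete, because iron deficiency mimics (and
masks) the thalassemia indices. Missing ferritin asserts nothing in
either direction. A positive screen without a measured HbA2 is
`not_evaluable` — the tree refuses to guess.

## The combinatory severity engine

`classify()` works on a genotype profile: two named α haplotypes, two β
allele classes, and modifier doses. The α call is pure dosage — the sum
of functional genes across the two haplotypes (4 normal, 3 silent
carrier, 2 trait, 1 Hb H disease, 0 Hb Bart's hydrops fetalis, ≥5
triplication). Nondeletional alleles count one functional gene and flag
the more severe nondeletional Hb H when relevant.

The β baseline maps the allele pair: β⁰/β⁰ → TM; β⁺/β⁺ → TI; one
thalassemia allele → minor (carrier); HbE/β⁰ → HbE/β-thalassemia at TM;
βS-containing disease genotypes → sickle cell disease. Two baselines were
genuinely open and are therefore configuration, not constants, in
`classify_rules()`:

* **β⁰/β⁺ baseline = TM.** The clinical course of this compound
  heterozygote is variable, but within this engine α triplication never
  downgrades a biallelic genotype, and the curated case set contains a
  β⁰/β⁺ + ααα/αα patient with thalassemia major; TM is the only baseline
  consistent with both, and it is overridable for laboratories that
  grade it TI.
* **HbE/β⁰ baseline = TM**, with the same downgrade rules as other
  biallelic genotypes; HbE/β⁺ starts at TI.

Modifier adjustments fire in a fixed order and are logged by name in
`modifier_notes`, so the final severity can be replayed from the
baseline — determinism and auditability are design requirements, not
conveniences:

1. biallelic KLF1 zinc-finger variants on a β-normal background →
   atypical thalassemia (microcytic hypochromic anemia), severity TI;
2. biallelic β-thalassemia + ≥1 KLF1 zinc-finger allele: TM → TI;
3. biallelic β-thalassemia + the significant-modifier combination: TM →
   TI. The combination is co-inherited α disease-causing variation
   **plus** HbF-raising alleles at `k_significant` (default 2) of the
   three SNP loci {XmnI, BCL11A, HMIP}. The four-locus pattern is
   described as a set without per-patient detail, so the threshold `k`
   is exposed rather than hard-coded; the default 2 makes the canonical
   "all four" pattern fire while not requiring every locus.
4. heterozygous β-thalassemia + α triplication/quadruplication
   (functional dosage ≥5): upgrade to TI;
5. biallelic β-thalassemia + α triplication: explicitly **no**
   downgrade (the extra α chains worsen, not relieve, chain imbalance).

Severities not representable as β-thalassemia grades are mapped
conservatively into the same five-level scale (`none`, `carrier`, `TI`,
`TM`, `lethal`): sickle cell disease and Hb H disease report TI
(clinically significant, not transfusion-dependent by default), Hb
Bart's hydrops reports `lethal` with a prenatal-significance note, and
atypical thalassemia reports TI. Genotype–modifier combinations no rule
covers keep their baseline and log `no_rule_applied`. GATA1 variants are
annotated but drive no combinatory rule. How a simultaneous
β⁰/β⁰ + ααα + KLF1 genotype should be labelled is unknowable from the
available evidence; the declared rule order above (KLF1 downgrade fires,
the triplication note is still logged) is a deliberate, documented
convention.

## Mendelian at-risk assessment

`offspring_distribution()` segregates each locus independently: the two
α haplotypes of a parent are transmitted as whole units at probability
1/2 (no recombination within the cluster is modelled), β alleles
likewise, and each modifier locus transmits an allele with probability
dose/2. Genotypes identical up to allele order are merged. Independence
between the β-globin locus and the HBG/HBD neighbours is a documented
simplification — the cluster is physically linked, but no recombination
model is available at this scale, and variants explicitly phased `cis`
are kept on one haplotype. `assess_risk()` classifies every outcome and
flags the couple at risk if any offspring genotype has severity TI, TM,
or lethal, or Hb H disease / hydrops at the α locus, with the
probability always reported so counselors see magnitude. Carrier-only
outcomes and benign Hb variants never trigger risk; they appear as
reminders, as do modifier-carriage probabilities of the offspring (both
the parental list and the offspring probabilities are emitted, since
either may be the quantity a counselor wants).

## The HbF association scan

`hbf_scan()` tests each variant by comparing the HbF trait between
carriers (dose ≥ 1) and non-carriers with a two-sided Welch (unequal
variance) test. Dominant carrier coding is the primary model because the
reported quantity of interest is the pair of group means; an additive
linear model on dose is available behind `model = "additive"` and the
choice is recorded in the result's metadata. `Frequency` in the result
table is the carrier frequency of the alternative allele — the fraction
of samples with at least one copy — which is the definition consistent
with values near 0.99 pairing with small carrier-group mean shifts.
Variants with fewer than `min_group_size = 2` samples in either group
are skipped, and the Bonferroni denominator is the number of variants
actually tested, logged in the result attributes. The zero-variance
degenerate case (both groups constant) returns p = 1 for equal means and
p = 0 otherwise, the limit of the test. Statistical association cannot
localize causal variants within a haplotype block; the printed report
carries that caveat, and no LD pruning is attempted.

## The synthetic cohort generator

`simulate_cohort()` draws two alleles per locus under Hardy–Weinberg
from configured frequencies, computes the true diagnosis with the same
rule engine, and samples a hemogram from a diagnosis-conditional normal
distribution clamped to physical ranges. The default allele frequencies
approximate a southern Chinese screening population (≈3.5 % β-thalassemia
or HbE alleles; --SEA the dominant double-gene deletion; modifier allele
frequencies back-computed from curated carrier frequencies via
p = 1 − √(1 − f)). The β-trait hemogram cluster (MCV 67 ± 5 fL,
MCH 21.5 ± 2 pg, HbA2 5.2 ± 0.7 %) is centred so that the canonical
screening example (MCV 73, MCH 24, HbA2 6 %) lies inside it. What the
generator does **not** emulate: linkage disequilibrium and haplotype
structure, age- and sex-specific reference intervals, iron status,
transfusion effects on indices, and measurement error models. Passing
round-trip tests therefore shows the engine and generator share rule
semantics and that the inference tree recovers well-separated clusters —
not that either would perform identically on real laboratory data.

`simulate_assoc_matrix()` draws independent binomial(2, f) genotype
columns and an additive-on-carriers trait with normal residuals; it
supports the noise-free limit (sd = 0) for exact-recovery checks.

## Numerical and testing choices

Probabilities in the Mendelian enumeration are exact rationals in
floating point (sums to 1 within 1e−12 are asserted). Tests exercise:
exhaustive gamete-pair enumeration as the oracle for the merged
offspring distribution (1,000 random couples, ≤3 segregating loci);
family-wise error of the Bonferroni scan on 1,000 pure-noise data sets
of 200 samples × 100 variants; power above 0.9 for a +10 g/L carrier
effect at carrier frequency 0.14 with n = 500 over 500 replicates;
agreement of the parametric p-value with an exact/Monte-Carlo
permutation test on small columns (decisions compared outside a narrow
band around the level, where finite permutation resolution makes the
comparison ill-posed); and a 10,000-case generator↔classifier label
round trip. These sizes were chosen to give tight binomial error on the
checked rates while keeping the default suite fast.

## Known limitations

* ACMG classes are knowledge-base *data*; the package computes no
  evidence-based classification.
* The full curated variant catalogue is represented by a count manifest
  plus a demonstration subset of records; the demonstration KB is not a
  clinical annotation resource, and some of its coordinates are
  placeholders within the correct gene span.
* Phase is assumed trans for two heterozygous HBB variants unless marked
  cis; no population phasing is attempted.
* The association scan has no covariate adjustment, kinship correction,
  or genomic control, and full-cohort reference statistics (which depend
  on unpublished sample-level data) are out of its scope by design.
* Hb electrophoresis peak calling, pediatric reference intervals, and
  prenatal-diagnosis decision rules are out of scope.
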