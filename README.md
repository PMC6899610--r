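# hemotyper

Desk-scale molecular screening, clinical genotyping, and genetic
counseling support for hemoglobinopathies.

Hemoglobinopathies — the thalassemias and structural hemoglobin variants —
are the most common monogenic disorders worldwide. Their diagnosis spans
three layers that clinicians normally have to combine by hand: a
hematologic screen (red-cell indices and the Hb pattern), molecular
genotyping of the disease-causing variants at the α- and β-globin loci,
and an assessment of *modifier* variants (KLF1, BCL11A, the HMIP
intergenic region, XmnI/HBG2, α-globin multi-copy alleles) that can shift
biallelic β-thalassemia between transfusion-dependent major (TM) and the
milder intermedia (TI). `hemotyper` packages all three layers, plus the
at-risk arithmetic for couples, for laboratory scientists and genetic
counselors who want a scriptable, auditable desk tool.

## What it computes

* **Knowledge base** — a curated variant table (HGVS names, rsIDs, GRCh37
  coordinates, ACMG 5-tier classes, β-allele classes β⁰/β⁺/β^E/β^S, α
  functional-gene counts, modifier effects) with a TSV format and a JSON
  mirror, schema validation, candidate-region checks, identifier lookup,
  and count summaries.
* **Carrier inference** — the routine screening decision tree: microcytic
  screen positive iff MCV < 82 fL or MCH < 27 pg; then HbA2 > 3.5 % →
  β-thalassemia trait, HbA2 < 2.5 % → suspected α-thalassemia trait,
  otherwise borderline; negative screen with HbF > 5 % → suspect HPFH/δβ.
  Every cut-off is configurable, and iron-deficiency and silent-carrier
  caveats are attached.
* **Clinical genotyping** — a combinatory rule engine over the genotype
  profile. α calls follow functional gene dosage (αα/αα = 4 … Hb H = 1,
  Hb Bart's hydrops = 0). β baselines follow the allele-class pair
  (β⁰/β⁰ → TM, β⁺/β⁺ → TI, …). Modifier rules then fire in a fixed,
  logged order: biallelic KLF1 zinc-finger genotypes → atypical
  thalassemia; KLF1 heterozygosity or the four-locus significant-modifier
  combination downgrade biallelic TM → TI; α triplication upgrades
  heterozygous β-thalassemia to TI but never downgrades biallelic disease.
* **At-risk assessment** — exact Mendelian enumeration of the offspring
  genotype distribution of a couple, classification of every outcome, and
  an at-risk report with probabilities, severities, and modifier
  reminders.
* **HbF association scan** — per-variant carrier vs non-carrier Welch test
  (dominant coding; additive linear model behind a flag) on an HbF trait
  vector, Bonferroni-corrected over the variants actually tested, with a
  publication-style result table.
* **Synthetic cohorts** — Hardy–Weinberg genotype simulation with
  diagnosis-conditional hemograms and genotype/trait matrices, so every
  module is testable end to end without patient data.

## Worked example

A 5-year-old girl with MCH 24 pg, MCV 73 fL, HbF 3 %, HbA2 6 %:

```r
library(hemotyper)
h <- hemogram(age = 5, sex = "female", MCV = 73, MCH = 24, HbA2 = 6, HbF = 3)
infer_trait(h)
#> Carrier inference: beta_thal_trait
#>   flags: genotyping_recommended
#>   beta-thalassemia trait inferred; molecular genotyping is highly recommended
```

The screen is positive (both MCV and MCH below the cut-offs) and HbA2 is
above 3.5 %, so she is inferred as a β-thalassemia trait carrier and
molecular genotyping is recommended.

Genotype shorthand goes straight into the rule engine (unicode and ASCII
forms are interchangeable):

```r
classify(parse_genotype("(β0/β0) + (KLF1 M/KLF1 N)"))
#> Hemoglobinopathy diagnosis
#>   genotype:      b0/b0 + (KLF1 M/KLF1 N)
#>   alpha locus:   normal
#>   beta locus:    beta_thal_intermedia
#>   overall:       beta-thalassemia intermedia
#>   severity:      TI
#>   rules applied: KLF1_downgrade_TM_to_TI
```

A β⁰ homozygote would be thalassemia major, but the heterozygous KLF1
zinc-finger allele downgrades the expected course to intermedia — and the
applied rule is logged. A couple report:

```r
assess_risk(parse_genotype("b0/bN, --SEA/aa"), parse_genotype("bE/bN"))
#> At-risk assessment: AT RISK for clinically significant hemoglobin disorders
#> At-risk offspring genotypes:
#>   b0/bE, --SEA/aa    P=0.1250  HbE/beta-thalassemia; alpha-thalassemia trait (TM)
#>   b0/bE              P=0.1250  HbE/beta-thalassemia (TM)
#> ...
#> Screening-relevant parental alleles: --SEA, b0, bE
```

A quarter of this couple's children would inherit the HbE/β⁰ compound
heterozygote, a transfusion-dependent disease, so the couple is flagged
at risk; carrier outcomes are listed as reminders.

There is also a command-line front end (installed at
`inst/cli/hemotyper`) with `kb`, `infer`, `genotype`, `risk`, `assoc`,
and `simulate` subcommands writing JSON and text reports.

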