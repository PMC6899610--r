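test_that("annotation matches knowledge-base records and carries unknowns forward", {
  kb <- demo_kb()
  ann <- annotate_variants(c("HBB:c.79G>A het"), kb)
  expect_equal(nrow(ann$annotated), 1L)
  expect_equal(ann$annotated$variant_id, "HbE")
  expect_equal(nrow(ann$unknowns), 0L)

  ann2 <- annotate_variants(c("rs999999999 het"), kb)
  expect_equal(nrow(ann2$annotated), 0L)
  expect_equal(ann2$unknowns$key, "rs999999999")

  ann3 <- annotate_variants(c("HBB:c.161C>T het"), kb)
  expect_equal(ann3$annotated$variant_id, "HbMidnapore")
})

test_that("baseline calls follow alpha dosage and beta allele classes", {
  dx <- function(g) classify(parse_genotype(g))
  expect_equal(dx("bN/bN")$overall_label, "no hemoglobinopathy genotype detected")
  expect_equal(dx("bN/bN, --SEA/-a3.7")$alpha_call, "HbH_disease")
  expect_equal(dx("bN/bN, --SEA/--SEA")$severity, "lethal")
  expect_equal(dx("bN/bN, --SEA/aa")$alpha_call, "alpha_thal_trait")
  expect_equal(dx("bN/bN, -a3.7/aa")$alpha_call, "silent_carrier")
  expect_equal(dx("b0/bN")$beta_call, "beta_thal_minor")
  expect_equal(dx("b0/b0")$severity, "TM")
  expect_equal(dx("b0/b+")$severity, "TM")
  expect_equal(dx("b+/b+")$severity, "TI")
  hbe <- dx("bE/b0")
  expect_equal(hbe$beta_call, "HbE_beta_thal")
  expect_equal(hbe$severity, "TM")
  expect_equal(dx("bS/bS")$beta_call, "sickle_cell_disease")
  expect_equal(dx("bS/b0")$beta_call, "sickle_cell_disease")
  expect_equal(dx("bE/bN")$beta_call, "Hb_variant_carrier")
})

test_that("modifier rules adjust severity in the declared order", {
  dx <- function(g) classify(parse_genotype(g))

  # heterozygous beta-thal + alpha triplication is upgraded to intermedia
  up <- dx("b0/bN, aaa/aa")
  expect_equal(up$beta_call, "beta_thal_intermedia")
  expect_equal(up$severity, "TI")
  expect_true("alpha_triplication_upgrade_to_TI" %in% up$modifier_notes)

  # biallelic KLF1 zinc-finger variants: atypical thalassemia
  at <- dx("(KLF1 M/KLF1 M)")
  expect_true(at$atypical_thalassemia)
  expect_equal(at$overall_label, "microcytic hypochromic anemia (atypical thalassemia)")

  # biallelic beta0 + alpha triplication is NOT downgraded
  tm <- dx("b0/b0, aaa/aa")
  expect_equal(tm$severity, "TM")
  expect_true("alpha_triplication_no_downgrade" %in% tm$modifier_notes)

  # biallelic beta0 + KLF1 heterozygote: downgraded to intermedia
  ti <- dx("(b0/b0) + (KLF1 M/KLF1 N)")
  expect_equal(ti$severity, "TI")
  expect_true("KLF1_downgrade_TM_to_TI" %in% ti$modifier_notes)

  # significant-modifier combination downgrade
  ti2 <- dx("(b0/b0) + 4 significant variants")
  expect_equal(ti2$severity, "TI")
  expect_true("significant_modifier_combination_downgrade" %in% ti2$modifier_notes)

  # the combination requires the configured number of HbF-raising loci
  p <- genotype_profile(beta = c("b0", "b0"),
                        modifiers = c(alpha_dc_coinherited = 1L,
                                      XmnI_rs7482144 = 1L))
  expect_equal(classify(p)$severity, "TM")
  expect_equal(classify(p, classify_rules(k_significant = 1))$severity, "TI")

  # unknown modifier combination: baseline kept, audit note recorded
  p2 <- genotype_profile(beta = c("b0", "bN"), modifiers = c(XmnI_rs7482144 = 1L))
  expect_equal(classify(p2)$severity, "carrier")
  expect_true("no_rule_applied" %in% classify(p2)$modifier_notes)
})

test_that("classification is deterministic and symmetric under allele order", {
  set.seed(21)
  for (i in 1:100) {
    p <- random_grammar_profile()
    swapped <- genotype_profile(alpha = rev(p$alpha), beta = rev(p$beta),
                                modifiers = p$modifiers)
    d1 <- classify(p); d2 <- classify(swapped); d3 <- classify(p)
    for (f in c("alpha_call", "beta_call", "overall_label", "severity",
                "atypical_thalassemia")) {
      expect_identical(d1[[f]], d2[[f]])
      expect_identical(d1[[f]], d3[[f]])
    }
    expect_identical(sort(d1$modifier_notes), sort(d2$modifier_notes))
  }
})

test_that("modifier notes are a faithful audit of the severity adjustments", {
  # replaying the logged rules on the baseline reproduces the final severity
  replay <- function(g) {
    d <- classify(parse_genotype(g))
    base <- classify(genotype_profile(alpha = d$profile$alpha,
                                      beta = d$profile$beta))
    sev <- base$severity
    if ("KLF1_biallelic_atypical_thalassemia" %in% d$modifier_notes) sev <- "TI"
    if ("KLF1_downgrade_TM_to_TI" %in% d$modifier_notes && sev == "TM") sev <- "TI"
    if ("significant_modifier_combination_downgrade" %in% d$modifier_notes &&
        sev == "TM") sev <- "TI"
    if ("alpha_triplication_upgrade_to_TI" %in% d$modifier_notes) sev <- "TI"
    list(replayed = sev, final = d$severity)
  }
  for (g in c("b0/b0", "(b0/b0) + (KLF1 M/KLF1 N)", "b0/bN, aaa/aa",
              "(b0/b0) + 4 significant variants", "(KLF1 M/KLF1 M)",
              "b0/b0, aaa/aa")) {
    r <- replay(g)
    expect_equal(r$replayed, r$final, info = g)
  }
})

test_that("the curated 26-case set reproduces the published severity split", {
  cases <- modification_case_set()
  expect_equal(nrow(cases), 26L)
  dx <- lapply(cases$genotype, function(g) classify(parse_genotype(g)))
  sev <- vapply(dx, `[[`, character(1L), "severity")
  atypical <- vapply(dx, `[[`, logical(1L), "atypical_thalassemia")
  beta_mod <- cases$group == "beta_thal_modification"
  expect_equal(sum(sev[beta_mod] == "TI"), 19L)
  expect_equal(sum(sev[beta_mod] == "TM"), 4L)
  expect_equal(sum(atypical), 3L)
  expect_true(all(sev[atypical] == "TI"))
})

test_that("classify_case composes annotation, assembly, and classification", {
  kb <- demo_kb()
  dx <- classify_case(c("HBB:c.52A>T het", "HBB:c.79G>A het", "rs999999999 het"),
                      kb)
  expect_equal(dx$beta_call, "HbE_beta_thal")
  expect_equal(dx$unknown_variants, "rs999999999")

  dx2 <- classify_case(character(), kb)
  expect_equal(dx2$severity, "none")
  expect_equal(dx2$overall_label, "no hemoglobinopathy genotype detected")

  # --SEA het + -a3.7 het from identifiers: Hb H disease
  dx3 <- classify_case(c("--SEA het", "-a3.7 het"), kb)
  expect_equal(dx3$alpha_call, "HbH_disease")
})
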