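test_that("functional alpha dosage sums haplotype gene counts", {
  count <- function(a1, a2)
    functional_alpha_count(genotype_profile(alpha = c(a1, a2)))
  expect_equal(count("aa", "aa"), 4L)
  expect_equal(count("--SEA", "-a3.7"), 1L)
  expect_equal(count("aaa", "aa"), 5L)
  expect_equal(count("--SEA", "--SEA"), 0L)
  expect_equal(count("aCSa", "aa"), 3L)
  # symmetric in haplotype order
  combos <- expand.grid(a = alpha_haplotype_table()$name,
                        b = alpha_haplotype_table()$name,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    expect_equal(count(combos$a[i], combos$b[i]), count(combos$b[i], combos$a[i]))
  }
})

test_that("shorthand parsing handles unicode, markup, and modifier terms", {
  p <- parse_genotype("β0/βN, ααα/αα")
  expect_setequal(p$beta, c("b0", "bN"))
  expect_setequal(p$alpha, c("aaa", "aa"))
  expect_equal(functional_alpha_count(p), 5L)

  p2 <- parse_genotype("βN/βN")
  expect_equal(functional_alpha_count(p2), 4L)
  expect_true(all(p2$beta == "bN"))

  p3 <- parse_genotype("(β0/β0) + (KLF1 M/KLF1 N)")
  expect_true(all(p3$beta == "b0"))
  expect_equal(p3$modifiers[["KLF1_zf"]], 1L)

  p4 <- parse_genotype("(b0/b0) + 4 significant variants")
  expect_equal(p4$modifiers[["alpha_dc_coinherited"]], 1L)
  expect_equal(p4$modifiers[["XmnI_rs7482144"]], 1L)
  expect_equal(p4$modifiers[["BCL11A_rs61749494"]], 1L)
  expect_equal(p4$modifiers[["HMIP_rs11759553"]], 1L)

  # markup superscripts (carets) are tolerated
  p5 <- parse_genotype("β^0^/β^+^")
  expect_setequal(p5$beta, c("b0", "b+"))

  expect_error(parse_genotype("b0/bZ"), "bZ")
  expect_error(parse_genotype(""), "non-empty")
})

test_that("render and parse are inverse on the canonical grammar", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_grammar_profile()
    q <- parse_genotype(render_genotype(p))
    expect_equal(sort(q$alpha), sort(p$alpha))
    expect_equal(sort(q$beta), sort(p$beta))
    expect_equal(q$modifiers, p$modifiers)
  }
})

test_that("profiles assemble from annotated variant lists", {
  kb <- demo_kb()
  hbe <- as.data.frame(kb_lookup(kb, "HBB:c.79G>A"))
  cd17 <- as.data.frame(kb_lookup(kb, "HBB:c.52A>T"))
  sea <- as.data.frame(kb_lookup(kb, "--SEA"))
  a37 <- as.data.frame(kb_lookup(kb, "-a3.7"))

  # two distinct heterozygous HBB records: compound het, trans assumed
  v <- rbind(hbe, cd17)
  v$zygosity <- "het"
  p <- profile_from_variants(v)
  expect_setequal(p$beta, c("bE", "b0"))

  # two het alpha CNVs land on separate haplotypes
  v2 <- rbind(sea, a37)
  v2$zygosity <- "het"
  p2 <- profile_from_variants(v2)
  expect_setequal(p2$alpha, c("--SEA", "-a3.7"))
  expect_equal(functional_alpha_count(p2), 1L)
  expect_equal(p2$modifiers[["alpha_dc_coinherited"]], 1L)

  # empty input: normal profile
  p3 <- profile_from_variants(NULL)
  expect_true(all(p3$beta == "bN") && all(p3$alpha == "aa"))

  # homozygote fills both slots
  v4 <- cd17; v4$zygosity <- "hom"
  expect_true(all(profile_from_variants(v4)$beta == "b0"))

  # modifiers map to their loci by rsID / zinc-finger flag
  xmn <- as.data.frame(kb_lookup(kb, "rs7482144")); xmn$zygosity <- "hom"
  klf <- as.data.frame(kb_lookup(kb, "KLF1:c.983G>A")); klf$zygosity <- "het"
  p5 <- profile_from_variants(rbind(xmn, klf))
  expect_equal(p5$modifiers[["XmnI_rs7482144"]], 2L)
  expect_equal(p5$modifiers[["KLF1_zf"]], 1L)
})

test_that("inconsistent allele combinations are rejected", {
  kb <- demo_kb()
  cd17 <- as.data.frame(kb_lookup(kb, "HBB:c.52A>T"))
  hbe <- as.data.frame(kb_lookup(kb, "HBB:c.79G>A"))
  v <- rbind(cd17, hbe)
  v$zygosity <- c("hom", "het")
  expect_error(profile_from_variants(v), "beta")

  sea <- as.data.frame(kb_lookup(kb, "--SEA"))
  a37 <- as.data.frame(kb_lookup(kb, "-a3.7"))
  v2 <- rbind(sea, a37)
  v2$zygosity <- c("hom", "het")
  expect_error(profile_from_variants(v2), "alpha")
})

test_that("random variant lists never yield more than 2 alleles per locus", {
  kb <- as.data.frame(demo_kb())
  set.seed(7)
  for (i in 1:100) {
    rows <- kb[sample(nrow(kb), sample(0:4, 1L)), , drop = FALSE]
    if (nrow(rows)) {
      rows$zygosity <- sample(c("het", "hom"), nrow(rows), replace = TRUE)
    } else {
      rows$zygosity <- character(0)
    }
    p <- tryCatch(profile_from_variants(rows), error = function(e) NULL)
    if (!is.null(p)) {
      expect_length(p$alpha, 2L)
      expect_length(p$beta, 2L)
      expect_true(all(p$modifiers <= 2L))
    }
  }
})
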