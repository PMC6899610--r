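test_that("KB TSV and JSON dialects round-trip to record-identical content", {
  kb <- demo_kb()
  for (ext in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_kb(kb, path)
    back <- load_kb(path)
    expect_equal(as.data.frame(back), as.data.frame(kb),
                 ignore_attr = TRUE)
  }
})

test_that("loading reports format problems instead of silently dropping rows", {
  # missing mandatory column
  path <- withr::local_tempfile(fileext = ".tsv")
  bad <- kb_record()
  bad$category <- NULL
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_kb(path), "category")

  # duplicate variant_id
  path2 <- withr::local_tempfile(fileext = ".tsv")
  dup <- rbind(kb_record(), kb_record())
  write.table(dup, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_kb(path2), "duplicate.*v1")

  # unparseable position is collected, not dropped silently
  path3 <- withr::local_tempfile(fileext = ".tsv")
  mix <- rbind(kb_record(), kb_record(variant_id = "v2", pos = "notanumber"))
  write.table(mix, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  kb3 <- load_kb(path3)
  expect_equal(nrow(kb3), 1L)
  expect_equal(nrow(attr(kb3, "errors")), 1L)

  # header-only file: empty KB, no error
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(kb_columns(), collapse = "\t"), path4)
  expect_equal(nrow(load_kb(path4)), 0L)
})

test_that("validator enforces the record invariants", {
  expect_equal(nrow(validate_kb(demo_kb())), 0L)

  one_issue <- function(rec, field_expected) {
    kb <- kb_new(rec)
    iss <- validate_kb(kb)
    expect_equal(nrow(iss), 1L)
    expect_equal(iss$field, field_expected)
    expect_equal(iss$variant_id, rec$variant_id)
  }
  # disease-causing restricted to globin genes
  one_issue(kb_record(gene = "BCL11A", chrom = "2", pos = 60689441L), "gene")
  # chromosome must match the gene
  one_issue(kb_record(chrom = "16", pos = 223704L), "chrom")
  # chrom/pos jointly set or jointly empty
  one_issue(kb_record(chrom = "", pos = 5248158L), "chrom/pos")
  # coordinates must fall inside a candidate region
  one_issue(kb_record(pos = 99999999L), "pos")
  # klf1_zinc_finger only on KLF1
  one_issue(kb_record(klf1_zinc_finger = TRUE), "klf1_zinc_finger")
  # modifier needs an effect or VUS status
  one_issue(kb_record(category = "modifier", modifier_effect = "none",
                      allele_class = "none"), "modifier_effect")
  # a single KLF1 zinc-finger modifier record is valid
  klf1 <- kb_record(variant_id = "k1", gene = "KLF1", chrom = "19",
                    pos = 12995430L, category = "modifier",
                    acmg_class = "likely_pathogenic",
                    phenotype_class = "uncertain", allele_class = "none",
                    modifier_effect = "severity_modifier",
                    klf1_zinc_finger = TRUE, hgvs = "KLF1:c.983G>A")
  expect_equal(nrow(validate_kb(kb_new(klf1))), 0L)
})

test_that("summaries count per gene and class, and totals are additive", {
  kb <- demo_kb()
  s <- summarize_kb(kb)
  tot <- kb_summary_totals(s)
  expect_equal(unname(tot["grand"]),
               unname(tot["disease_causing"] + tot["modifier"]))
  expect_equal(sum(s$disease["HBB", ]), unname(tot["HBB"]))

  # additivity: summaries of two disjoint halves sum to the full summary
  idx <- seq_len(nrow(kb)) %% 2L == 0L
  s1 <- summarize_kb(kb_new(as.data.frame(kb)[idx, ]))
  s2 <- summarize_kb(kb_new(as.data.frame(kb)[!idx, ]))
  expect_equal(s1$disease + s2$disease, s$disease)
  expect_equal(s1$modifier + s2$modifier, s$modifier)

  # empty KB: all-zero summary
  s0 <- summarize_kb(kb_new(kb_record()[0, ]))
  expect_true(all(s0$disease == 0L) && all(s0$modifier == 0L))
  expect_equal(unname(kb_summary_totals(s0)["grand"]), 0L)
})

test_that("count manifest reproduces the curated database totals", {
  s <- read_count_manifest(system.file("extdata", "kb_count_manifest.tsv",
                                       package = "hemotyper"))
  tot <- kb_summary_totals(s)
  expect_equal(unname(tot["HBB"]), 124)
  expect_equal(unname(tot["disease_causing"]), 265)
  expect_equal(unname(tot["modifier"]), 106)
  expect_equal(unname(tot["grand"]), 371)
})

test_that("lookup matches rsID, HGVS, coordinates, and CNV names", {
  kb <- demo_kb()
  hbe <- kb_lookup(kb, "HBB:c.79G>A")
  expect_equal(nrow(hbe), 1L)
  expect_equal(hbe$allele_class, "betaE")

  xmn <- kb_lookup(kb, "rs7482144")
  expect_equal(xmn$chrom, "11")
  expect_equal(xmn$pos, 5276169L)
  expect_equal(xmn$gene, "HBG2")

  expect_equal(nrow(kb_lookup(kb, "rs999999999")), 0L)

  by_coord <- kb_lookup(kb, c("11", "5248232", "A", "T"))
  expect_equal(by_coord$variant_id, "HbS")
  expect_error(kb_lookup(kb, c("11", "x", "A")), "coordinate")

  sea <- kb_lookup(kb, "--SEA")
  expect_equal(sea$allele_class, "0")
})

test_that("region membership respects half-open interval bounds", {
  kb <- demo_kb()
  expect_equal(region_membership(kb, "6", 135426573), "HMIP")
  expect_equal(region_membership(kb, "11", 5276169), "HBB_cluster")
  expect_true(is.na(region_membership(kb, "1", 1)))
  regions <- candidate_regions_default()
  for (i in seq_len(nrow(regions))) {
    expect_equal(region_membership(kb, regions$chrom[i], regions$start[i]),
                 regions$region[i])
    expect_true(is.na(region_membership(kb, regions$chrom[i], regions$end[i])) ||
                  region_membership(kb, regions$chrom[i], regions$end[i]) !=
                    regions$region[i])
  }
})

test_that("the packaged modifier fixture has 34 in-region records with HbF effects", {
  kb <- load_kb(system.file("extdata", "modifier_kb.tsv", package = "hemotyper"))
  expect_equal(nrow(kb), 34L)
  expect_true(all(kb$category == "modifier"))
  expect_true(all(kb$modifier_effect %in% c("elevates_HbF", "decreases_HbF")))
  expect_equal(nrow(validate_kb(kb)), 0L)
  inside <- vapply(seq_len(nrow(kb)), function(i)
    !is.na(region_membership(kb, kb$chrom[i], kb$pos[i])), logical(1L))
  expect_true(all(inside))
})
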