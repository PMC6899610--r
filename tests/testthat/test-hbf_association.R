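test_that("carrier partition uses dominant coding and skip rules", {
  p <- carrier_partition(c(0, 1, 2, 0))
  expect_equal(p$carriers, c(2L, 3L))
  expect_equal(p$noncarriers, c(1L, 4L))
  expect_true(p$tested)

  expect_false(carrier_partition(c(0, 0, 0, 0))$tested)
  # missing genotypes are excluded before the group-size rule
  p3 <- carrier_partition(c(0, 2, NA, 1))
  expect_false(p3$tested)
  expect_equal(length(p3$noncarriers), 1L)
})

test_that("a strong carrier effect is detected with the right direction", {
  # variant A separates the trait cleanly; variant B is noise
  set.seed(31)
  g <- cbind(A = rep(c(1, 0), each = 20), B = rbinom(40, 2, 0.3))
  trait <- c(rnorm(20, 30, 1), rnorm(20, 10, 1))
  res <- hbf_scan(g, trait)
  a <- res[res$variant == "A", ]
  expect_true(a$significant)
  expect_equal(a$direction, "elevates_HbF")
  expect_equal(a$mean_HbF_carriers, mean(trait[1:20]))
  # cross-check the Welch p-value against stats::t.test
  expect_equal(a$p_value,
               t.test(trait[g[, "A"] >= 1], trait[g[, "A"] == 0])$p.value)
})

test_that("parametric and permutation tests agree in accept/reject on toy columns", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(10:20, 1L)
    g <- rbinom(n, 2, 0.4)
    if (sum(g >= 1) < 2 || sum(g == 0) < 2) next
    shift <- sample(c(0, 8), 1L)
    trait <- rnorm(n, 12, 2) + shift * (g >= 1)
    res <- hbf_scan(matrix(g, ncol = 1), trait, correction = "none")
    p_perm <- permutation_p(trait[g >= 1], trait[g == 0])
    # decisions must agree except in a narrow indeterminate band around 0.05
    if (abs(p_perm - 0.05) > 0.02 && abs(res$p_value - 0.05) > 0.02) {
      expect_equal(res$p_value <= 0.05, p_perm <= 0.05,
                   info = sprintf("welch p=%.4f perm p=%.4f", res$p_value, p_perm))
    }
  }
})

test_that("Bonferroni correction is conservative and monotone", {
  sim <- simulate_assoc_matrix(100, 10, seed = 33)
  with_corr <- hbf_scan(sim$genotypes, sim$trait, correction = "bonferroni")
  without <- hbf_scan(sim$genotypes, sim$trait, correction = "none")
  expect_true(all(with_corr$variant[with_corr$significant] %in%
                    without$variant[without$significant]))
  # m = 1: the correction is the identity
  one <- hbf_scan(sim$genotypes[, 1, drop = FALSE], sim$trait)
  expect_equal(attr(one, "threshold"), attr(one, "alpha"))
})

test_that("results are invariant under joint sample permutation", {
  sim <- simulate_assoc_matrix(120, 8, effects = c(v2 = 10), seed = 34)
  res <- hbf_scan(sim$genotypes, sim$trait)
  perm <- sample(nrow(sim$genotypes))
  res_p <- hbf_scan(sim$genotypes[perm, ], sim$trait[perm])
  expect_equal(as.data.frame(res), as.data.frame(res_p))
})

test_that("the additive linear-model coding is available behind a flag", {
  sim <- simulate_assoc_matrix(200, 4, effects = c(v1 = 10), seed = 35)
  res <- hbf_scan(sim$genotypes, sim$trait, model = "additive")
  expect_equal(attr(res, "model"), "additive")
  expect_true(res$significant[res$variant == "v1"])
  # cross-check against a direct lm fit
  fit <- lm(sim$trait ~ sim$genotypes[, "v1"])
  expect_equal(res$p_value[res$variant == "v1"],
               summary(fit)$coefficients[2, 4])
})

test_that("result tables round-trip and mirror the packaged modifier table", {
  tab <- modifier_scan_table()
  expect_equal(nrow(tab), 34L)
  expect_equal(tab$Frequency[tab$SNPs == "rs7482144"], "0.1412")
  expect_equal(tab$Location[tab$SNPs == "rs7482144"], "11:5276169")

  # load -> write is byte-identical
  src <- system.file("extdata", "hbf_modifier_scan.tsv", package = "hemotyper")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(tab, out)
  expect_identical(readLines(out), readLines(src))

  # direction label in the table matches the carrier/non-carrier mean order
  elevated <- tab$Modification == "Elevated HbF"
  expect_equal(as.numeric(tab$HbF_carriers) > as.numeric(tab$HbF_noncarriers),
               elevated)

  # empty results produce a header-only file
  sim <- simulate_assoc_matrix(20, 2, seed = 36)
  empty <- hbf_scan(sim$genotypes, sim$trait)[0, ]
  class(empty) <- c("hbf_scan", "data.frame")
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(empty, out2)
  lines <- readLines(out2)
  expect_length(lines, 1L)
  expect_match(lines, "^SNPs\t")
})

test_that("dimension mismatches and bad alpha are input errors", {
  sim <- simulate_assoc_matrix(30, 3, seed = 37)
  expect_error(hbf_scan(sim$genotypes, sim$trait[-1]), "length")
  expect_error(hbf_scan(sim$genotypes, sim$trait, alpha = 1.5), "alpha")
})
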