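# Synthetic cohort generator: Hardy-Weinberg genotypes, diagnosis-dependent
# hemograms, and genotype/trait matrices for association testing.

# run code under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.default_hemogram_dists <- function() {
  d <- function(HGB, MCV, MCH, HbA2, HbF) {
    list(HGB = HGB, MCV = MCV, MCH = MCH, HbA2 = HbA2, HbF = HbF)
  }
  list(
    normal       = d(c(135, 12), c(90, 4),  c(30, 1.5),  c(2.8, 0.3),  c(0.5, 0.3)),
    alpha_silent = d(c(130, 12), c(84, 4),  c(27.5, 1.5), c(2.6, 0.3), c(0.5, 0.3)),
    alpha_trait  = d(c(120, 12), c(72, 5),  c(23, 2),    c(2.0, 0.35), c(0.6, 0.4)),
    beta_trait   = d(c(115, 12), c(67, 5),  c(21.5, 2),  c(5.2, 0.7),  c(2.0, 1.2)),
    TI           = d(c(80, 10),  c(70, 6),  c(22, 2),    c(4.5, 1.0),  c(40, 15)),
    TM           = d(c(55, 10),  c(68, 6),  c(21, 2),    c(3.5, 1.5),  c(70, 15)),
    atypical     = d(c(95, 10),  c(70, 5),  c(22, 2),    c(3.0, 0.5),  c(10, 5)),
    lethal       = d(c(40, 8),   c(110, 10), c(30, 3),   c(0.3, 0.2),  c(5, 3))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Allele frequencies approximate a southern Chinese screening population:
#' common deletional alpha alleles (--SEA predominant among double-gene
#' deletions), a few percent of beta-thalassemia alleles, and modifier
#' allele frequencies consistent with the curated carrier frequencies of
#' the packaged modifier table (carrier frequency f maps to allele
#' frequency 1 - sqrt(1 - f) under Hardy-Weinberg). Hemogram distributions
#' are normal with clamping to physical ranges; they are synthetic
#' calibration clusters, not epidemiological references.
#'
#' @param n number of individuals.
#' @param alpha_freq named allele frequencies over alpha haplotypes
#'   (must sum to 1).
#' @param beta_freq named allele frequencies over beta allele codes.
#' @param modifier_freq named allele frequencies for modifier loci.
#' @param hemogram per-group mean/sd for HGB, MCV, MCH, HbA2, HbF.
#' @param seed integer seed; a fixed seed gives identical output.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 1000L,
                          alpha_freq = c(aa = 0.90, `--SEA` = 0.05,
                                         `-a3.7` = 0.03, `-a4.2` = 0.01,
                                         aaa = 0.01),
                          beta_freq = c(bN = 0.965, b0 = 0.02, `b+` = 0.005,
                                        bE = 0.01),
                          modifier_freq = c(KLF1_zf = 0.01,
                                            XmnI_rs7482144 = 0.073,
                                            BCL11A_rs61749494 = 0.134,
                                            HMIP_rs11759553 = 0.191),
                          hemogram = .default_hemogram_dists(),
                          seed = 1L) {
  chk <- function(f, what) {
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
      stop(what, " frequencies must be non-negative and sum to 1")
  }
  chk(alpha_freq, "alpha")
  chk(beta_freq, "beta")
  if (any(modifier_freq < 0 | modifier_freq > 1))
    stop("modifier allele frequencies must lie in [0, 1]")
  for (g in names(hemogram)) for (v in names(hemogram[[g]])) {
    if (hemogram[[g]][[v]][2L] <= 0) stop("hemogram sds must be positive")
  }
  structure(list(n = as.integer(n), alpha_freq = alpha_freq,
                 beta_freq = beta_freq, modifier_freq = modifier_freq,
                 hemogram = hemogram, seed = seed),
            class = "cohort_config")
}

.diagnosis_group <- function(dx) {
  if (dx$atypical_thalassemia) return("atypical")
  switch(dx$severity,
         lethal = "lethal", TM = "TM", TI = "TI",
         carrier = if (dx$beta_call %in% c("beta_thal_minor"))
                     "beta_trait"
                   else if (dx$alpha_call == "alpha_thal_trait") "alpha_trait"
                   else if (dx$alpha_call == "silent_carrier") "alpha_silent"
                   else "normal",
         "normal")
}

.sample_hemogram <- function(group, dists, age, sex) {
  d <- dists[[group]]
  draw <- function(v) stats::rnorm(1L, d[[v]][1L], d[[v]][2L])
  hemogram(age = age, sex = sex,
           HGB = max(20, draw("HGB")),
           MCV = max(40, draw("MCV")),
           MCH = max(10, draw("MCH")),
           HbA2 = min(100, max(0, draw("HbA2"))),
           HbF = min(100, max(0, draw("HbF"))))
}

#' Simulate a phenotyped, genotyped cohort
#'
#' Genotypes are drawn per locus under Hardy-Weinberg from the configured
#' allele frequencies; each individual's true diagnosis is computed with
#' the combinatory rule engine; the hemogram is then sampled from that
#' diagnosis group's distribution. Truth labels are emitted so that
#' classifier and inference round-trips can be tested.
#'
#' @param cfg a [cohort_config()].
#' @param rules a [classify_rules()] configuration shared with the engine.
#' @return List of class `synthetic_cohort` with `genotypes`
#'   (individual_id, genotype shorthand), `phenotypes` (hemogram table),
#'   and `truth` (per-individual label, severity, and hemogram group).
#' @export
simulate_cohort <- function(cfg = cohort_config(), rules = classify_rules()) {
  stopifnot(inherits(cfg, "cohort_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n
    empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
    genotypes <- empty(individual_id = character(), genotype = character())
    phenotypes <- empty(individual_id = character(), age = numeric(),
                        sex = character(), HGB = numeric(), MCV = numeric(),
                        MCH = numeric(), HbA2 = numeric(), HbF = numeric())
    truth <- empty(individual_id = character(), overall_label = character(),
                   severity = character(), group = character())
    if (n > 0L) {
      rows_g <- vector("list", n); rows_p <- vector("list", n)
      rows_t <- vector("list", n)
      for (i in seq_len(n)) {
        id <- sprintf("S%05d", i)
        alpha <- sample(names(cfg$alpha_freq), 2L, replace = TRUE,
                        prob = cfg$alpha_freq)
        beta <- sample(names(cfg$beta_freq), 2L, replace = TRUE,
                       prob = cfg$beta_freq)
        mods <- vapply(cfg$modifier_freq, function(f)
          stats::rbinom(1L, 2L, f), integer(1L))
        profile <- genotype_profile(alpha = alpha, beta = beta, modifiers = mods)
        dx <- classify(profile, rules)
        group <- .diagnosis_group(dx)
        age <- round(stats::runif(1L, 1, 60))
        sex <- sample(c("male", "female"), 1L)
        h <- .sample_hemogram(group, cfg$hemogram, age, sex)
        rows_g[[i]] <- empty(individual_id = id, genotype = render_genotype(profile))
        rows_p[[i]] <- empty(individual_id = id, age = age, sex = sex,
                             HGB = h$HGB, MCV = h$MCV, MCH = h$MCH,
                             HbA2 = h$HbA2, HbF = h$HbF)
        rows_t[[i]] <- empty(individual_id = id, overall_label = dx$overall_label,
                             severity = dx$severity, group = group)
      }
      genotypes <- do.call(rbind, rows_g)
      phenotypes <- do.call(rbind, rows_p)
      truth <- do.call(rbind, rows_t)
    }
    structure(list(genotypes = genotypes, phenotypes = phenotypes,
                   truth = truth, config = cfg),
              class = "synthetic_cohort")
  })
}

#' Simulate couples from a cohort configuration
#'
#' Pairs simulated individuals uniformly at random; optionally oversamples
#' carrier-by-carrier pairs by redrawing each partner until a
#' non-normal-severity genotype is found (enrichment for risk-module
#' testing).
#'
#' @param n_couples number of couples.
#' @param cfg a [cohort_config()] (its `n` is ignored).
#' @param enrich_carriers if `TRUE`, both partners are redrawn until they
#'   carry at least one non-normal allele.
#' @param seed integer seed.
#' @return List of pairs of [genotype_profile()]s.
#' @export
simulate_couples <- function(n_couples = 100L, cfg = cohort_config(),
                             enrich_carriers = FALSE, seed = 1L) {
  .with_seed(seed, {
    draw <- function() {
      repeat {
        alpha <- sample(names(cfg$alpha_freq), 2L, replace = TRUE,
                        prob = cfg$alpha_freq)
        beta <- sample(names(cfg$beta_freq), 2L, replace = TRUE,
                       prob = cfg$beta_freq)
        mods <- vapply(cfg$modifier_freq, function(f)
          stats::rbinom(1L, 2L, f), integer(1L))
        p <- genotype_profile(alpha = alpha, beta = beta, modifiers = mods)
        if (!enrich_carriers || any(p$beta != "bN") || any(p$alpha != "aa"))
          return(p)
      }
    }
    lapply(seq_len(n_couples), function(i) list(p1 = draw(), p2 = draw()))
  })
}

#' Simulate a genotype matrix and HbF trait for association testing
#'
#' Genotype columns are i.i.d. binomial(2, f_j); the trait is
#' `baseline + sum(effect_j * carrier_j) + Normal(0, sd)` where
#' `carrier_j` indicates dose >= 1 at a causal variant.
#'
#' @param n samples; `m` variants.
#' @param m number of variant columns.
#' @param effects named numeric vector of carrier effects in g/L, names
#'   matching variant columns (`"v1"`, ... by default); empty for a null
#'   matrix.
#' @param baseline baseline HbF, g/L.
#' @param sd residual standard deviation, g/L.
#' @param freq allele frequency (scalar recycled, or length-m vector).
#' @param seed integer seed.
#' @return List with `genotypes` (n x m matrix), `trait` (length n), and
#'   `causal` (the effects vector).
#' @export
simulate_assoc_matrix <- function(n, m, effects = numeric(), baseline = 12,
                                  sd = 8, freq = 0.2, seed = 1L) {
  freq <- rep_len(freq, m)
  ids <- sprintf("v%d", seq_len(m))
  if (length(effects) > 0L) {
    if (is.null(names(effects))) stop("effects must be named by variant column")
    bad <- setdiff(names(effects), ids)
    if (length(bad) > 0L)
      stop("effects name unknown variant column(s): ", paste(bad, collapse = ", "))
  }
  .with_seed(seed, {
    genotypes <- vapply(seq_len(m), function(j)
      stats::rbinom(n, 2L, freq[j]), integer(n))
    genotypes <- matrix(genotypes, nrow = n, ncol = m,
                        dimnames = list(NULL, ids))
    trait <- baseline + stats::rnorm(n, 0, sd)
    for (v in names(effects)) {
      trait <- trait + effects[[v]] * (genotypes[, v] >= 1L)
    }
    list(genotypes = genotypes, trait = trait, causal = effects)
  })
}

#' Write a synthetic cohort to disk
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed); writes
#'   `genotypes.tsv`, `phenotypes.csv`, `truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
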