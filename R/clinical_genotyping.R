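# Clinical genotyping: annotation against the knowledge base and the
# combinatory severity rule engine producing an overall diagnosis.

ALPHA_CALLS <- c("normal", "silent_carrier", "alpha_thal_trait",
                 "HbH_disease", "Hb_Barts_hydrops")
BETA_CALLS <- c("normal", "beta_thal_minor", "beta_thal_intermedia",
                "beta_thal_major", "HbE_beta_thal", "sickle_cell_disease",
                "Hb_variant_carrier", "HPFH_carrier")
SEVERITIES <- c("none", "carrier", "TI", "TM", "lethal")

#' Rule configuration for the combinatory severity engine
#'
#' @param k_significant minimum number of HbF-raising SNP loci (of XmnI,
#'   BCL11A, HMIP) that, together with co-inherited alpha disease-causing
#'   variation, downgrades biallelic beta-thalassemia from major to
#'   intermedia.
#' @param beta0_plus_baseline baseline severity of the beta0/beta+ compound
#'   heterozygote. `"TM"` by default: the clinical course is variable, but
#'   alpha triplication never downgrades a biallelic genotype, so an
#'   observed beta0/beta+ plus triplication patient with thalassemia major
#'   fixes the baseline at TM.
#' @param hbe_beta0_baseline baseline severity of the HbE/beta0 compound
#'   heterozygote.
#' @return A list of class `hb_rules`.
#' @export
classify_rules <- function(k_significant = 2,
                           beta0_plus_baseline = c("TM", "TI"),
                           hbe_beta0_baseline = c("TM", "TI")) {
  stopifnot(k_significant >= 0, k_significant <= 3)
  structure(list(k_significant = as.integer(k_significant),
                 beta0_plus_baseline = match.arg(beta0_plus_baseline),
                 hbe_beta0_baseline = match.arg(hbe_beta0_baseline)),
            class = "hb_rules")
}

#' Annotate input variants against the knowledge base
#'
#' Each input is matched via [kb_lookup()] by any identifier form (rsID,
#' HGVS, coordinate key, or named CNV allele). Unmatched inputs are not
#' errors: they are carried forward as variants of uncertain significance.
#'
#' @param inputs either a character vector of `"key zygosity"` strings
#'   (e.g. `"HBB:c.79G>A het"`) or a data.frame with columns `key`,
#'   `zygosity`, and optionally `phase`.
#' @param kb an `hb_kb` knowledge base.
#' @return List with `annotated` (matched records plus `zygosity`/`phase`
#'   columns) and `unknowns` (data.frame of unmatched keys).
#' @export
annotate_variants <- function(inputs, kb) {
  if (is.character(inputs)) {
    parts <- strsplit(trimws(inputs), "\\s+")
    inputs <- data.frame(
      key = vapply(parts, `[`, character(1L), 1L),
      zygosity = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "het",
                        character(1L)),
      stringsAsFactors = FALSE)
  }
  if (nrow(inputs) == 0L) {
    return(list(annotated = cbind(kb[0, ], zygosity = character(), phase = character()),
                unknowns = data.frame(key = character(), zygosity = character())))
  }
  if (!"phase" %in% names(inputs)) inputs$phase <- ""
  if (!all(inputs$zygosity %in% c("het", "hom")))
    stop("zygosity must be 'het' or 'hom'")
  annotated <- list()
  unknowns <- list()
  for (i in seq_len(nrow(inputs))) {
    hit <- tryCatch(kb_lookup(kb, inputs$key[i]), error = function(e) kb[0, ])
    if (nrow(hit) == 0L) {
      unknowns[[length(unknowns) + 1L]] <- inputs[i, c("key", "zygosity")]
    } else {
      hit <- hit[1L, , drop = FALSE]  # first match wins for duplicated ids
      hit$zygosity <- inputs$zygosity[i]
      hit$phase <- inputs$phase[i]
      annotated[[length(annotated) + 1L]] <- hit
    }
  }
  list(
    annotated = if (length(annotated)) do.call(rbind, annotated)
                else cbind(kb[0, ], zygosity = character(), phase = character()),
    unknowns = if (length(unknowns)) do.call(rbind, unknowns)
               else data.frame(key = character(), zygosity = character())
  )
}

.beta_baseline <- function(beta, rules) {
  b <- sort(beta)
  thal <- c("b0", "b+")
  n_thal <- sum(beta %in% thal)
  has <- function(...) identical(unname(b), sort(as.character(c(...))))
  if (all(beta == "bN")) return(list(call = "normal", severity = "none", note = NULL))
  if (has("bS", "bS") || has("b0", "bS") || has("b+", "bS"))
    return(list(call = "sickle_cell_disease", severity = "TI",
                note = "sickle_cell_disease_clinically_significant"))
  if (has("b0", "bE"))
    return(list(call = "HbE_beta_thal", severity = rules$hbe_beta0_baseline,
                note = NULL))
  if (has("b+", "bE"))
    return(list(call = "HbE_beta_thal", severity = "TI",
                note = "HbE_beta_plus_baseline_TI"))
  if (has("b0", "b0")) return(list(call = "beta_thal_major", severity = "TM", note = NULL))
  if (has("b0", "b+")) {
    sev <- rules$beta0_plus_baseline
    call <- if (sev == "TM") "beta_thal_major" else "beta_thal_intermedia"
    return(list(call = call, severity = sev, note = NULL))
  }
  if (has("b+", "b+")) return(list(call = "beta_thal_intermedia", severity = "TI", note = NULL))
  if (any(beta == "bD"))
    return(list(call = "beta_thal_intermedia", severity = "TI",
                note = "dominant_beta_thal_allele"))
  if (n_thal == 1L) return(list(call = "beta_thal_minor", severity = "carrier", note = NULL))
  if (has("bE", "bE"))
    return(list(call = "Hb_variant_carrier", severity = "carrier",
                note = "HbE_homozygote_mild"))
  if (any(beta == "hpfh"))
    return(list(call = "HPFH_carrier", severity = "carrier", note = NULL))
  # single Hb variant allele (bE or bS heterozygote)
  list(call = "Hb_variant_carrier", severity = "carrier", note = NULL)
}

.alpha_baseline <- function(profile) {
  n <- functional_alpha_count(profile)
  call <- if (n >= 4L) "normal"
          else switch(as.character(n), "3" = "silent_carrier",
                      "2" = "alpha_thal_trait", "1" = "HbH_disease",
                      "0" = "Hb_Barts_hydrops")
  notes <- character()
  if (call == "HbH_disease" && any(.alpha_nondeletional(profile$alpha)))
    notes <- "nondeletional_HbH_more_severe"
  list(call = call, n = n, notes = notes)
}

#' Classify a genotype profile into a diagnosis
#'
#' Applies the combinatory rule engine. The alpha call follows functional
#' gene dosage (4 normal, 3 silent carrier, 2 trait, 1 Hb H disease,
#' 0 Hb Bart's hydrops fetalis). The beta baseline follows the allele-class
#' pair (biallelic beta0 genotypes are thalassemia major, beta+/beta+
#' intermedia, one thalassemia allele a minor/carrier state, HbE/beta0 and
#' sickle genotypes their named diseases). Modifier adjustments are then
#' applied in a fixed, audited order:
#' \enumerate{
#'   \item biallelic KLF1 zinc-finger variants on a beta-normal background
#'     are reported as atypical thalassemia (microcytic hypochromic anemia);
#'   \item biallelic beta-thalassemia with at least one KLF1 zinc-finger
#'     allele is downgraded TM to TI;
#'   \item biallelic beta-thalassemia with the significant-modifier
#'     combination (co-inherited alpha disease-causing variation plus
#'     HbF-raising alleles at `k_significant` or more of XmnI, BCL11A,
#'     HMIP) is downgraded TM to TI;
#'   \item heterozygous beta-thalassemia with alpha triplication or
#'     quadruplication (functional dosage >= 5) is upgraded to intermedia;
#'   \item biallelic beta-thalassemia with alpha triplication is never
#'     downgraded.
#' }
#' Each applied rule is logged in `modifier_notes`.
#'
#' @param profile a [genotype_profile()].
#' @param rules a [classify_rules()] configuration.
#' @param unknown_variants character vector of unmatched input keys to carry
#'   into the diagnosis as variants of uncertain significance.
#' @return Object of class `hb_diagnosis`.
#' @export
classify <- function(profile, rules = classify_rules(),
                     unknown_variants = character()) {
  stopifnot(inherits(profile, "genotype_profile"), inherits(rules, "hb_rules"))
  alpha <- .alpha_baseline(profile)
  beta <- .beta_baseline(profile$beta, rules)
  notes <- c(alpha$notes, beta$note)
  severity <- beta$severity
  beta_call <- beta$call
  atypical <- FALSE

  mods <- profile$modifiers
  dose <- function(locus) if (locus %in% names(mods)) mods[[locus]] else 0L
  klf1 <- dose("KLF1_zf")
  beta_thal_alleles <- sum(profile$beta %in% c("b0", "b+", "bD"))
  biallelic_bthal <- beta_call %in%
    c("beta_thal_major", "beta_thal_intermedia", "HbE_beta_thal") &&
    beta_thal_alleles + sum(profile$beta == "bE") >= 2L
  het_bthal <- beta_thal_alleles == 1L && sum(profile$beta == "bN") == 1L
  any_modifier <- length(mods) > 0L && any(mods > 0L)

  # (1) biallelic KLF1 zinc-finger variants on a beta-normal background
  if (klf1 == 2L && all(profile$beta == "bN")) {
    atypical <- TRUE
    severity <- "TI"
    notes <- c(notes, "KLF1_biallelic_atypical_thalassemia")
  }
  # (2) biallelic beta-thalassemia + KLF1 zinc-finger allele: TM -> TI
  if (!atypical && biallelic_bthal && klf1 >= 1L && severity == "TM") {
    severity <- "TI"
    beta_call <- "beta_thal_intermedia"
    notes <- c(notes, "KLF1_downgrade_TM_to_TI")
  }
  # (3) biallelic beta-thalassemia + significant-modifier combination
  alpha_dc <- dose("alpha_dc_coinherited") > 0L || alpha$n < 4L
  n_hbf_loci <- sum(c(dose("XmnI_rs7482144"), dose("BCL11A_rs61749494"),
                      dose("HMIP_rs11759553")) >= 1L)
  if (biallelic_bthal && alpha_dc && n_hbf_loci >= rules$k_significant &&
      severity == "TM") {
    severity <- "TI"
    beta_call <- "beta_thal_intermedia"
    notes <- c(notes, "significant_modifier_combination_downgrade")
  }
  # (4) heterozygous beta-thalassemia + alpha triplication/quadruplication
  if (het_bthal && alpha$n >= 5L) {
    severity <- "TI"
    beta_call <- "beta_thal_intermedia"
    notes <- c(notes, "alpha_triplication_upgrade_to_TI")
  }
  # (5) biallelic beta-thalassemia + alpha triplication: no downgrade
  if (biallelic_bthal && alpha$n >= 5L) {
    notes <- c(notes, "alpha_triplication_no_downgrade")
  }
  if (any_modifier && length(notes) == 0L) notes <- "no_rule_applied"

  # alpha disease states dominate the overall severity where more severe
  if (alpha$call == "Hb_Barts_hydrops") {
    severity <- "lethal"
    notes <- c(notes, "Hb_Barts_hydrops_prenatal_significance")
  } else if (alpha$call == "HbH_disease" && severity %in% c("none", "carrier")) {
    severity <- "TI"
  } else if (alpha$call %in% c("alpha_thal_trait", "silent_carrier") &&
             severity == "none") {
    severity <- "carrier"
  }

  label <- .overall_label(alpha$call, beta_call, severity, atypical)
  structure(list(alpha_call = alpha$call, beta_call = beta_call,
                 overall_label = label, severity = severity,
                 atypical_thalassemia = atypical,
                 modifier_notes = unique(notes),
                 unknown_variants = unknown_variants,
                 profile = profile),
            class = "hb_diagnosis")
}

.overall_label <- function(alpha_call, beta_call, severity, atypical) {
  if (atypical) return("microcytic hypochromic anemia (atypical thalassemia)")
  alpha_lab <- switch(alpha_call,
    normal = NULL, silent_carrier = "alpha-thalassemia silent carrier",
    alpha_thal_trait = "alpha-thalassemia trait", HbH_disease = "Hb H disease",
    Hb_Barts_hydrops = "Hb Bart's hydrops fetalis")
  beta_lab <- switch(beta_call,
    normal = NULL, beta_thal_minor = "beta-thalassemia minor",
    beta_thal_intermedia = "beta-thalassemia intermedia",
    beta_thal_major = "beta-thalassemia major",
    HbE_beta_thal = "HbE/beta-thalassemia",
    sickle_cell_disease = "sickle cell disease",
    Hb_variant_carrier = "Hb variant carrier",
    HPFH_carrier = "HPFH carrier")
  labs <- c(beta_lab, alpha_lab)
  if (length(labs) == 0L) "no hemoglobinopathy genotype detected"
  else paste(labs, collapse = "; ")
}

#' Annotate, assemble, and classify a variant list in one step
#'
#' Composition of [annotate_variants()], [profile_from_variants()], and
#' [classify()]; unmatched inputs propagate into
#' `unknown_variants` of the diagnosis.
#'
#' @inheritParams annotate_variants
#' @param rules a [classify_rules()] configuration.
#' @return An `hb_diagnosis`.
#' @export
classify_case <- function(inputs, kb, rules = classify_rules()) {
  ann <- annotate_variants(inputs, kb)
  profile <- profile_from_variants(ann$annotated)
  classify(profile, rules, unknown_variants = ann$unknowns$key)
}

#' @export
print.hb_diagnosis <- function(x, ...) {
  cat("Hemoglobinopathy diagnosis\n")
  cat("  genotype:     ", render_genotype(x$profile), "\n")
  cat("  alpha locus:  ", x$alpha_call, "\n")
  cat("  beta locus:   ", x$beta_call, "\n")
  cat("  overall:      ", x$overall_label, "\n")
  cat("  severity:     ", x$severity, "\n")
  if (length(x$modifier_notes))
    cat("  rules applied:", paste(x$modifier_notes, collapse = ", "), "\n")
  if (length(x$unknown_variants))
    cat("  uncertain significance (not in KB):",
        paste(x$unknown_variants, collapse = ", "), "\n")
  invisible(x)
}

#' Curated complicated-case genotype set
#'
#' The packaged 26-case set of compound heterozygotes combined with
#' modifier variants used to exercise the severity rule engine: 23
#' beta-thalassemia-modification cases (biallelic beta0 genotypes with
#' alpha triplication, KLF1 zinc-finger heterozygosity, or the four-locus
#' significant-modifier combination, and heterozygous beta-thalassemia with
#' alpha triplication) plus 3 atypical-thalassemia cases (biallelic KLF1
#' zinc-finger genotypes).
#'
#' @return data.frame with columns `case_id`, `group`
#'   (`"beta_thal_modification"` / `"atypical_thalassemia"`), and
#'   `genotype` (shorthand accepted by [parse_genotype()]).
#' @export
modification_case_set <- function() {
  rows <- list(
    list("b0/b0, aaa/aa", 3L, "beta_thal_modification"),
    list("b0/b+, aaa/aa", 1L, "beta_thal_modification"),
    # heterozygous beta-thalassemia with triplication/quadruplication:
    # cycle through the stated concrete genotype combinations
    list(c("b0/bN, aaa/aa", "b+/bN, aaa/aa", "b0/bN, aaa/aaa"), 9L,
         "beta_thal_modification"),
    list("(b0/b0) + (KLF1 M/KLF1 N)", 5L, "beta_thal_modification"),
    list("(b0/b0) + 4 significant variants", 5L, "beta_thal_modification"),
    list("(KLF1 M/KLF1 M)", 3L, "atypical_thalassemia")
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    g <- rep_len(r[[1L]], r[[2L]])
    data.frame(group = r[[3L]], genotype = g, stringsAsFactors = FALSE)
  }))
  out$case_id <- sprintf("case%02d", seq_len(nrow(out)))
  out[, c("case_id", "group", "genotype")]
}
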