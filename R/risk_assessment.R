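# At-risk assessment: Mendelian enumeration of offspring genotypes for a
# couple, classification of every outcome, and an at-risk report.

#' Enumerate the gamete distributions of a genotype profile
#'
#' Each locus contributes its two alleles at probability 1/2 each; alpha
#' haplotypes segregate as whole named units; modifier loci segregate
#' independently, a parent of dose d transmitting the allele with
#' probability d/2.
#'
#' @param profile a [genotype_profile()].
#' @return List with `alpha` and `beta` (named probability vectors over
#'   alleles) and `modifiers` (named vector of transmission probabilities).
#' @export
enumerate_gametes <- function(profile) {
  stopifnot(inherits(profile, "genotype_profile"))
  tab <- function(alleles) {
    p <- table(alleles) / 2
    stats::setNames(as.numeric(p), names(p))
  }
  mods <- profile$modifiers
  list(alpha = tab(profile$alpha), beta = tab(profile$beta),
       modifiers = if (length(mods)) mods / 2 else stats::setNames(numeric(), character()))
}

.pair_distribution <- function(g1, g2) {
  # cross two gamete distributions at one locus; unordered pairs merged
  out <- new.env(parent = emptyenv())
  for (a in names(g1)) for (b in names(g2)) {
    key <- paste(sort(c(a, b)), collapse = "|")
    prev <- if (!is.null(out[[key]])) out[[key]] else 0
    out[[key]] <- prev + g1[[a]] * g2[[b]]
  }
  keys <- sort(ls(out))
  data.frame(pair = keys,
             prob = vapply(keys, function(k) out[[k]], numeric(1L)),
             stringsAsFactors = FALSE)
}

.dose_distribution <- function(p1, p2) {
  # child dose = Bernoulli(p1) + Bernoulli(p2)
  probs <- c(`0` = (1 - p1) * (1 - p2), `1` = p1 * (1 - p2) + (1 - p1) * p2,
             `2` = p1 * p2)
  probs[probs > 0]
}

#' Offspring genotype distribution of a couple
#'
#' Cross product of the two parents' gamete distributions, loci combined
#' independently; genotypes identical up to allele order are merged with
#' summed probabilities. The `alpha_dc_coinherited` flag is capped at dose
#' 1 in offspring.
#'
#' @param p1,p2 parental [genotype_profile()]s.
#' @return Object of class `offspring_distribution`: a list with `profiles`
#'   (list of genotype profiles) and `prob` (numeric vector summing to 1).
#' @export
offspring_distribution <- function(p1, p2) {
  g1 <- enumerate_gametes(p1)
  g2 <- enumerate_gametes(p2)
  alpha <- .pair_distribution(g1$alpha, g2$alpha)
  beta <- .pair_distribution(g1$beta, g2$beta)
  loci <- union(names(g1$modifiers), names(g2$modifiers))
  mod_dists <- lapply(loci, function(l) {
    tp1 <- if (l %in% names(g1$modifiers)) g1$modifiers[[l]] else 0
    tp2 <- if (l %in% names(g2$modifiers)) g2$modifiers[[l]] else 0
    d <- .dose_distribution(tp1, tp2)
    if (l == "alpha_dc_coinherited" && "2" %in% names(d)) {
      d["1"] <- sum(d[c("1", "2")], na.rm = TRUE)
      d <- d[names(d) != "2"]
    }
    d
  })
  names(mod_dists) <- loci

  grids <- c(list(alpha = seq_len(nrow(alpha)), beta = seq_len(nrow(beta))),
             lapply(mod_dists, seq_along))
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  profiles <- vector("list", nrow(grid))
  prob <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ai <- grid$alpha[i]; bi <- grid$beta[i]
    p <- alpha$prob[ai] * beta$prob[bi]
    doses <- integer(length(loci))
    names(doses) <- loci
    for (l in loci) {
      d <- mod_dists[[l]][[grid[[l]][i]]]
      doses[l] <- as.integer(names(mod_dists[[l]])[grid[[l]][i]])
      p <- p * d
    }
    profiles[[i]] <- genotype_profile(
      alpha = strsplit(alpha$pair[ai], "|", fixed = TRUE)[[1L]],
      beta = strsplit(beta$pair[bi], "|", fixed = TRUE)[[1L]],
      modifiers = doses)
    prob[i] <- p
  }
  # merge genotypes identical after canonicalization
  key <- vapply(profiles, .profile_key, character(1L))
  ord <- order(key)
  key <- key[ord]; profiles <- profiles[ord]; prob <- prob[ord]
  keep <- !duplicated(key)
  merged_prob <- as.numeric(tapply(prob, factor(key, levels = key[keep]), sum))
  structure(list(profiles = profiles[keep], prob = merged_prob,
                 key = key[keep]),
            class = "offspring_distribution")
}

.profile_key <- function(p) {
  mods <- p$modifiers[p$modifiers > 0L]
  paste(paste(sort(p$alpha), collapse = "/"),
        paste(sort(p$beta), collapse = "/"),
        paste(sprintf("%s=%d", names(mods), mods), collapse = ","),
        sep = " ; ")
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat("Offspring genotype distribution (", length(x$prob), " outcomes)\n", sep = "")
  for (i in seq_along(x$prob)) {
    cat(sprintf("  %-40s %.4f\n", render_genotype(x$profiles[[i]]), x$prob[i]))
  }
  invisible(x)
}

#' At-risk assessment for a couple
#'
#' Enumerates the offspring genotype distribution, classifies every
#' outcome with the combinatory rule engine, and reports whether the
#' couple is at risk: any offspring genotype with severity TI, TM, or
#' lethal, or with Hb H disease or Hb Bart's hydrops at the alpha locus.
#' Carrier-only outcomes and benign Hb variant alleles never trigger risk;
#' carrier probabilities and parental modifier variants are reported as
#' reminders for counseling.
#'
#' @param p1,p2 parental [genotype_profile()]s.
#' @param rules a [classify_rules()] configuration.
#' @return Object of class `hb_risk_report`.
#' @export
assess_risk <- function(p1, p2, rules = classify_rules()) {
  parent_dx <- list(classify(p1, rules), classify(p2, rules))
  dist <- offspring_distribution(p1, p2)
  dx <- lapply(dist$profiles, classify, rules = rules)
  sev <- vapply(dx, `[[`, character(1L), "severity")
  alpha_call <- vapply(dx, `[[`, character(1L), "alpha_call")
  risky <- sev %in% c("TI", "TM", "lethal") |
    alpha_call %in% c("HbH_disease", "Hb_Barts_hydrops")
  risk_items <- data.frame(
    genotype = vapply(dist$profiles[risky], render_genotype, character(1L)),
    overall_label = vapply(dx[risky], `[[`, character(1L), "overall_label"),
    probability = dist$prob[risky],
    severity = sev[risky],
    stringsAsFactors = FALSE)
  carrier_items <- data.frame(
    genotype = vapply(dist$profiles[sev == "carrier"], render_genotype, character(1L)),
    overall_label = vapply(dx[sev == "carrier"], `[[`, character(1L), "overall_label"),
    probability = dist$prob[sev == "carrier"],
    stringsAsFactors = FALSE)

  # modifier reminders: probability that an offspring carries >= 1 allele
  loci <- sort(union(names(p1$modifiers), names(p2$modifiers)))
  reminders <- character()
  for (l in loci) {
    p_off <- sum(dist$prob[vapply(dist$profiles, function(p)
      l %in% names(p$modifiers) && p$modifiers[[l]] >= 1L, logical(1L))])
    if (p_off > 0) {
      reminders <- c(reminders,
                     sprintf("offspring may carry modifier %s (P = %.4g)", l, p_off))
    }
  }
  structure(list(
    at_risk = any(risky),
    risk_items = risk_items,
    carrier_items = carrier_items,
    modifier_reminders = reminders,
    screening_relevant_parent_variants = .screening_relevant(p1, p2),
    parent_diagnoses = parent_dx,
    distribution = dist), class = "hb_risk_report")
}

.screening_relevant <- function(p1, p2) {
  out <- character()
  for (p in list(p1, p2)) {
    out <- c(out,
             p$alpha[p$alpha != "aa"],
             p$beta[p$beta != "bN"],
             if ("KLF1_zf" %in% names(p$modifiers) && p$modifiers[["KLF1_zf"]] > 0L)
               "KLF1_zf")
  }
  sort(unique(out))
}

#' @export
print.hb_risk_report <- function(x, ...) {
  cat("At-risk assessment:", if (x$at_risk) "AT RISK" else "not at risk",
      "for clinically significant hemoglobin disorders\n")
  if (nrow(x$risk_items)) {
    cat("At-risk offspring genotypes:\n")
    for (i in seq_len(nrow(x$risk_items))) {
      cat(sprintf("  %-35s P=%.4f  %s (%s)\n", x$risk_items$genotype[i],
                  x$risk_items$probability[i], x$risk_items$overall_label[i],
                  x$risk_items$severity[i]))
    }
  }
  if (nrow(x$carrier_items)) {
    cat("Carrier outcomes (reminder):\n")
    for (i in seq_len(nrow(x$carrier_items))) {
      cat(sprintf("  %-35s P=%.4f  %s\n", x$carrier_items$genotype[i],
                  x$carrier_items$probability[i], x$carrier_items$overall_label[i]))
    }
  }
  for (r in x$modifier_reminders) cat(" ", r, "\n")
  if (length(x$screening_relevant_parent_variants))
    cat("Screening-relevant parental alleles:",
        paste(x$screening_relevant_parent_variants, collapse = ", "), "\n")
  invisible(x)
}
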