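# Carrier inference: threshold decision tree over red-cell indices and the
# Hb pattern, following the traditional routine thalassemia screening
# strategy (microcytic/hypochromic screen, then HbA2 discrimination).

#' Screening threshold configuration
#'
#' Cut-offs for the carrier-inference decision tree. Defaults are the
#' internationally standard screening values: microcytosis below 82 fL MCV
#' or hypochromia below 27 pg MCH flags the screen; HbA2 above 3.5%
#' indicates a beta-thalassemia trait, below 2.5% a suspected
#' alpha-thalassemia trait, between the two a borderline result; HbF above
#' 5% in a screen-negative individual suggests HPFH or a delta-beta form;
#' ferritin below 12 ng/mL raises an iron-deficiency caveat.
#'
#' @param mcv MCV cut-off, fL.
#' @param mch MCH cut-off, pg.
#' @param hba2_low,hba2_high HbA2 discrimination window, percent.
#' @param hbf HbF cut-off for screen-negative individuals, percent.
#' @param ferritin iron-deficiency cut-off, ng/mL.
#' @return A named list of class `hb_thresholds`.
#' @export
screening_thresholds <- function(mcv = 82, mch = 27, hba2_low = 2.5,
                                 hba2_high = 3.5, hbf = 5, ferritin = 12) {
  stopifnot(mcv > 0, mch > 0, hba2_low >= 0, hba2_high >= hba2_low,
            hbf >= 0, ferritin >= 0)
  structure(list(mcv = mcv, mch = mch, hba2_low = hba2_low,
                 hba2_high = hba2_high, hbf = hbf, ferritin = ferritin),
            class = "hb_thresholds")
}

#' Construct a hemogram
#'
#' @param age age in years.
#' @param sex `"male"`, `"female"`, or `"unknown"`.
#' @param HGB hemoglobin concentration, g/L.
#' @param MCV mean corpuscular volume, fL (must be positive).
#' @param MCH mean corpuscular hemoglobin, pg (must be positive).
#' @param HbA2 HbA2 fraction, percent (0-100); may be `NA` when not measured.
#' @param HbF HbF fraction, percent (0-100).
#' @param ferritin serum ferritin, ng/mL; `NA` when not measured.
#' @return A list of class `hemogram`.
#' @export
hemogram <- function(age = NA_real_, sex = c("unknown", "male", "female"),
                     HGB = NA_real_, MCV, MCH, HbA2 = NA_real_, HbF = NA_real_,
                     ferritin = NA_real_) {
  sex <- match.arg(sex)
  if (!is.finite(MCV) || MCV <= 0) stop("MCV must be a positive number (fL)")
  if (!is.finite(MCH) || MCH <= 0) stop("MCH must be a positive number (pg)")
  if (!is.na(HbA2) && (HbA2 < 0 || HbA2 > 100)) stop("HbA2 must be a percentage in [0, 100]")
  if (!is.na(HbF) && (HbF < 0 || HbF > 100)) stop("HbF must be a percentage in [0, 100]")
  structure(list(age = age, sex = sex, HGB = HGB, MCV = MCV, MCH = MCH,
                 HbA2 = HbA2, HbF = HbF, ferritin = ferritin),
            class = "hemogram")
}

#' Infer thalassemia carrier status from a hemogram
#'
#' Deterministic decision tree: the microcytic/hypochromic screen is
#' positive iff MCV or MCH falls below its cut-off. A positive screen is
#' resolved by HbA2: above the upper cut-off is a beta-thalassemia trait
#' (molecular genotyping recommended), below the lower cut-off a suspected
#' alpha-thalassemia trait, in between a borderline result with genotyping
#' recommended. A negative screen with elevated HbF suggests HPFH or a
#' delta-beta form; otherwise the result is normal, always flagged with the
#' caveat that silent thalassemia carriers have normal or borderline
#' indices and cannot be excluded. Low ferritin adds an iron-deficiency
#' caveat and a recommendation to re-screen when iron-replete; missing
#' ferritin asserts nothing about iron status.
#'
#' @param h a [hemogram()].
#' @param thresholds a [screening_thresholds()] configuration.
#' @return Object of class `hb_inference` with elements `call`, `flags`,
#'   `recommendation`, and `thresholds_used` (an echo of `thresholds`).
#' @export
infer_trait <- function(h, thresholds = screening_thresholds()) {
  stopifnot(inherits(h, "hemogram"), inherits(thresholds, "hb_thresholds"))
  t <- thresholds
  flags <- character()
  screen_positive <- h$MCV < t$mcv || h$MCH < t$mch
  if (screen_positive && is.na(h$HbA2)) {
    call <- "not_evaluable"
    flags <- c(flags, "genotyping_recommended")
  } else if (screen_positive) {
    if (h$HbA2 > t$hba2_high) {
      call <- "beta_thal_trait"
      flags <- c(flags, "genotyping_recommended")
    } else if (h$HbA2 < t$hba2_low) {
      call <- "suspected_alpha_thal_trait"
      flags <- c(flags, "genotyping_recommended")
    } else {
      call <- "borderline_recommend_genotyping"
      flags <- c(flags, "genotyping_recommended")
    }
  } else if (!is.na(h$HbF) && h$HbF > t$hbf) {
    call <- "elevated_HbF_suspect_HPFH_or_deltabeta"
    flags <- c(flags, "genotyping_recommended")
  } else {
    call <- "normal"
    flags <- c(flags, "silent_carrier_not_excluded")
  }
  recommendation <- switch(call,
    beta_thal_trait = "beta-thalassemia trait inferred; molecular genotyping is highly recommended",
    suspected_alpha_thal_trait = "suspected alpha-thalassemia trait; molecular genotyping recommended",
    borderline_recommend_genotyping = "borderline HbA2 with microcytosis/hypochromia; molecular genotyping recommended",
    elevated_HbF_suspect_HPFH_or_deltabeta = "elevated HbF; consider HPFH or delta-beta thalassemia, genotyping recommended",
    not_evaluable = "positive red-cell screen but HbA2 not measured; complete the Hb pattern",
    normal = "no thalassemia trait inferred; silent carriers are not excluded by normal indices")
  if (!is.na(h$ferritin) && h$ferritin < t$ferritin) {
    flags <- c(flags, "iron_deficiency_caveat")
    recommendation <- paste0(recommendation,
      "; iron deficiency detected - repeat the hematologic screen once iron-replete")
  }
  structure(list(call = call, flags = unique(flags),
                 recommendation = recommendation, thresholds_used = t),
            class = "hb_inference")
}

#' @export
print.hb_inference <- function(x, ...) {
  cat("Carrier inference:", x$call, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  cat(" ", x$recommendation, "\n")
  invisible(x)
}

#' Run carrier inference over a phenotype table
#'
#' @param phenotypes data.frame with columns `individual_id`, `age`, `sex`,
#'   `HGB`, `MCV`, `MCH`, `HbA2`, `HbF`, and optionally `ferritin`.
#' @param thresholds a [screening_thresholds()] configuration.
#' @return data.frame with one row per individual: `individual_id`, `call`,
#'   `flags` (comma-separated), `recommendation`.
#' @export
infer_cohort <- function(phenotypes, thresholds = screening_thresholds()) {
  stopifnot(all(c("individual_id", "MCV", "MCH") %in% names(phenotypes)))
  get <- function(col, i) {
    if (col %in% names(phenotypes)) phenotypes[[col]][i] else NA_real_
  }
  rows <- lapply(seq_len(nrow(phenotypes)), function(i) {
    sex <- if ("sex" %in% names(phenotypes)) as.character(phenotypes$sex[i]) else "unknown"
    if (is.na(sex) || !sex %in% c("male", "female")) sex <- "unknown"
    h <- hemogram(age = get("age", i), sex = sex, HGB = get("HGB", i),
                  MCV = phenotypes$MCV[i], MCH = phenotypes$MCH[i],
                  HbA2 = get("HbA2", i), HbF = get("HbF", i),
                  ferritin = get("ferritin", i))
    res <- infer_trait(h, thresholds)
    data.frame(individual_id = phenotypes$individual_id[i], call = res$call,
               flags = paste(res$flags, collapse = ","),
               recommendation = res$recommendation, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
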