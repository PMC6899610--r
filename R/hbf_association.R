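# HbF quantitative-trait association scan: per-variant carrier vs
# non-carrier comparison with Bonferroni correction.

#' Partition samples into carriers and non-carriers for one variant
#'
#' Dominant carrier coding: carriers are samples with at least one
#' alternative allele; missing genotypes are excluded. A variant is
#' skipped (not tested) when either group is smaller than
#' `min_group_size`.
#'
#' @param genotypes integer vector of allele doses (0/1/2, `NA` missing).
#' @param min_group_size minimum samples per group for testing.
#' @return List with `carriers` and `noncarriers` (index vectors),
#'   `tested` (logical), and `skip_reason`.
#' @export
carrier_partition <- function(genotypes, min_group_size = 2L) {
  ok <- !is.na(genotypes)
  carriers <- which(ok & genotypes >= 1L)
  noncarriers <- which(ok & genotypes == 0L)
  tested <- length(carriers) >= min_group_size &&
    length(noncarriers) >= min_group_size
  list(carriers = carriers, noncarriers = noncarriers, tested = tested,
       skip_reason = if (tested) NA_character_ else
         sprintf("group sizes %d/%d below minimum %d",
                 length(carriers), length(noncarriers), min_group_size))
}

# Welch two-sample statistics (two-sided, unequal variances)
.welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (!is.finite(se2) || se2 <= 0) {
    # zero-variance limit: identical means -> p = 1, otherwise p -> 0
    p <- if (isTRUE(all.equal(m1, m2))) 1 else 0
    return(list(mean1 = m1, mean2 = m2, p = p))
  }
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(mean1 = m1, mean2 = m2, p = 2 * stats::pt(-abs(tt), df))
}

#' Carrier vs non-carrier HbF association scan
#'
#' For every variant column, compares the trait between carriers (dose
#' >= 1) and non-carriers with a two-sided Welch test (default), or fits
#' an additive linear model on allele dose when `model = "additive"`.
#' Significance is judged against `alpha / m`, where m is the number of
#' variants actually tested after skip rules (Bonferroni), or against
#' `alpha` when `correction = "none"`. Direction is `elevates_HbF` iff the
#' carrier mean exceeds the non-carrier mean.
#'
#' @param genotypes n x m numeric matrix of allele doses (0/1/2, `NA`
#'   missing); column names identify variants.
#' @param trait numeric vector of length n (HbF, g/L).
#' @param alpha nominal family-wise level in (0, 1).
#' @param correction `"bonferroni"` or `"none"`.
#' @param model `"dominant"` (carrier coding, Welch test) or `"additive"`
#'   (linear regression on dose).
#' @param annotation optional data.frame with one row per variant (e.g.
#'   columns `rsid`, `locus`, `chrom`, `pos`, `ref`, `alt`); when `chrom`
#'   and `pos` are present, results are sorted by position.
#' @param min_group_size minimum per-group sample count for testing.
#' @return Object of class `hbf_scan`: a data.frame with columns
#'   `variant`, `n_carriers`, `n_noncarriers`, `carrier_frequency`,
#'   `mean_HbF_carriers`, `mean_HbF_noncarriers`, `direction`, `p_value`,
#'   `tested`, `significant`, plus attributes `m_tested`, `alpha`,
#'   `threshold`, `model`, and `correction`.
#' @export
hbf_scan <- function(genotypes, trait, alpha = 0.05,
                     correction = c("bonferroni", "none"),
                     model = c("dominant", "additive"),
                     annotation = NULL, min_group_size = 2L) {
  correction <- match.arg(correction)
  model <- match.arg(model)
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != length(trait))
    stop("trait length must equal the number of genotype rows")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(m))
  if (!is.null(annotation) && nrow(annotation) != m)
    stop("annotation must have one row per variant column")

  res <- data.frame(variant = ids, n_carriers = NA_integer_,
                    n_noncarriers = NA_integer_,
                    carrier_frequency = NA_real_,
                    mean_HbF_carriers = NA_real_,
                    mean_HbF_noncarriers = NA_real_,
                    direction = NA_character_, p_value = NA_real_,
                    tested = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    part <- carrier_partition(genotypes[, j], min_group_size)
    n1 <- length(part$carriers); n0 <- length(part$noncarriers)
    res$n_carriers[j] <- n1
    res$n_noncarriers[j] <- n0
    if (n1 + n0 > 0L) res$carrier_frequency[j] <- n1 / (n1 + n0)
    if (!part$tested) next
    res$tested[j] <- TRUE
    res$mean_HbF_carriers[j] <- mean(trait[part$carriers])
    res$mean_HbF_noncarriers[j] <- mean(trait[part$noncarriers])
    res$direction[j] <- if (res$mean_HbF_carriers[j] > res$mean_HbF_noncarriers[j])
      "elevates_HbF" else "decreases_HbF"
    if (model == "dominant") {
      res$p_value[j] <- .welch(trait[part$carriers], trait[part$noncarriers])$p
    } else {
      keep <- !is.na(genotypes[, j])
      fit <- stats::lm(trait[keep] ~ genotypes[keep, j])
      cf <- summary(fit)$coefficients
      res$p_value[j] <- if (nrow(cf) < 2L) 1 else cf[2L, 4L]
    }
  }
  m_tested <- sum(res$tested)
  threshold <- if (correction == "bonferroni" && m_tested > 0L)
    alpha / m_tested else alpha
  res$significant <- res$tested & !is.na(res$p_value) & res$p_value <= threshold

  if (!is.null(annotation)) {
    res <- cbind(res, annotation)
    if (all(c("chrom", "pos") %in% names(annotation))) {
      res <- res[order(res$chrom, res$pos), , drop = FALSE]
      rownames(res) <- NULL
    }
  }
  structure(res, m_tested = m_tested, alpha = alpha, threshold = threshold,
            model = model, correction = correction,
            class = c("hbf_scan", "data.frame"))
}

#' @export
print.hbf_scan <- function(x, ...) {
  cat(sprintf("HbF association scan (%s coding, %s correction): %d variants, %d tested, %d significant at alpha = %g (threshold %.3g)\n",
              attr(x, "model"), attr(x, "correction"), nrow(x),
              attr(x, "m_tested"), sum(x$significant), attr(x, "alpha"),
              attr(x, "threshold")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  cat("Note: statistical association does not localize causal variants within a haplotype block.\n")
  invisible(x)
}

RESULT_TABLE_COLUMNS <- c("SNPs", "Locus", "Location", "Nucleotide_change",
                          "Frequency", "Modification", "P_value",
                          "HbF_carriers", "HbF_noncarriers")

#' Write an association result table
#'
#' Fixed column order: SNPs, Locus, Location (`chrom:pos`, GRCh37),
#' Nucleotide_change, Frequency, Modification, P_value, HbF_carriers,
#' HbF_noncarriers. An `hbf_scan` is formatted; a character data.frame in
#' the same layout (for example from [read_result_table()]) is written
#' verbatim, so a load-write cycle is byte-identical.
#'
#' @param results an `hbf_scan` or a data.frame with the table columns.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path) {
  if (inherits(results, "hbf_scan")) {
    blank <- character(nrow(results))
    loc <- if (all(c("chrom", "pos") %in% names(results)))
      sprintf("%s:%d", results$chrom, results$pos) else blank
    tab <- data.frame(
      SNPs = if ("rsid" %in% names(results)) results$rsid else results$variant,
      Locus = if ("locus" %in% names(results)) results$locus else blank,
      Location = loc,
      Nucleotide_change = if (all(c("ref", "alt") %in% names(results)))
        paste0(results$ref, ">", results$alt) else blank,
      Frequency = sprintf("%.4g", results$carrier_frequency),
      Modification = ifelse(results$direction == "elevates_HbF",
                            "Elevated HbF", "Decreased HbF"),
      P_value = sprintf("%.3g", results$p_value),
      HbF_carriers = sprintf("%.4f", results$mean_HbF_carriers),
      HbF_noncarriers = sprintf("%.4f", results$mean_HbF_noncarriers),
      stringsAsFactors = FALSE)
    tab <- tab[results$tested, , drop = FALSE]
  } else {
    missing <- setdiff(RESULT_TABLE_COLUMNS, names(results))
    if (length(missing) > 0L)
      stop("result table missing column(s): ", paste(missing, collapse = ", "))
    tab <- results[, RESULT_TABLE_COLUMNS, drop = FALSE]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an association result table
#'
#' @param path TSV written by [write_result_table()] (or the packaged
#'   curated modifier table, see [modifier_scan_table()]).
#' @return data.frame with character columns in the fixed table layout.
#' @export
read_result_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", fileEncoding = "UTF-8")
  missing <- setdiff(RESULT_TABLE_COLUMNS, names(tab))
  if (length(missing) > 0L)
    stop("result table missing column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Packaged curated HbF modifier scan table
#'
#' The 34 curated functional HbF modifier variants in the candidate genes
#' and the HMIP intergenic region, with carrier frequencies, effect
#' directions, association p-values, and carrier / non-carrier HbF group
#' means (g/L), GRCh37 coordinates.
#'
#' @return data.frame in the result-table layout (character columns).
#' @export
modifier_scan_table <- function() {
  path <- system.file("extdata", "hbf_modifier_scan.tsv",
                      package = "hemotyper", mustWork = TRUE)
  read_result_table(path)
}
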