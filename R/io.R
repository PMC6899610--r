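# Input readers: per-individual variant lists (TSV and minimal VCF),
# phenotype tables, threshold/rule JSON.

#' Read a per-individual variant list (TSV)
#'
#' Columns: `individual_id`, `key` (rsID, HGVS, CNV name, or
#' `chrom:pos:ref:alt`), `zygosity` (`het`/`hom`), optional `phase`
#' (`cis` marks a variant on the same HBB-cluster haplotype as the
#' previous one).
#'
#' @param path TSV file.
#' @return data.frame of variant inputs.
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", fileEncoding = "UTF-8")
  need <- c("individual_id", "key", "zygosity")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L)
    stop("variant TSV missing column(s): ", paste(missing, collapse = ", "))
  if (!"phase" %in% names(tab)) tab$phase <- ""
  tab
}

#' Read a minimal single-sample VCF
#'
#' Uses only CHROM, POS, REF, ALT and the first sample's GT field; all
#' other fields are ignored. Each record becomes a lookup key
#' `chrom:pos:ref:alt` with zygosity `hom` for `1/1`-style genotypes and
#' `het` otherwise; `0/0` and `./.` records are dropped.
#'
#' @param path VCF file (uncompressed).
#' @param individual_id id to assign to the sample.
#' @return data.frame with columns `individual_id`, `key`, `zygosity`,
#'   `phase`.
#' @export
read_variants_vcf <- function(path, individual_id = "sample") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) next
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) next
    gt <- strsplit(f[10L], ":", fixed = TRUE)[[1L]][gt_i]
    alleles <- strsplit(gt, "[/|]")[[1L]]
    n_alt <- sum(alleles == "1")
    if (n_alt == 0L) next
    chrom <- sub("^chr", "", f[1L])
    out[[length(out) + 1L]] <- data.frame(
      individual_id = individual_id,
      key = paste(chrom, f[2L], f[4L], strsplit(f[5L], ",")[[1L]][1L], sep = ":"),
      zygosity = if (n_alt >= 2L) "hom" else "het",
      phase = "", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(individual_id = character(), key = character(),
                      zygosity = character(), phase = character()))
  do.call(rbind, out)
}

#' Read a phenotype table (CSV)
#'
#' Columns: `individual_id`, `age`, `sex`, `HGB`, `MCV`, `MCH`, `HbA2`,
#' `HbF`, optional `ferritin`.
#'
#' @param path CSV file.
#' @return data.frame of phenotypes.
#' @export
read_phenotypes_csv <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("individual_id", "MCV", "MCH"), names(tab))
  if (length(missing) > 0L)
    stop("phenotype CSV missing column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Read a screening-threshold configuration from JSON
#'
#' @param path JSON file with any subset of the [screening_thresholds()]
#'   fields; unspecified fields keep their defaults.
#' @return An `hb_thresholds` object.
#' @export
read_thresholds_json <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(screening_thresholds, as.list(vals))
}

#' Read a rule configuration from JSON
#'
#' @param path JSON file with any subset of the [classify_rules()] fields.
#' @return An `hb_rules` object.
#' @export
read_rules_json <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(classify_rules, as.list(vals))
}
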