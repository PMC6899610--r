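# Variant knowledge base: schema, IO (TSV/JSON), validation, summaries, lookup.

KB_COLUMNS <- c(
  "variant_id", "gene", "hgvs", "rsid", "chrom", "pos", "ref", "alt",
  "category", "acmg_class", "phenotype_class", "allele_class",
  "modifier_effect", "klf1_zinc_finger", "screening_relevant", "source"
)

GLOBIN_GENES <- c("HBB", "HBA1", "HBA2", "HBD", "HBG1", "HBG2")
KB_GENES <- c(GLOBIN_GENES, "KLF1", "BCL11A", "GATA1", "HMIP")

ACMG_CLASSES <- c("pathogenic", "likely_pathogenic", "uncertain_significance",
                  "likely_benign", "benign")
PHENOTYPE_CLASSES <- c("Hb_variant", "thalassemia", "HPFH", "uncertain")
BETA_ALLELE_CLASSES <- c("beta0", "beta_plus", "betaE", "betaS",
                         "beta_dominant", "hpfh_del", "none")
MODIFIER_EFFECTS <- c("elevates_HbF", "decreases_HbF", "severity_modifier", "none")

# GRCh37 chromosome expected for each gene
GENE_CHROM <- c(
  HBB = "11", HBD = "11", HBG1 = "11", HBG2 = "11",
  HBA1 = "16", HBA2 = "16",
  KLF1 = "19", BCL11A = "2", HMIP = "6", GATA1 = "X"
)

#' Default candidate regions (GRCh37)
#'
#' Gene spans padded by 50 kb on both sides, except the HMIP intergenic
#' region which is a fixed interval on chromosome 6 wide enough to contain
#' all curated HMIP modifier coordinates. Intervals are 1-based half-open
#' `[start, end)`.
#'
#' @return A data.frame with columns `region`, `chrom`, `start`, `end`.
#' @export
candidate_regions_default <- function() {
  pad <- 50000L
  spans <- data.frame(
    region = c("HBB_cluster", "HBA_cluster", "KLF1", "BCL11A", "GATA1"),
    chrom  = c("11", "16", "19", "2", "X"),
    start  = c(5246696L, 222846L, 12995237L, 60684329L, 48644982L),
    end    = c(5276396L, 227521L, 12998018L, 60780634L, 48652718L),
    stringsAsFactors = FALSE
  )
  spans$start <- pmax(1L, spans$start - pad)
  spans$end <- spans$end + pad
  rbind(spans, data.frame(region = "HMIP", chrom = "6",
                          start = 135200000L, end = 135600000L))
}

# which candidate region(s) cover a gene, for coordinate-consistency checks
GENE_REGION <- list(
  HBB = "HBB_cluster", HBD = "HBB_cluster", HBG1 = "HBB_cluster",
  HBG2 = "HBB_cluster", HBA1 = "HBA_cluster", HBA2 = "HBA_cluster",
  KLF1 = "KLF1", BCL11A = "BCL11A", GATA1 = "GATA1", HMIP = "HMIP"
)

#' Construct a knowledge base from a record data.frame
#'
#' @param records data.frame with the columns of [kb_columns()].
#' @param regions candidate regions; defaults to [candidate_regions_default()].
#' @param version version string recorded in the metadata.
#' @param build genome build string; the packaged content is GRCh37.
#' @param errors data.frame of unparseable input rows kept for inspection.
#' @return An object of class `hb_kb` (a data.frame of variant records with
#'   `regions` and `meta` attributes).
#' @export
kb_new <- function(records, regions = candidate_regions_default(),
                   version = "0", build = "GRCh37", errors = NULL) {
  missing <- setdiff(KB_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop("knowledge-base records missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  records <- records[, KB_COLUMNS, drop = FALSE]
  dup <- unique(records$variant_id[duplicated(records$variant_id)])
  if (length(dup) > 0L) {
    stop("duplicate variant_id in knowledge base: ", paste(dup, collapse = ", "))
  }
  structure(records,
            regions = regions,
            meta = list(version = version, build = build),
            errors = errors,
            class = c("hb_kb", "data.frame"))
}

#' Knowledge-base column names
#' @return Character vector of the canonical record fields.
#' @export
kb_columns <- function() KB_COLUMNS

# parse raw character fields into typed record fields; rows that fail to
# parse are returned separately, never silently dropped
.kb_type_rows <- function(raw) {
  raw[is.na(raw)] <- "."
  pos <- suppressWarnings(as.integer(raw$pos))
  pos[raw$pos %in% c(".", "")] <- 0L
  to_flag <- function(x) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no", ".", "")] <- FALSE
    out
  }
  zf <- to_flag(raw$klf1_zinc_finger)
  sr <- to_flag(raw$screening_relevant)
  bad <- is.na(pos) | is.na(zf) | is.na(sr)
  clean <- function(x) ifelse(x == ".", "", x)
  rec <- data.frame(
    variant_id = raw$variant_id, gene = raw$gene,
    hgvs = clean(raw$hgvs), rsid = clean(raw$rsid),
    chrom = clean(raw$chrom), pos = pos,
    ref = clean(raw$ref), alt = clean(raw$alt),
    category = raw$category, acmg_class = raw$acmg_class,
    phenotype_class = raw$phenotype_class, allele_class = raw$allele_class,
    modifier_effect = raw$modifier_effect,
    klf1_zinc_finger = zf, screening_relevant = sr,
    source = clean(raw$source),
    stringsAsFactors = FALSE
  )
  list(records = rec[!bad, , drop = FALSE],
       errors = raw[bad, , drop = FALSE])
}

#' Load a knowledge base from disk
#'
#' Reads the tab-separated dialect (header row, columns = record fields,
#' `.` for empty optional fields, UTF-8) or the JSON mirror (array of
#' objects). Rows that cannot be typed (for example a non-integer position)
#' are collected into the `errors` attribute rather than dropped.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"json"`; default guessed from the extension.
#' @param regions candidate regions to attach.
#' @return An `hb_kb` object.
#' @export
load_kb <- function(path, dialect = c("auto", "tsv", "json"),
                    regions = candidate_regions_default()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("knowledge-base file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (dialect == "tsv") {
    raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                             quote = "", fileEncoding = "UTF-8",
                             check.names = FALSE)
  } else {
    raw <- jsonlite::fromJSON(path)
    if (length(raw) == 0L) {
      raw <- as.data.frame(matrix(character(), ncol = length(KB_COLUMNS),
                                  dimnames = list(NULL, KB_COLUMNS)),
                           stringsAsFactors = FALSE)
    }
    raw[] <- lapply(raw, as.character)
  }
  missing <- setdiff(KB_COLUMNS, names(raw))
  if (length(missing) > 0L) {
    stop("knowledge-base file ", path, " missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  typed <- .kb_type_rows(raw)
  kb_new(typed$records, regions = regions,
         errors = if (nrow(typed$errors)) typed$errors else NULL)
}

#' Write a knowledge base to disk
#'
#' Inverse of [load_kb()]: the written file round-trips to a record-identical
#' knowledge base in either dialect. Empty optional fields are written as `.`
#' in the TSV dialect.
#'
#' @param kb an `hb_kb` object.
#' @param path output file.
#' @param dialect `"tsv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, dialect = c("auto", "tsv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  out <- as.data.frame(kb, stringsAsFactors = FALSE)
  out$pos <- as.character(out$pos)
  out$pos[out$pos == "0"] <- "."
  out$klf1_zinc_finger <- ifelse(kb$klf1_zinc_finger, "true", "false")
  out$screening_relevant <- ifelse(kb$screening_relevant, "true", "false")
  for (col in c("hgvs", "rsid", "chrom", "ref", "alt", "source")) {
    out[[col]][out[[col]] == ""] <- "."
  }
  if (dialect == "tsv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows")
  }
  invisible(path)
}

#' Validate knowledge-base records against the schema invariants
#'
#' Checks every record for: known gene and enumerated category/ACMG/
#' phenotype/allele-class/modifier-effect values; modifier records carrying
#' a modifier effect (or being of uncertain significance); disease-causing
#' records restricted to globin genes; `klf1_zinc_finger` only on KLF1;
#' chromosome/position jointly set or jointly empty, the chromosome matching
#' the gene, and set coordinates falling inside a candidate region.
#'
#' Issues are data, not exceptions: a zero-row result means the knowledge
#' base is valid.
#'
#' @param kb an `hb_kb` object.
#' @return data.frame with columns `variant_id`, `field`, `rule`.
#' @export
validate_kb <- function(kb) {
  issues <- list()
  add <- function(id, field, rule) {
    issues[[length(issues) + 1L]] <<- data.frame(
      variant_id = id, field = field, rule = rule, stringsAsFactors = FALSE)
  }
  regions <- attr(kb, "regions")
  alpha_ok <- as.character(0:4)
  for (i in seq_len(nrow(kb))) {
    r <- kb[i, ]
    if (!r$gene %in% KB_GENES)
      add(r$variant_id, "gene", "gene must be a recognized candidate gene")
    if (!r$category %in% c("disease_causing", "modifier"))
      add(r$variant_id, "category", "category must be disease_causing or modifier")
    if (!r$acmg_class %in% ACMG_CLASSES)
      add(r$variant_id, "acmg_class", "acmg_class must be one of the ACMG 5 tiers")
    if (!r$phenotype_class %in% PHENOTYPE_CLASSES)
      add(r$variant_id, "phenotype_class", "unknown phenotype_class")
    if (!r$allele_class %in% c(BETA_ALLELE_CLASSES, alpha_ok))
      add(r$variant_id, "allele_class",
          "allele_class must be a beta class or an alpha functional-gene count 0-4")
    if (!r$modifier_effect %in% MODIFIER_EFFECTS)
      add(r$variant_id, "modifier_effect", "unknown modifier_effect")
    if (identical(r$category, "modifier") &&
        identical(r$modifier_effect, "none") &&
        !identical(r$acmg_class, "uncertain_significance"))
      add(r$variant_id, "modifier_effect",
          "modifier record must have a modifier effect or be of uncertain significance")
    if (identical(r$category, "disease_causing") && !r$gene %in% GLOBIN_GENES)
      add(r$variant_id, "gene", "disease-causing records are restricted to globin genes")
    if (isTRUE(r$klf1_zinc_finger) && !identical(r$gene, "KLF1"))
      add(r$variant_id, "klf1_zinc_finger", "klf1_zinc_finger only applies to KLF1")
    has_chrom <- nzchar(r$chrom)
    has_pos <- r$pos > 0L
    if (has_chrom != has_pos) {
      add(r$variant_id, "chrom/pos", "chrom and pos must be jointly set or jointly empty")
    } else if (has_pos) {
      expected <- GENE_CHROM[[r$gene]]
      if (!is.null(expected) && !identical(r$chrom, expected)) {
        add(r$variant_id, "chrom",
            sprintf("chrom %s inconsistent with gene %s (expected %s)",
                    r$chrom, r$gene, expected))
      } else if (is.na(region_membership(kb, r$chrom, r$pos))) {
        add(r$variant_id, "pos", "coordinate outside all candidate regions")
      }
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(variant_id = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Summarize a knowledge base
#'
#' Per-gene by phenotype-class count matrix for disease-causing records,
#' per-gene modifier counts, and totals. Totals are computed, never stored.
#'
#' @param kb an `hb_kb` object.
#' @return An object of class `hb_kb_summary`.
#' @export
summarize_kb <- function(kb) {
  dc <- kb[kb$category == "disease_causing", , drop = FALSE]
  mod <- kb[kb$category == "modifier", , drop = FALSE]
  disease <- table(factor(dc$gene, levels = GLOBIN_GENES),
                   factor(dc$phenotype_class, levels = PHENOTYPE_CLASSES))
  disease <- unclass(as.matrix(disease))
  modifier <- table(factor(mod$gene, levels = KB_GENES))
  modifier <- stats::setNames(as.integer(modifier), names(modifier))
  structure(list(disease = disease, modifier = modifier),
            class = "hb_kb_summary")
}

#' @export
print.hb_kb_summary <- function(x, ...) {
  s <- x
  cat("Knowledge-base summary\n")
  cat("Disease-causing variants (gene x pathogenicity):\n")
  m <- cbind(s$disease, Total = rowSums(s$disease))
  print(m)
  cat("Disease-causing total:", kb_summary_totals(s)["disease_causing"], "\n")
  cat("Modifier variants:", kb_summary_totals(s)["modifier"], "\n")
  cat("Grand total:", kb_summary_totals(s)["grand"], "\n")
  invisible(x)
}

#' Totals of a knowledge-base summary
#'
#' @param s an `hb_kb_summary` (from [summarize_kb()] or
#'   [read_count_manifest()]).
#' @return Named numeric vector: per-gene disease-causing totals plus
#'   `disease_causing`, `modifier`, and `grand` totals.
#' @export
kb_summary_totals <- function(s) {
  gene_totals <- rowSums(s$disease)
  c(gene_totals,
    disease_causing = sum(s$disease),
    modifier = sum(s$modifier),
    grand = sum(s$disease) + sum(s$modifier))
}

#' Read a knowledge-base count manifest
#'
#' A count manifest records the size of a knowledge base whose full records
#' are not distributed: one row per gene and pathogenicity class with a
#' count, plus aggregate `modifier` rows (gene `.` allowed when the per-gene
#' modifier breakdown is unknown). Columns: `gene`, `category`
#' (`disease_causing`/`modifier`), `phenotype_class`, `count`.
#'
#' @param path manifest TSV.
#' @return An `hb_kb_summary` with the same shape as [summarize_kb()].
#' @export
read_count_manifest <- function(path) {
  m <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  need <- c("gene", "category", "phenotype_class", "count")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0L) {
    stop("count manifest missing column(s): ", paste(missing, collapse = ", "))
  }
  dc <- m[m$category == "disease_causing", , drop = FALSE]
  mod <- m[m$category == "modifier", , drop = FALSE]
  disease <- matrix(0L, nrow = length(GLOBIN_GENES), ncol = length(PHENOTYPE_CLASSES),
                    dimnames = list(GLOBIN_GENES, PHENOTYPE_CLASSES))
  for (i in seq_len(nrow(dc))) {
    disease[dc$gene[i], dc$phenotype_class[i]] <-
      disease[dc$gene[i], dc$phenotype_class[i]] + dc$count[i]
  }
  modifier <- stats::setNames(rep(0L, length(KB_GENES) + 1L), c(KB_GENES, "."))
  for (i in seq_len(nrow(mod))) {
    g <- if (mod$gene[i] %in% names(modifier)) mod$gene[i] else "."
    modifier[g] <- modifier[g] + mod$count[i]
  }
  structure(list(disease = disease, modifier = modifier),
            class = "hb_kb_summary")
}

#' Look up knowledge-base records by identifier
#'
#' Accepts an rsID (`rs...`), an HGVS string (`GENE:c....`), a named CNV
#' allele (`--SEA`, `-a3.7`, `aaa`, ... — unicode alpha shorthand accepted),
#' or a coordinate key `chrom:pos:ref:alt`. All records matching any
#' identifier form are returned; an empty result is not an error.
#'
#' @param kb an `hb_kb` object.
#' @param key identifier string, or a list/vector `c(chrom, pos, ref, alt)`.
#' @return The matching rows of `kb` (possibly zero rows).
#' @export
kb_lookup <- function(kb, key) {
  if (is.list(key) || (is.character(key) && length(key) > 1L) || is.numeric(key)) {
    key <- unlist(key)
    if (length(key) != 4L) {
      stop("coordinate key must have exactly 4 elements: chrom, pos, ref, alt")
    }
    pos <- suppressWarnings(as.integer(key[2L]))
    if (is.na(pos) || pos < 1L) stop("malformed coordinate key: pos must be a positive integer")
    hit <- kb$chrom == as.character(key[1L]) & kb$pos == pos &
      kb$ref == as.character(key[3L]) & kb$alt == as.character(key[4L])
    return(kb[hit, , drop = FALSE])
  }
  key <- trimws(as.character(key))
  if (grepl("^rs[0-9]+$", key)) {
    return(kb[kb$rsid == key, , drop = FALSE])
  }
  if (grepl(":", key, fixed = TRUE) && grepl("^[A-Za-z0-9]+:[cgmnp]\\.", key)) {
    return(kb[kb$hgvs == key, , drop = FALSE])
  }
  if (grepl("^[A-Za-z0-9]+:[0-9]+:", key)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    return(kb_lookup(kb, as.list(parts)))
  }
  # CNV / named allele: match the alt field (canonical ASCII form)
  canon <- tryCatch(normalize_alpha_name(key), error = function(e) key)
  kb[kb$alt == canon | kb$alt == key | kb$variant_id == key, , drop = FALSE]
}

#' Candidate-region membership of a genomic position
#'
#' Intervals are half-open: `start` is inside its region, `end` is not.
#'
#' @param kb an `hb_kb` object (its `regions` attribute is queried).
#' @param chrom chromosome name (GRCh37 convention, no `chr` prefix).
#' @param pos 1-based position.
#' @return The region name, or `NA_character_` if no region contains the
#'   position.
#' @export
region_membership <- function(kb, chrom, pos) {
  stopifnot(pos >= 1)
  regions <- if (inherits(kb, "hb_kb")) attr(kb, "regions") else kb
  chrom <- sub("^chr", "", as.character(chrom))
  hit <- regions$chrom == chrom & regions$start <= pos & pos < regions$end
  if (!any(hit)) NA_character_ else regions$region[which(hit)[1L]]
}

#' Packaged demonstration knowledge base
#'
#' Loads the demonstration knowledge base shipped with the package: the
#' common Chinese deletional and nondeletional alpha-thalassemia alleles,
#' a set of representative beta-thalassemia and clinically significant Hb
#' variant alleles (Hb S, Hb E, Hb Midnapore), KLF1 zinc-finger alleles,
#' and the 34 curated HbF modifier variants in the candidate genes and the
#' HMIP region. It is a demonstration subset, not the full curated content.
#'
#' @return An `hb_kb` object.
#' @export
demo_kb <- function() {
  path <- system.file("extdata", "demo_kb.tsv", package = "hemotyper",
                      mustWork = TRUE)
  kb <- load_kb(path, dialect = "tsv")
  attr(kb, "meta")$version <- "demo-1"
  kb
}

#' @export
print.hb_kb <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Hemoglobinopathy knowledge base (%s, version %s): %d records\n",
              meta$build, meta$version, nrow(x)))
  cat(sprintf("  disease-causing: %d, modifier: %d\n",
              sum(x$category == "disease_causing"), sum(x$category == "modifier")))
  err <- attr(x, "errors")
  if (!is.null(err)) cat(sprintf("  unparseable rows retained: %d\n", nrow(err)))
  invisible(x)
}
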