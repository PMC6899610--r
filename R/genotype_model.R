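# Genotype model: alpha copy-number haplotypes, beta allele classes,
# modifier genotypes, shorthand parsing, functional dosage.

# canonical ASCII haplotype names -> functional alpha-gene count
ALPHA_HAPLOTYPES <- data.frame(
  name = c("aa", "-a3.7", "-a4.2", "--SEA", "--THAI", "--FIL",
           "aaa", "aaaa", "aCSa", "aQSa", "aNDa"),
  functional = c(2L, 1L, 1L, 0L, 0L, 0L, 3L, 4L, 1L, 1L, 1L),
  nondeletional = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

BETA_CODES <- c(bN = "betaN", b0 = "beta0", `b+` = "beta_plus", bE = "betaE",
                bS = "betaS", bD = "beta_dominant", hpfh = "hpfh_del")

MODIFIER_LOCI <- c("KLF1_zf", "XmnI_rs7482144", "BCL11A_rs61749494",
                   "HMIP_rs11759553", "alpha_dc_coinherited", "other")

# unicode/markup-tolerant normalization of shorthand text to ASCII
.normalize_shorthand <- function(text) {
  x <- text
  x <- gsub("\u03b2", "b", x)   # beta
  x <- gsub("\u03b1", "a", x)   # alpha
  x <- gsub("\u2070", "0", x)   # superscript 0
  x <- gsub("\u207a", "+", x)   # superscript +
  x <- gsub("\u1d3a", "N", x)   # modifier-letter capital N
  x <- gsub("\u1d39", "M", x)   # modifier-letter capital M
  x <- gsub("\u1d31", "E", x)   # modifier-letter capital E
  x <- gsub("\u02e2", "S", x)   # modifier-letter s
  x <- gsub("[\\^]", "", x)     # markup superscript carets
  x
}

#' Normalize an alpha-haplotype name to its canonical ASCII form
#'
#' Accepts the unicode shorthand (`"\u03b1\u03b1"`, `"--SEA"`,
#' `"-\u03b13.7"`, `"\u03b1\u03b1\u03b1"`, `"\u03b1CS\u03b1"`, ...) and the
#' ASCII aliases (`"aa"`, `"-a3.7"`, `"aaa"`, `"aCSa"`, ...).
#'
#' @param name haplotype name.
#' @return Canonical name, one of `alpha_haplotype_table()$name`.
#' @export
normalize_alpha_name <- function(name) {
  x <- trimws(.normalize_shorthand(name))
  if (x %in% ALPHA_HAPLOTYPES$name) return(x)
  # nondeletional generic form aXXa
  if (grepl("^a[A-Za-z]{1,3}a$", x)) return(x)
  stop("unrecognized alpha haplotype name: ", name)
}

#' Alpha-haplotype reference table
#'
#' Named alpha-globin haplotype alleles with their functional gene counts:
#' the normal `aa` cis pair (2), single-gene deletions `-a3.7`/`-a4.2` (1),
#' double-gene deletions `--SEA`/`--THAI`/`--FIL` (0), triplication `aaa`
#' (3), quadruplication `aaaa` (4), and nondeletional forms such as `aCSa`
#' (Hb Constant Spring) counting 1 functional plus 1 dysfunctional gene.
#'
#' @return data.frame with columns `name`, `functional`, `nondeletional`.
#' @export
alpha_haplotype_table <- function() ALPHA_HAPLOTYPES

.alpha_functional <- function(name) {
  i <- match(name, ALPHA_HAPLOTYPES$name)
  out <- ALPHA_HAPLOTYPES$functional[i]
  # generic nondeletional aXXa forms: 1 functional + 1 dysfunctional
  out[is.na(i)] <- 1L
  out
}

.alpha_nondeletional <- function(name) {
  i <- match(name, ALPHA_HAPLOTYPES$name)
  out <- ALPHA_HAPLOTYPES$nondeletional[i]
  out[is.na(i)] <- TRUE
  out
}

#' Construct a genotype profile
#'
#' A genotype profile holds an individual's two alpha-globin haplotypes
#' (named copy-number alleles), two beta-globin alleles (functional
#' classes), and modifier-locus allele doses.
#'
#' @param alpha character pair of alpha haplotype names (unicode or ASCII).
#' @param beta character pair of beta allele codes among
#'   `c("bN","b0","b+","bE","bS","bD","hpfh")`.
#' @param modifiers named integer vector of allele doses (0/1/2) for loci in
#'   `c("KLF1_zf","XmnI_rs7482144","BCL11A_rs61749494","HMIP_rs11759553",`
#'   `"alpha_dc_coinherited","other")`. `alpha_dc_coinherited` is a 0/1 flag.
#' @return Object of class `genotype_profile`.
#' @export
genotype_profile <- function(alpha = c("aa", "aa"), beta = c("bN", "bN"),
                             modifiers = integer()) {
  if (length(alpha) != 2L) stop("exactly 2 alpha haplotypes required")
  if (length(beta) != 2L) stop("exactly 2 beta alleles required")
  alpha <- vapply(alpha, normalize_alpha_name, character(1L), USE.NAMES = FALSE)
  beta <- vapply(beta, .normalize_beta_code, character(1L), USE.NAMES = FALSE)
  modifiers <- modifiers[modifiers > 0L]
  if (length(modifiers) > 0L) {
    if (is.null(names(modifiers)) || any(!nzchar(names(modifiers))))
      stop("modifiers must be a named vector")
    bad <- setdiff(names(modifiers), MODIFIER_LOCI)
    if (length(bad) > 0L) stop("unknown modifier locus: ", paste(bad, collapse = ", "))
    if (anyDuplicated(names(modifiers)))
      stop("modifier loci must be unique within a profile")
    if (any(modifiers < 0L | modifiers > 2L)) stop("modifier dose must be 0, 1 or 2")
    if (!is.na(modifiers["alpha_dc_coinherited"]) &&
        modifiers[["alpha_dc_coinherited"]] > 1L)
      stop("alpha_dc_coinherited is a 0/1 flag")
    modifiers <- modifiers[order(match(names(modifiers), MODIFIER_LOCI))]
  }
  structure(list(alpha = alpha, beta = beta,
                 modifiers = stats::setNames(as.integer(modifiers), names(modifiers))),
            class = "genotype_profile")
}

.normalize_beta_code <- function(code) {
  x <- trimws(.normalize_shorthand(code))
  if (identical(x, "bP")) x <- "b+"   # shielded beta-plus (see parse_genotype)
  if (x %in% names(BETA_CODES)) return(x)
  # accept the long allele-class names used in the knowledge base
  long <- c(betaN = "bN", none = "bN", beta0 = "b0", beta_plus = "b+",
            betaE = "bE", betaS = "bS", beta_dominant = "bD", hpfh_del = "hpfh")
  if (x %in% names(long)) return(unname(long[x]))
  stop("unrecognized beta allele code: ", code)
}

#' Functional alpha-globin gene dosage of a profile
#'
#' Sum of the functional gene counts of the two alpha haplotypes
#' (normal `aa`/`aa` = 4; range 0-8 with triplications/quadruplications).
#'
#' @param profile a `genotype_profile`.
#' @return Integer dosage.
#' @export
functional_alpha_count <- function(profile) {
  stopifnot(inherits(profile, "genotype_profile"))
  sum(.alpha_functional(profile$alpha))
}

#' Parse genotype shorthand into a profile
#'
#' Recognizes the compact clinical notation for combined genotypes, e.g.
#' `"b0/bN, aaa/aa"`, `"(\u03b20/\u03b20) + (KLF1 M/KLF1 N)"`, or
#' `"(b0/b0) + 4 significant variants"`. The beta pair is mandatory; the
#' alpha pair defaults to `aa/aa`; `KLF1 M` terms set the KLF1 zinc-finger
#' dose (one per `M` in the slash pair); the literal term
#' `4 significant variants` expands to co-inherited alpha disease-causing
#' variation plus one HbF-raising allele at each of the XmnI, BCL11A, and
#' HMIP loci. Unicode (`\u03b2`, `\u03b1`, superscripts) and ASCII aliases
#' are interchangeable; whitespace and `^` markup are ignored.
#'
#' @param text shorthand string.
#' @return A `genotype_profile`.
#' @export
parse_genotype <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("genotype shorthand must be a non-empty string")
  x <- .normalize_shorthand(text)
  x <- gsub("[()]", "", x)
  # shield the beta-plus allele so '+' can act as the term separator
  x <- gsub("b+", "bP", x, fixed = TRUE)
  parts <- trimws(unlist(strsplit(x, "[+,]")))
  parts <- parts[nzchar(parts)]
  alpha <- NULL
  beta <- NULL
  modifiers <- stats::setNames(integer(length(MODIFIER_LOCI)), MODIFIER_LOCI)
  for (part in parts) {
    if (grepl("^4\\s*significant\\s*variants?\\*?$", part, ignore.case = TRUE)) {
      modifiers["alpha_dc_coinherited"] <- 1L
      modifiers["XmnI_rs7482144"] <- modifiers["XmnI_rs7482144"] + 1L
      modifiers["BCL11A_rs61749494"] <- modifiers["BCL11A_rs61749494"] + 1L
      modifiers["HMIP_rs11759553"] <- modifiers["HMIP_rs11759553"] + 1L
      next
    }
    toks <- trimws(unlist(strsplit(part, "/", fixed = TRUE)))
    if (length(toks) != 2L) {
      stop(sprintf("cannot parse genotype term '%s' in '%s': expected allele/allele",
                   part, text))
    }
    if (all(grepl("^KLF1\\s*[MN]$", toks))) {
      dose <- sum(grepl("M$", toks))
      modifiers["KLF1_zf"] <- modifiers["KLF1_zf"] + dose
      next
    }
    if (all(grepl("^b", toks))) {
      if (!is.null(beta))
        stop("more than one beta allele pair in genotype shorthand: ", text)
      beta <- vapply(toks, function(tk) {
        tryCatch(.normalize_beta_code(tk), error = function(e)
          stop(sprintf("unknown beta allele token '%s' in '%s'", tk, text),
               call. = FALSE))
      }, character(1L), USE.NAMES = FALSE)
      next
    }
    maybe_alpha <- tryCatch(
      vapply(toks, normalize_alpha_name, character(1L), USE.NAMES = FALSE),
      error = function(e) NULL)
    if (!is.null(maybe_alpha)) {
      if (!is.null(alpha))
        stop("more than one alpha haplotype pair in genotype shorthand: ", text)
      alpha <- maybe_alpha
      next
    }
    stop(sprintf("unknown genotype term '%s' at position %d in '%s'",
                 part, which(parts == part)[1L], text))
  }
  if (is.null(beta)) beta <- c("bN", "bN")
  if (is.null(alpha)) alpha <- c("aa", "aa")
  genotype_profile(alpha = alpha, beta = beta, modifiers = modifiers)
}

#' Render a profile back to canonical ASCII shorthand
#'
#' Inverse of [parse_genotype()] on canonical forms: the beta pair, the
#' alpha pair when not `aa/aa`, a `KLF1 M/...` term for a KLF1 zinc-finger
#' dose, and `+ 4 significant variants` when the full significant-modifier
#' combination is present.
#'
#' @param profile a `genotype_profile`.
#' @return Shorthand string.
#' @export
render_genotype <- function(profile) {
  stopifnot(inherits(profile, "genotype_profile"))
  out <- paste(profile$beta, collapse = "/")
  if (!identical(unname(profile$alpha), c("aa", "aa"))) {
    out <- paste0(out, ", ", paste(profile$alpha, collapse = "/"))
  }
  mods <- profile$modifiers
  sig <- c("alpha_dc_coinherited", "XmnI_rs7482144", "BCL11A_rs61749494",
           "HMIP_rs11759553")
  if (all(sig %in% names(mods)) && all(mods[sig] == 1L)) {
    out <- paste0(out, " + 4 significant variants")
    mods <- mods[!names(mods) %in% sig]
  }
  if (!is.na(mods["KLF1_zf"]) && mods[["KLF1_zf"]] > 0L) {
    d <- mods[["KLF1_zf"]]
    pair <- if (d == 2L) "KLF1 M/KLF1 M" else "KLF1 M/KLF1 N"
    out <- paste0(out, " + (", pair, ")")
  }
  out
}

#' Assemble a genotype profile from annotated variants
#'
#' Builds a [genotype_profile()] from knowledge-base records with
#' zygosities. Beta alleles come from HBB disease-causing records
#' (homozygous fills both alleles; two distinct heterozygous records form a
#' compound heterozygote, phase assumed trans unless `phase = "cis"` marks
#' two variants on the same chromosome); alpha haplotypes are assembled
#' from CNV/named-allele records; modifier records map to their loci by
#' rsID or KLF1 zinc-finger flag. Unfilled slots default to normal alleles.
#' Any non-`aa` alpha haplotype sets the `alpha_dc_coinherited` flag.
#'
#' @param variants data.frame with at least the knowledge-base record
#'   columns plus `zygosity` (`"het"`/`"hom"`) and optionally `phase`.
#' @return A `genotype_profile`.
#' @export
profile_from_variants <- function(variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(genotype_profile())
  stopifnot(all(c("gene", "category", "allele_class", "zygosity") %in% names(variants)))
  if (!all(variants$zygosity %in% c("het", "hom")))
    stop("zygosity must be 'het' or 'hom'")
  phase <- if ("phase" %in% names(variants)) variants$phase else rep("", nrow(variants))
  phase[is.na(phase)] <- ""

  beta <- character()
  alpha <- character()
  modifiers <- stats::setNames(integer(length(MODIFIER_LOCI)), MODIFIER_LOCI)

  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    n <- if (v$zygosity == "hom") 2L else 1L
    if (v$category == "disease_causing" && v$allele_class %in%
          c("beta0", "beta_plus", "betaE", "betaS", "beta_dominant", "hpfh_del")) {
      code <- .normalize_beta_code(v$allele_class)
      if (identical(phase[i], "cis") && length(beta) > 0L) {
        # cis to the previous beta variant: same haplotype, no new allele slot;
        # keep the more severe class on that haplotype
        next
      }
      beta <- c(beta, rep(code, n))
    } else if (v$allele_class %in% as.character(0:4)) {
      # named alpha haplotype allele (deletion, nondeletional, or multi-copy)
      name <- normalize_alpha_name(v$alt)
      if (n == 2L && length(alpha) > 0L)
        stop("inconsistent alpha genotype: homozygous CNV plus another alpha allele")
      alpha <- c(alpha, rep(name, n))
      if (n == 2L && length(alpha) > 2L)
        stop("inconsistent alpha genotype: homozygous CNV plus another alpha allele")
    } else if (v$category == "modifier") {
      locus <- .modifier_locus(v)
      modifiers[locus] <- min(2L, modifiers[locus] + n)
    }
  }
  if (length(beta) > 2L)
    stop("inconsistent beta genotype: more than 2 implied HBB alleles")
  if (length(alpha) > 2L)
    stop("inconsistent alpha genotype: more than 2 implied haplotypes")
  beta <- c(beta, rep("bN", 2L - length(beta)))
  alpha <- c(alpha, rep("aa", 2L - length(alpha)))
  # disease-causing alpha co-inheritance: any haplotype with reduced output
  if (any(.alpha_functional(alpha) < 2L)) modifiers["alpha_dc_coinherited"] <- 1L
  genotype_profile(alpha = alpha, beta = beta, modifiers = modifiers)
}

.modifier_locus <- function(record) {
  if (isTRUE(record$klf1_zinc_finger)) return("KLF1_zf")
  rsid <- if ("rsid" %in% names(record)) record$rsid else ""
  switch(rsid,
         rs7482144 = "XmnI_rs7482144",
         rs61749494 = "BCL11A_rs61749494",
         rs11759553 = "HMIP_rs11759553",
         "other")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("Genotype profile:", render_genotype(x), "\n")
  cat("  functional alpha genes:", functional_alpha_count(x), "\n")
  if (length(x$modifiers) > 0L) {
    cat("  modifiers:",
        paste(sprintf("%s=%d", names(x$modifiers), x$modifiers), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
format.genotype_profile <- function(x, ...) render_genotype(x)
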