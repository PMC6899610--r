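# Shared helpers: in-code fixtures and independent oracles.

# minimal valid KB record as a one-row data.frame; fields overridable
kb_record <- function(...) {
  rec <- data.frame(
    variant_id = "v1", gene = "HBB", hgvs = "HBB:c.52A>T", rsid = "",
    chrom = "11", pos = 5248158L, ref = "A", alt = "T",
    category = "disease_causing", acmg_class = "pathogenic",
    phenotype_class = "thalassemia", allele_class = "beta0",
    modifier_effect = "none", klf1_zinc_finger = FALSE,
    screening_relevant = TRUE, source = "test",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# draw a random profile from the shorthand grammar (canonical forms only)
random_grammar_profile <- function() {
  beta <- sample(c("bN", "b0", "b+", "bE", "bS"), 2L, replace = TRUE)
  alpha <- sample(c("aa", "-a3.7", "--SEA", "aaa", "aaaa", "aCSa"), 2L,
                  replace = TRUE)
  mods <- c(KLF1_zf = sample(0:2, 1L))
  if (stats::runif(1L) < 0.3) {
    mods <- c(mods, alpha_dc_coinherited = 1L, XmnI_rs7482144 = 1L,
              BCL11A_rs61749494 = 1L, HMIP_rs11759553 = 1L)
  }
  genotype_profile(alpha = alpha, beta = beta, modifiers = mods)
}

# canonical key of a genotype (order-free), independent of package internals
profile_key <- function(alpha, beta, doses) {
  doses <- doses[doses > 0L]
  if (length(doses)) doses <- doses[order(names(doses))]
  paste(paste(sort(alpha), collapse = "/"), paste(sort(beta), collapse = "/"),
        paste(sprintf("%s=%d", names(doses), doses), collapse = ","),
        sep = " ; ")
}

# brute-force offspring distribution: exhaustive enumeration of all
# 2^L x 2^L equally likely gamete pairings (modifier doses expanded to
# two 0/1 allele slots)
brute_force_offspring <- function(p1, p2) {
  expand_parent <- function(p) {
    loci <- list(alpha = p$alpha, beta = p$beta)
    for (l in names(p$modifiers)) {
      d <- p$modifiers[[l]]
      loci[[l]] <- c(rep(1L, d), rep(0L, 2L - d))
    }
    loci
  }
  l1 <- expand_parent(p1)
  l2 <- expand_parent(p2)
  loci <- union(names(l1), names(l2))
  for (l in loci) {
    if (is.null(l1[[l]])) l1[[l]] <- c(0L, 0L)
    if (is.null(l2[[l]])) l2[[l]] <- c(0L, 0L)
  }
  L <- length(loci)
  picks <- expand.grid(rep(list(1:2), 2L * L))
  out <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(picks))) {
    g1 <- lapply(seq_len(L), function(i) l1[[loci[i]]][picks[r, i][[1L]]])
    g2 <- lapply(seq_len(L), function(i) l2[[loci[i]]][picks[r, L + i][[1L]]])
    alpha <- c(g1[[1L]], g2[[1L]])
    beta <- c(g1[[2L]], g2[[2L]])
    doses <- integer(0)
    if (L > 2L) {
      doses <- vapply(3:L, function(i) g1[[i]] + g2[[i]], integer(1L))
      names(doses) <- loci[3:L]
      if ("alpha_dc_coinherited" %in% names(doses))
        doses["alpha_dc_coinherited"] <- min(1L, doses[["alpha_dc_coinherited"]])
    }
    key <- profile_key(alpha, beta, doses)
    prev <- if (!is.null(out[[key]])) out[[key]] else 0
    out[[key]] <- prev + 1 / nrow(picks)
  }
  keys <- sort(ls(out))
  stats::setNames(vapply(keys, function(k) out[[k]], numeric(1L)), keys)
}

# permutation p-value for the difference of group means (oracle for the
# parametric carrier test); exact when the number of carrier subsets is
# small, Monte-Carlo otherwise
permutation_p <- function(x, y, n_draws = 1e5) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  if (choose(n, n1) <= 2e4) {
    idx <- utils::combn(n, n1)
    stats <- apply(idx, 2L, function(i)
      abs(mean(pooled[i]) - mean(pooled[-i])))
    return(mean(stats >= obs - 1e-12))
  }
  stats <- replicate(n_draws, {
    i <- sample.int(n, n1)
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  (sum(stats >= obs - 1e-12) + 1) / (n_draws + 1)
}
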