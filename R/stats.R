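# Mutational spectrum, Ts/Tv, divergence dating, error rate, and the
# chromosomal-uniformity scan.

PURINES <- c("A", "G")
SPECTRUM_CLASSES <- c("G:C->A:T", "G:C->T:A", "G:C->C:G",
                      "A:T->G:C", "A:T->T:A", "A:T->C:G")

is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else is a transversion. With
#' zero transversions the ratio is reported as `Inf`.
#'
#' @param snps `variant_calls` restricted (internally) to `vtype == "snp"`.
#' @param subset optional derived-lineage filter (`"N2"` or `"LSJ1"`),
#'   applied to the `derived_lineage` column from [polarize_variants()].
#' @return list with `ts`, `tv`, `ratio`.
#' @export
ts_tv <- function(snps, subset = NULL) {
  snps <- snps[snps$vtype == "snp", , drop = FALSE]
  if (!is.null(subset))
    snps <- snps[!is.na(snps$derived_lineage) &
                   snps$derived_lineage == subset, , drop = FALSE]
  ts <- sum(is_transition(snps$ref_allele, snps$alt_allele))
  tv <- nrow(snps) - ts
  list(ts = ts, tv = tv, ratio = if (tv == 0) Inf else ts / tv)
}

# Strand-collapsed 6-class label for an ancestral -> derived substitution.
spectrum_class <- function(anc, der) {
  flip <- anc %in% c("C", "T")
  a <- ifelse(flip, chartr("ACGT", "TGCA", anc), anc)
  d <- ifelse(flip, chartr("ACGT", "TGCA", der), der)
  ifelse(a == "G", paste0("G:C->", d, ":", chartr("ACGT", "TGCA", d)),
         paste0("A:T->", d, ":", chartr("ACGT", "TGCA", d)))
}

#' Strand-collapsed substitution spectrum
#'
#' Each polarized SNP is assigned its ancestral->derived class, collapsed to
#' the six strand-symmetric classes. Per-lineage columns cover only
#' polarized SNPs; the `overall` column additionally counts
#' unknown-polarity SNPs via the reference->focal direction (the only
#' orientation available without an ancestral call).
#'
#' @param snps polarized SNP `variant_calls` (needs `ancestral` and
#'   `derived_lineage` columns; rows with other vtypes are ignored).
#' @return a `data.frame` with one row per class and columns `overall`,
#'   `derived_in_N2`, `derived_in_LSJ1`.
#' @export
substitution_spectrum <- function(snps) {
  snps <- snps[snps$vtype == "snp", , drop = FALSE]
  known <- !is.na(snps$ancestral) & snps$ancestral != "unknown"
  # ancestral allele: ref_allele carries the reference-lineage (N2) base
  anc <- ifelse(snps$ancestral == "N2", snps$ref_allele, snps$alt_allele)
  der <- ifelse(snps$ancestral == "N2", snps$alt_allele, snps$ref_allele)
  cls <- character(nrow(snps))
  cls[known] <- spectrum_class(anc[known], der[known])
  cls[!known] <- spectrum_class(snps$ref_allele[!known],
                                snps$alt_allele[!known])
  tab <- function(idx) {
    t0 <- table(factor(cls[idx], levels = SPECTRUM_CLASSES))
    as.integer(t0)
  }
  data.frame(
    class = SPECTRUM_CLASSES,
    overall = tab(rep(TRUE, length(cls))),
    derived_in_N2 = tab(known & snps$derived_lineage == "N2"),
    derived_in_LSJ1 = tab(known & snps$derived_lineage == "LSJ1"),
    stringsAsFactors = FALSE)
}

#' Generations of separation from the SNP count
#'
#' Two lineages accumulate substitutions independently, so `S` observed SNPs
#' imply `t = S / (2 * mu * L)` generations since their separation.
#'
#' @param S observed SNP count between the lineages.
#' @param mu per-bp per-generation substitution rate (default 2.7e-9, the
#'   mutation-accumulation-line estimate).
#' @param L genome length in bp.
#' @return estimated generations `t`.
#' @export
divergence_generations <- function(S, mu = 2.7e-9, L) {
  stopifnot(S >= 0, mu > 0, L > 0)
  S / (2 * mu * L)
}

#' Expected SNP accumulation in a single lineage
#'
#' @inheritParams divergence_generations
#' @param t generations of cultivation.
#' @return expected SNP count `mu * L * t`.
#' @export
expected_snps <- function(mu = 2.7e-9, L, t) {
  stopifnot(mu > 0, L > 0, t >= 0)
  mu * L * t
}

#' Convert generations to years
#'
#' @param t generations.
#' @param g generation time in days (default 4).
#' @return years (365.25-day years).
#' @export
separation_years <- function(t, g = 4) {
  stopifnot(t >= 0, g > 0)
  t * g / 365.25
}

#' Reference error rate as one-in-X bp
#'
#' @param L genome length in bp.
#' @param n_errors number of detected reference errors.
#' @return `L / n_errors` (one error every X bp); `Inf` when `n_errors` is 0.
#' @export
reference_error_rate <- function(L, n_errors) {
  stopifnot(L > 0, n_errors >= 0)
  if (n_errors == 0) Inf else L / n_errors
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation (the test suite checks it against a brute-force
#' step-up enumeration): adjusted value for the i-th smallest p is
#' `min_{j >= i} p_(j) * m / j`, capped at 1; rejections at level `q` are
#' all hypotheses up to the largest i with `p_(i) <= i*q/m`.
#'
#' @param pvalues numeric vector of p-values.
#' @param q target false-discovery rate (default 0.05).
#' @return list with `qvalues` (in input order) and `reject` (logical).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  m <- length(pvalues)
  if (m == 0) return(list(qvalues = numeric(), reject = logical()))
  o <- order(pvalues)
  adj <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  qvalues <- numeric(m)
  qvalues[o] <- adj
  ok <- which(pvalues[o] <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  list(qvalues = qvalues, reject = reject)
}

#' Kolmogorov-Smirnov uniformity scan of variant positions
#'
#' Per chromosome, tests whether variant positions (scaled by chromosome
#' length) are uniform, with Benjamini-Hochberg adjustment across
#' chromosomes. The direction of the ECDF deviation is reported
#' descriptively (positive = excess density toward the chromosome ends
#' relative to uniform at the point of maximal deviation).
#'
#' @param variants a `variant_calls` data frame (any vtype).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param q FDR level for the rejection set (default 0.05).
#' @param exact_below sample size under which the exact K-S null is used
#'   instead of the asymptotic one (default 30).
#' @return data frame with one row per tested chromosome: `chrom`, `n`,
#'   `length`, `density`, `D`, `p`, `qvalue`, `reject`.
#' @export
ks_uniformity_scan <- function(variants, chrom_lengths, q = 0.05,
                               exact_below = 30L) {
  rows <- lapply(names(chrom_lengths), function(ch) {
    pos <- variants$pos[variants$chrom == ch]
    if (length(pos) == 0) {
      warning("chromosome ", ch, " has no variants; skipped")
      return(NULL)
    }
    u <- pos / chrom_lengths[[ch]]
    kt <- suppressWarnings(
      ks.test(u, "punif", exact = length(u) < exact_below))
    # descriptive ECDF deviation sign at the point of maximal deviation:
    # +1 = variant excess before that point (left-shifted mass), -1 = deficit
    us <- sort(u); n <- length(us)
    dev_hi <- seq_len(n) / n - us
    dev_lo <- us - (seq_len(n) - 1) / n
    sgn <- if (max(dev_hi) >= max(dev_lo)) 1L else -1L
    data.frame(chrom = ch, n = n,
               length = unname(chrom_lengths[[ch]]),
               density = n / chrom_lengths[[ch]],
               D = unname(kt$statistic), p = kt$p.value,
               deviation_sign = sgn,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no chromosome had any variants")
  adj <- bh_fdr(res$p, q)
  res$qvalue <- adj$qvalues
  res$reject <- adj$reject
  rownames(res) <- NULL
  res
}

#' Assemble the headline summary statistics for a pipeline run
#'
#' @param polymorphisms polarized polymorphism `variant_calls`.
#' @param n_errors number of reference errors detected.
#' @param L genome length in bp.
#' @param mu per-bp per-generation substitution rate.
#' @param g generation time in days.
#' @return list with SNP/indel counts, Ts/Tv (overall and per derived
#'   lineage), polarization summary, divergence generations and years,
#'   reference error rate, and polymorphism densities under both published
#'   denominators (retained small changes, and small plus large changes).
#' @export
summary_report <- function(polymorphisms, n_errors, L, mu = 2.7e-9, g = 4) {
  S <- sum(polymorphisms$vtype == "snp")
  t_hat <- divergence_generations(S, mu, L)
  list(
    n_snps = S,
    n_indels = sum(polymorphisms$vtype != "snp"),
    ts_tv_overall = ts_tv(polymorphisms)$ratio,
    ts_tv_derived_N2 = if ("derived_lineage" %in% names(polymorphisms))
      ts_tv(polymorphisms, "N2")$ratio else NA,
    ts_tv_derived_LSJ1 = if ("derived_lineage" %in% names(polymorphisms))
      ts_tv(polymorphisms, "LSJ1")$ratio else NA,
    polarization = if ("ancestral" %in% names(polymorphisms))
      summarize_polarization(polymorphisms) else NULL,
    t_generations = t_hat,
    years = separation_years(t_hat, g),
    error_one_in_bp = reference_error_rate(L, n_errors),
    bp_per_polymorphism = L / max(1L, nrow(polymorphisms)))
}
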