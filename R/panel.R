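# Panel-vote reference-error classification.
#
# A candidate focal-vs-reference difference is called a REFERENCE ERROR when
# at least k of the n independently resequenced reference-lineage panel
# strains carry the focal strain's allele: the reference disagreeing with
# nearly everyone is evidence against the reference, not for n independent
# mutations. Panel strains with no informative coverage at a site can never
# vote for an error (they might merely have poor coverage, not the reference
# allele).

#' Panel-vote configuration
#'
#' @param k minimum number of panel strains carrying the focal allele to call
#'   a reference error (default 4).
#' @param n panel size (default 6).
#' @param vote_denominator `"panel"` (default; k is an absolute count) or
#'   `"observed"` (k is rescaled by the fraction of strains with informative
#'   coverage: `ceiling(k * observed / n)`).
#' @return a list of class `"panel_config"`.
#' @export
panel_config <- function(k = 4L, n = 6L,
                         vote_denominator = c("panel", "observed")) {
  k <- as.integer(k); n <- as.integer(n)
  stopifnot(k >= 1L, k <= n)
  structure(list(k = k, n = n,
                 vote_denominator = match.arg(vote_denominator)),
            class = "panel_config")
}

#' Classify one site from panel genotype observations
#'
#' @param observations data frame with columns `strain` and `allele`; allele
#'   is one of `"reference_like"`, `"focal_like"`, `"missing"`. `missing`
#'   never counts toward the error vote.
#' @param config a [panel_config()].
#' @return list with `status` (`"reference_error"` or `"polymorphism"`),
#'   `support_count`, and `missing_count`.
#' @export
classify_site <- function(observations, config = panel_config()) {
  stopifnot(all(observations$allele %in%
                  c("reference_like", "focal_like", "missing")))
  if (anyDuplicated(observations$strain))
    stop("duplicate panel strain in observations")
  if (nrow(observations) > config$n)
    stop("more observations than panel size n")
  support <- sum(observations$allele == "focal_like")
  missing <- sum(observations$allele == "missing")
  k_eff <- if (config$vote_denominator == "observed") {
    observed <- nrow(observations) - missing
    if (observed == 0L) Inf else ceiling(config$k * observed / config$n)
  } else config$k
  list(status = if (support >= k_eff) "reference_error" else "polymorphism",
       support_count = support, missing_count = missing)
}

# Panel observations for a set of candidate sites. `panel` is a named list
# of per-strain variant_calls (from read_vcf). A strain is focal_like at a
# site iff it carries a record with the exact same (chrom,pos,type,alleles)
# key and a called genotype; a "./." no-call record at the position means
# missing coverage; no record means reference_like.
panel_observations <- function(calls, panel) {
  keys <- variant_key(calls)
  pos_keys <- paste(calls$chrom, calls$pos, sep = "\r")
  support <- missing <- integer(nrow(calls))
  for (strain in names(panel)) {
    pc <- panel[[strain]]
    nocall <- !is.na(pc$gt) & pc$gt == "./."
    hit <- keys %in% variant_key(pc[!nocall, , drop = FALSE])
    miss <- !hit & pos_keys %in%
      paste(pc$chrom[nocall], pc$pos[nocall], sep = "\r")
    if (!any(hit | miss))
      warning("panel strain ", strain,
              " shares no site with the focal calls (suspicious input)")
    support <- support + hit
    missing <- missing + miss
  }
  data.frame(support_count = support, missing_count = missing)
}

#' Partition focal calls into reference errors and true polymorphisms
#'
#' Applies the panel vote of [classify_site()] to every candidate call.
#' Totals are conserved: every input call appears in exactly one of the two
#' output tables.
#'
#' @param calls quality-filtered focal-strain `variant_calls`.
#' @param panel named list of per-strain `variant_calls` for the resequenced
#'   reference-lineage panel (see [read_vcf()]); a `"./."` genotype record
#'   marks assayed-but-missing coverage.
#' @param config a [panel_config()].
#' @return list with `errors` and `polymorphisms`, each a `variant_calls`
#'   data frame with added `support_count`, `missing_count`, `status`.
#' @export
partition_variants <- function(calls, panel, config = panel_config()) {
  if (length(panel) > config$n)
    stop("panel has more strains than config n")
  obs <- panel_observations(calls, panel)
  calls$support_count <- obs$support_count
  calls$missing_count <- obs$missing_count
  k_eff <- if (config$vote_denominator == "observed") {
    observed <- length(panel) - obs$missing_count
    ifelse(observed == 0L, Inf, ceiling(config$k * observed / config$n))
  } else config$k
  is_err <- calls$support_count >= k_eff
  calls$status <- ifelse(is_err, "reference_error", "polymorphism")
  errors <- calls[is_err, , drop = FALSE]
  polymorphisms <- calls[!is_err, , drop = FALSE]
  rownames(errors) <- rownames(polymorphisms) <- NULL
  class(errors) <- class(polymorphisms) <- c("variant_calls", "data.frame")
  list(errors = errors, polymorphisms = polymorphisms)
}
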