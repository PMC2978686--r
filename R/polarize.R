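# Ancestral-allele polarization by outgroup concordance.
#
# Whichever of the two sibling-lineage alleles is carried by BOTH wild
# outgroup isolates is taken as ancestral in the common founder; the
# mutation then arose in the other lineage. Discordant outgroups, a missing
# outgroup call (under the default strict two-witness rule), or an outgroup
# allele matching neither lineage allele all yield an unknown ancestral
# state.

ANCESTRAL_STATES <- c("ancestral_N2", "ancestral_LSJ1", "unknown")

#' Infer the ancestral allele at one polymorphic site
#'
#' @param outgroup_obs character vector of length 2 with the two outgroup
#'   observations, each one of `"reference_like"` (outgroup carries the
#'   reference-lineage allele), `"focal_like"` (carries the focal-strain
#'   allele), `"missing"`, or `"third_allele"`.
#' @param permissive if `TRUE`, a single informative outgroup decides when
#'   the other is missing (off by default: the rule requires presence in
#'   both outgroups).
#' @return list with `state` (`"ancestral_N2"`, `"ancestral_LSJ1"`,
#'   `"unknown"`), `derived_lineage` (`"LSJ1"`, `"N2"`, `"unknown"`),
#'   `discordant` and `third_allele` flags.
#' @export
infer_ancestral <- function(outgroup_obs, permissive = FALSE) {
  stopifnot(length(outgroup_obs) == 2L,
            all(outgroup_obs %in% c("reference_like", "focal_like",
                                    "missing", "third_allele")))
  third <- any(outgroup_obs == "third_allele")
  n_ref <- sum(outgroup_obs == "reference_like")
  n_foc <- sum(outgroup_obs == "focal_like")
  discordant <- n_ref == 1L && n_foc == 1L
  state <- "unknown"
  if (!third) {
    if (n_ref == 2L || (permissive && n_ref == 1L && n_foc == 0L))
      state <- "ancestral_N2"
    if (n_foc == 2L || (permissive && n_foc == 1L && n_ref == 0L))
      state <- "ancestral_LSJ1"
  }
  derived <- switch(state, ancestral_N2 = "LSJ1", ancestral_LSJ1 = "N2",
                    unknown = "unknown")
  list(state = state, derived_lineage = derived, discordant = discordant,
       third_allele = third)
}

# Observation of one outgroup strain at each candidate site, from its
# per-strain call set. A record matching the focal variant key => the
# outgroup carries the focal allele; a "./." no-call record => missing; a
# conflicting record at the same position => third allele; no record => the
# outgroup matches the reference-lineage allele.
outgroup_observations <- function(calls, outgroup_calls) {
  keys <- variant_key(calls)
  pos_keys <- paste(calls$chrom, calls$pos, sep = "\r")
  nocall <- !is.na(outgroup_calls$gt) & outgroup_calls$gt == "./."
  called <- outgroup_calls[!nocall, , drop = FALSE]
  hit <- keys %in% variant_key(called)
  miss <- pos_keys %in% paste(outgroup_calls$chrom[nocall],
                              outgroup_calls$pos[nocall], sep = "\r")
  other <- pos_keys %in% paste(called$chrom, called$pos, sep = "\r") & !hit
  ifelse(hit, "focal_like",
         ifelse(other, "third_allele",
                ifelse(miss, "missing", "reference_like")))
}

#' Polarize a table of polymorphisms with two outgroup call sets
#'
#' @param polymorphisms `variant_calls` retained as true lineage differences.
#' @param outgroup1,outgroup2 per-strain `variant_calls` for the two wild
#'   outgroups (e.g. read from their VCFs).
#' @param permissive see [infer_ancestral()].
#' @return `polymorphisms` with added columns `ancestral` (`"N2"`, `"LSJ1"`,
#'   `"unknown"` -- the published table vocabulary), `derived_lineage`,
#'   `discordant`, `third_allele`.
#' @export
polarize_variants <- function(polymorphisms, outgroup1, outgroup2,
                              permissive = FALSE) {
  o1 <- outgroup_observations(polymorphisms, outgroup1)
  o2 <- outgroup_observations(polymorphisms, outgroup2)
  res <- lapply(seq_len(nrow(polymorphisms)), function(j)
    infer_ancestral(c(o1[j], o2[j]), permissive = permissive))
  state <- vapply(res, `[[`, character(1), "state")
  polymorphisms$ancestral <- c(ancestral_N2 = "N2", ancestral_LSJ1 = "LSJ1",
                               unknown = "unknown")[state]
  polymorphisms$derived_lineage <-
    vapply(res, `[[`, character(1), "derived_lineage")
  polymorphisms$discordant <- vapply(res, `[[`, logical(1), "discordant")
  polymorphisms$third_allele <- vapply(res, `[[`, logical(1), "third_allele")
  class(polymorphisms) <- c("variant_calls", "data.frame")
  polymorphisms
}

#' Summarize polarization results
#'
#' Counts and percentages per ancestral state. All denominators are reported
#' explicitly: percentages are given over all polymorphisms and over the
#' polarized (non-unknown) subset.
#'
#' @param polarized output of [polarize_variants()] (or any data frame with
#'   an `ancestral` column over `N2`/`LSJ1`/`unknown`).
#' @return list with `counts` (named: ancestral_N2, ancestral_LSJ1, unknown,
#'   discordant), `total`, `pct_of_total`, `pct_of_known`.
#' @export
summarize_polarization <- function(polarized) {
  a <- polarized$ancestral
  counts <- c(ancestral_N2 = sum(a == "N2"),
              ancestral_LSJ1 = sum(a == "LSJ1"),
              unknown = sum(a == "unknown"))
  disc <- if ("discordant" %in% names(polarized))
    sum(polarized$discordant) else NA_integer_
  total <- length(a)
  known <- counts[["ancestral_N2"]] + counts[["ancestral_LSJ1"]]
  list(counts = counts, discordant = disc, total = total,
       pct_of_total = if (total) 100 * counts / total else counts * NA,
       pct_of_known = if (known) 100 * counts[1:2] / known else
         counts[1:2] * NA)
}
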