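# Call-level quality / ambiguity filters.
#
# Boundary semantics are deliberate and exact: SNPs and small indels are
# discarded when quality is strictly BELOW the threshold (so a small indel at
# exactly 25 is kept); large insertions are kept only when quality is
# strictly ABOVE the large-insertion threshold (so exactly 35 is discarded);
# large deletions are always analysed.

#' Filter configuration
#'
#' @param q_snp_min SNP quality threshold; calls with quality strictly below
#'   it are discarded (default 50).
#' @param q_small_indel_min small-indel threshold, strict-below discard
#'   (default 25).
#' @param q_large_ins_min large-insertion threshold; kept only strictly above
#'   (default 35). Large deletions are never quality-filtered.
#' @param drop_ambiguous discard calls the aligner flagged as ambiguously
#'   placed (default `TRUE`, applied to every variant type).
#' @return a list of class `"filter_config"`.
#' @export
filter_config <- function(q_snp_min = 50, q_small_indel_min = 25,
                          q_large_ins_min = 35, drop_ambiguous = TRUE) {
  stopifnot(q_snp_min >= 0, q_small_indel_min >= 0, q_large_ins_min >= 0,
            is.logical(drop_ambiguous))
  structure(list(q_snp_min = q_snp_min,
                 q_small_indel_min = q_small_indel_min,
                 q_large_ins_min = q_large_ins_min,
                 drop_ambiguous = drop_ambiguous),
            class = "filter_config")
}

partition_calls <- function(calls, drop, reason) {
  kept <- calls[!drop, , drop = FALSE]
  discarded <- calls[drop, , drop = FALSE]
  discarded$reason <- reason[drop]
  rownames(kept) <- rownames(discarded) <- NULL
  class(kept) <- class(discarded) <- c("variant_calls", "data.frame")
  list(kept = kept, discarded = discarded)
}

#' Quality/ambiguity filter for SNPs and small indels
#'
#' Pure partition: every input call ends up in exactly one of `kept` or
#' `discarded`; discards carry a `reason` of `"low_quality"` or
#' `"ambiguous"`. Large-indel calls pass through untouched (see
#' [apply_large_indel_filter()]).
#'
#' @param calls a `variant_calls` data frame.
#' @param config a [filter_config()].
#' @return list with elements `kept` and `discarded`.
#' @export
apply_quality_filter <- function(calls, config = filter_config()) {
  thr <- ifelse(calls$vtype == "snp", config$q_snp_min,
                ifelse(calls$vtype %in% c("small_ins", "small_del"),
                       config$q_small_indel_min, 0))
  low <- calls$quality < thr
  amb <- config$drop_ambiguous & calls$ambiguous &
    calls$vtype %in% c("snp", "small_ins", "small_del")
  reason <- ifelse(low, "low_quality", ifelse(amb, "ambiguous", NA))
  partition_calls(calls, low | amb, reason)
}

#' Retention filter for large indels
#'
#' All large deletions are kept for analysis; large insertions are kept only
#' with quality strictly above the threshold. SNP/small-indel calls pass
#' through untouched.
#'
#' @inheritParams apply_quality_filter
#' @return list with elements `kept` and `discarded`.
#' @export
apply_large_indel_filter <- function(calls, config = filter_config()) {
  low <- calls$vtype == "large_ins" & calls$quality <= config$q_large_ins_min
  amb <- config$drop_ambiguous & calls$ambiguous &
    calls$vtype %in% c("large_ins", "large_del")
  reason <- ifelse(low, "low_quality", ifelse(amb, "ambiguous", NA))
  partition_calls(calls, low | amb, reason)
}

#' Apply both filter stages
#'
#' @inheritParams apply_quality_filter
#' @return list with `kept` and `discarded` (reasons retained).
#' @export
apply_filters <- function(calls, config = filter_config()) {
  a <- apply_quality_filter(calls, config)
  b <- apply_large_indel_filter(a$kept, config)
  disc <- rbind(a$discarded, b$discarded)
  rownames(disc) <- NULL
  list(kept = b$kept, discarded = disc)
}
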