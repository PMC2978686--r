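# Coding-consequence annotation.
#
# Effects are computed by codon arithmetic on the spliced CDS; an
# independent brute-force route (mutate the genome, re-extract, re-translate)
# lives in the test suite as the oracle.

# inframe_multi_aa extends the published category set: only large (>=6 bp)
# in-frame CDS indels can reach it, and the paper's small-indel tables never
# can (small indels are 1-3 bp).
EFFECT_SEVERITY <- c("stop_gained", "stop_lost", "frameshift",
                     "inframe_single_aa", "inframe_multi_aa",
                     "nonsynonymous", "pseudogene_hit",
                     "utr", "synonymous", "intronic", "intergenic")

CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(CODON_TABLE[codons]), collapse = "")
}

#' Build the spliced coding sequence and its coordinate map
#'
#' Concatenates CDS exons 5' to 3' (reverse-complementing minus-strand
#' genes) and returns, alongside the sequence, the bijective map from CDS
#' position to genomic position.
#'
#' @param gene a [gene_model()].
#' @param genome a `"genome"` object.
#' @return list with `seq` (CDS as a string, 5' to 3') and `map` (integer
#'   vector: `map[i]` is the genomic position of CDS base `i`).
#' @export
build_cds <- function(gene, genome) {
  chrom_len <- nchar(genome$sequences[[gene$chrom]])
  if (is.null(chrom_len) || length(chrom_len) == 0)
    stop("chromosome ", gene$chrom, " not in genome")
  if (any(gene$cds_exons$start < 1L) || any(gene$cds_exons$end > chrom_len))
    stop("CDS interval outside chromosome bounds for ", gene$transcript_id)
  pieces <- substring(genome$sequences[[gene$chrom]],
                      gene$cds_exons$start, gene$cds_exons$end)
  seq_plus <- paste(pieces, collapse = "")
  map_plus <- unlist(Map(seq, gene$cds_exons$start, gene$cds_exons$end),
                     use.names = FALSE)
  if (gene$strand == "+") list(seq = seq_plus, map = as.integer(map_plus))
  else list(seq = revcomp(seq_plus), map = rev(as.integer(map_plus)))
}

in_intervals <- function(pos, iv) {
  nrow(iv) > 0 && any(pos >= iv$start & pos <= iv$end)
}

gene_span <- function(gene) {
  iv <- rbind(gene$cds_exons, gene$utr_exons)
  c(min(iv$start), max(iv$end))
}

coding_effect <- function(category, gene = NULL, codon_change = NULL,
                          boundary = FALSE) {
  list(category = category,
       gene_id = if (is.null(gene)) NA_character_ else gene$gene_id,
       transcript_id = if (is.null(gene)) NA_character_ else
         gene$transcript_id,
       codon_change = codon_change, boundary = boundary)
}

most_severe <- function(effects) {
  if (length(effects) == 0) return(coding_effect("intergenic"))
  sev <- match(vapply(effects, `[[`, character(1), "category"),
               EFFECT_SEVERITY)
  effects[[which.min(sev)]]
}

classify_snp_one <- function(call, gene, genome) {
  span <- gene_span(gene)
  if (call$pos < span[1] || call$pos > span[2]) return(NULL)
  if (!in_intervals(call$pos, gene$cds_exons)) {
    if (in_intervals(call$pos, gene$utr_exons))
      return(coding_effect("utr", gene))
    return(coding_effect("intronic", gene))
  }
  if (gene$biotype == "pseudogene")
    return(coding_effect("pseudogene_hit", gene))
  cds <- build_cds(gene, genome)
  if (genome_base(genome, call$chrom, call$pos) != call$ref_allele)
    stop(sprintf("ref allele mismatch at %s:%d (genome %s, call %s)",
                 call$chrom, call$pos,
                 genome_base(genome, call$chrom, call$pos),
                 call$ref_allele))
  cpos <- match(call$pos, cds$map)
  alt <- if (gene$strand == "+") call$alt_allele else revcomp(call$alt_allele)
  ci <- (cpos - 1L) %/% 3L + 1L
  off <- (cpos - 1L) %% 3L + 1L
  ref_codon <- substr(cds$seq, 3L * ci - 2L, 3L * ci)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt
  ref_aa <- unname(CODON_TABLE[ref_codon])
  alt_aa <- unname(CODON_TABLE[alt_codon])
  cat_ <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "nonsynonymous"
  coding_effect(cat_, gene,
                codon_change = list(ref_codon = ref_codon,
                                    alt_codon = alt_codon, aa_pos = ci))
}

#' Classify the coding effect of a SNP
#'
#' Maps a single-nucleotide variant onto all overlapping gene models and
#' returns the most severe consequence (severity order: stop_gained >
#' stop_lost > frameshift > inframe_single_aa > nonsynonymous >
#' pseudogene_hit > utr > synonymous > intronic > intergenic).
#'
#' @param call one-row `variant_calls` with `vtype == "snp"`.
#' @param genes list of [gene_model()]s.
#' @param genome a `"genome"` object; the call's ref allele must match the
#'   genome base at its position (anything else is an input inconsistency
#'   and raises an error).
#' @return a coding-effect list: `category`, `gene_id`, `transcript_id`,
#'   `codon_change` (ref/alt codon and amino-acid position, when coding).
#' @export
classify_snp_effect <- function(call, genes, genome) {
  stopifnot(call$vtype == "snp")
  effs <- Filter(Negate(is.null),
                 lapply(genes, function(g)
                   if (g$chrom == call$chrom)
                     classify_snp_one(call, g, genome)))
  most_severe(effs)
}

classify_indel_one <- function(call, gene, genome) {
  span <- gene_span(gene)
  is_del <- call$vtype %in% c("small_del", "large_del")
  # bases touched, in the table dialect: deletions delete pos..pos+len-1;
  # insertions land in the gap between pos and pos+1
  lo <- call$pos; hi <- if (is_del) call$pos + call$length - 1L else
    call$pos + 1L
  if (hi < span[1] || lo > span[2]) return(NULL)
  iv <- gene$cds_exons
  if (is_del) {
    hit <- iv$start <= hi & iv$end >= lo
    if (!any(hit)) {
      if (in_intervals(lo, gene$utr_exons) || in_intervals(hi, gene$utr_exons))
        return(coding_effect("utr", gene))
      return(coding_effect("intronic", gene))
    }
    if (gene$biotype == "pseudogene")
      return(coding_effect("pseudogene_hit", gene))
    ov <- sum(pmin(iv$end[hit], hi) - pmax(iv$start[hit], lo) + 1L)
    boundary <- ov < call$length || sum(hit) > 1L
    if (boundary)
      return(coding_effect("frameshift", gene, boundary = TRUE))
    if (call$length %% 3L != 0L)
      return(coding_effect("frameshift", gene))
    if (call$length == 3L) return(coding_effect("inframe_single_aa", gene))
    return(coding_effect("inframe_multi_aa", gene))
  }
  # insertion: coding only if the gap lies strictly inside a CDS exon
  inside <- any(iv$start <= lo & iv$end > lo)
  if (!inside) {
    if (any(gene$utr_exons$start <= lo & gene$utr_exons$end > lo))
      return(coding_effect("utr", gene))
    return(coding_effect("intronic", gene))
  }
  if (gene$biotype == "pseudogene")
    return(coding_effect("pseudogene_hit", gene))
  if (call$length %% 3L != 0L) return(coding_effect("frameshift", gene))
  if (call$length == 3L) return(coding_effect("inframe_single_aa", gene))
  coding_effect("inframe_multi_aa", gene)
}

#' Classify the coding effect of an insertion or deletion
#'
#' Within a protein-coding CDS, an indel whose length is not a multiple of 3
#' is a frameshift; a 3-bp indel alters, adds, or removes a single amino
#' acid (`inframe_single_aa`); any indel in a gene annotated as a pseudogene
#' is a `pseudogene_hit`. Indels spanning an exon boundary are reported as
#' frameshift with `boundary = TRUE` (splice-consequence modelling is out of
#' scope).
#'
#' @inheritParams classify_snp_effect
#' @param call one-row `variant_calls` with an indel `vtype`.
#' @return a coding-effect list; see [classify_snp_effect()].
#' @export
classify_indel_effect <- function(call, genes, genome) {
  stopifnot(call$vtype %in% c("small_ins", "small_del", "large_ins",
                              "large_del"))
  effs <- Filter(Negate(is.null),
                 lapply(genes, function(g)
                   if (g$chrom == call$chrom)
                     classify_indel_one(call, g, genome)))
  most_severe(effs)
}

#' Classify coding effects for a table of variants
#'
#' @param calls a `variant_calls` data frame.
#' @param genes list of [gene_model()]s.
#' @param genome a `"genome"` object.
#' @return `calls` with added columns `effect`, `gene_id`, `transcript_id`.
#' @export
annotate_effects <- function(calls, genes, genome) {
  effs <- lapply(seq_len(nrow(calls)), function(j) {
    v <- calls[j, ]
    if (v$vtype == "snp") classify_snp_effect(v, genes, genome)
    else classify_indel_effect(v, genes, genome)
  })
  calls$effect <- vapply(effs, `[[`, character(1), "category")
  calls$gene_id <- vapply(effs, `[[`, character(1), "gene_id")
  calls$transcript_id <- vapply(effs, `[[`, character(1), "transcript_id")
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' Summarize coding-effect categories
#'
#' Per-category counts for the reference-error set and the polymorphism set
#' (the two published consequence-table shapes), plus exonic subtotals with
#' and without UTR-only variants.
#'
#' @param classified_errors,classified_polymorphisms outputs of
#'   [annotate_effects()] (either may be `NULL`).
#' @return list of two named count vectors (`errors`, `polymorphisms`), each
#'   covering every effect category, plus `exonic` counts (`cds_only` and
#'   `cds_plus_utr`).
#' @export
summarize_effects <- function(classified_errors = NULL,
                              classified_polymorphisms = NULL) {
  count_cats <- function(x) {
    out <- setNames(integer(length(EFFECT_SEVERITY)), EFFECT_SEVERITY)
    if (!is.null(x) && nrow(x)) {
      tb <- table(factor(x$effect, levels = EFFECT_SEVERITY))
      out[names(tb)] <- as.integer(tb)
    }
    out
  }
  e <- count_cats(classified_errors)
  p <- count_cats(classified_polymorphisms)
  cds_cats <- c("stop_gained", "stop_lost", "frameshift",
                "inframe_single_aa", "inframe_multi_aa", "nonsynonymous",
                "synonymous", "pseudogene_hit")
  list(errors = e, polymorphisms = p,
       exonic = list(
         errors = c(cds_only = sum(e[cds_cats]),
                    cds_plus_utr = sum(e[c(cds_cats, "utr")])),
         polymorphisms = c(cds_only = sum(p[cds_cats]),
                           cds_plus_utr = sum(p[c(cds_cats, "utr")]))))
}
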