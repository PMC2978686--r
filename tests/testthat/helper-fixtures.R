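# Fixtures are built in code; oracles here deliberately use different code
# paths (Biostrings, per-base walks, exhaustive enumeration) than the
# package internals they check.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_genome <- function(len = 600, chroms = "I") {
  domestiscan::genome(setNames(vapply(rep(len, length(chroms)),
                                      rand_seq, character(1)), chroms))
}

write_vcf_text <- function(records, file = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               records), file)
  file
}

make_call <- function(chrom, pos, ref, alt, vtype = NULL, quality = 99,
                      ambiguous = FALSE, ...) {
  variant_calls(chrom, pos, ref, alt, vtype = vtype, quality = quality,
                ambiguous = ambiguous, ...)
}

# panel observation pattern helper: bits = 0/1 focal-allele presence
obs_from_bits <- function(bits, missing = logical(length(bits))) {
  data.frame(strain = paste0("s", seq_along(bits)),
             allele = ifelse(missing, "missing",
                             ifelse(bits == 1, "focal_like",
                                    "reference_like")),
             stringsAsFactors = FALSE)
}

## ---- independent oracles ----

# per-base walk CDS extraction (vs the package's vectorized substring route)
oracle_cds <- function(gene, gnm) {
  s <- gnm$sequences[[gene$chrom]]
  out <- character(0)
  for (j in seq_len(nrow(gene$cds_exons)))
    for (p in gene$cds_exons$start[j]:gene$cds_exons$end[j])
      out <- c(out, substring(s, p, p))
  seq5to3 <- if (gene$strand == "+") out
    else rev(chartr("ACGT", "TGCA", out))
  paste(seq5to3, collapse = "")
}

oracle_translate <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

# brute-force SNP consequence: mutate the genome, re-extract, re-translate
oracle_snp_category <- function(chrom, pos, alt, gene, gnm) {
  iv_hit <- function(iv) nrow(iv) > 0 && any(pos >= iv$start & pos <= iv$end)
  span <- range(c(gene$cds_exons$start, gene$cds_exons$end,
                  gene$utr_exons$start, gene$utr_exons$end))
  if (pos < span[1] || pos > span[2]) return("intergenic")
  if (!iv_hit(gene$cds_exons)) {
    if (iv_hit(gene$utr_exons)) return("utr")
    return("intronic")
  }
  if (gene$biotype == "pseudogene") return("pseudogene_hit")
  mut <- gnm
  substr(mut$sequences[[chrom]], pos, pos) <- alt
  p_ref <- oracle_translate(oracle_cds(gene, gnm))
  p_alt <- oracle_translate(oracle_cds(gene, mut))
  if (p_ref == p_alt) return("synonymous")
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  aa_ref <- substr(p_ref, i, i); aa_alt <- substr(p_alt, i, i)
  if (aa_alt == "*") "stop_gained"
  else if (aa_ref == "*") "stop_lost"
  else "nonsynonymous"
}

# random toy gene fully inside [lo, hi] on the given strand
random_gene <- function(id, chrom, lo, hi, strand = sample(c("+", "-"), 1),
                        biotype = "protein_coding") {
  n_ex <- sample(1:3, 1)
  ex_len <- sample(seq(9L, 45L, by = 3L), n_ex, replace = TRUE)
  introns <- if (n_ex > 1) sample(10:30, n_ex - 1, replace = TRUE)
    else integer(0)
  utr5 <- sample(5:20, 1); utr3 <- sample(5:20, 1)
  span <- utr5 + sum(ex_len) + sum(introns) + utr3
  stopifnot(hi - lo + 1 >= span)
  start <- lo + sample.int(hi - lo + 2L - span, 1L) - 1L
  cds_start <- start + utr5
  starts <- cds_start + c(0L, cumsum(ex_len[-n_ex] + introns))
  gene_model(id, paste0(id, ".t1"), chrom, strand,
             data.frame(start = starts, end = starts + ex_len - 1L),
             data.frame(start = c(start, max(starts + ex_len - 1L) + 1L),
                        end = c(cds_start - 1L,
                                max(starts + ex_len - 1L) + utr3)),
             biotype)
}

# apply a left-anchored VCF record to a sequence string (the string-edit
# oracle for the coordinate-convention checks)
apply_vcf_record <- function(s, pos, ref, alt) {
  stopifnot(substr(s, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(s, 1L, pos - 1L), alt,
         substr(s, pos + nchar(ref), nchar(s)))
}

# apply a dialect call (del at pos..pos+len-1; ins after pos) to a string
apply_dialect_call <- function(s, call) {
  if (call$vtype %in% c("small_del", "large_del"))
    paste0(substr(s, 1L, call$pos - 1L),
           substr(s, call$pos + call$length, nchar(s)))
  else if (call$vtype %in% c("small_ins", "large_ins"))
    paste0(substr(s, 1L, call$pos), call$alt_allele,
           substr(s, call$pos + 1L, nchar(s)))
  else {
    substr(s, call$pos, call$pos) <- call$alt_allele
    s
  }
}

scaled_synth <- function(...) {
  synth_config(chrom_lengths = setNames(rep(1e5, 3), c("I", "II", "III")),
               n_genes = 15L, ...)
}
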