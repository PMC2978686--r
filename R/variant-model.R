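# Domain types: variant calls, genomes, gene models.
#
# Coordinate dialect (used by every table this package writes): positions are
# 1-based; a deletion's `pos` is the FIRST DELETED base and `ref_allele` holds
# the deleted sequence; an insertion occurs AFTER `pos` and `alt_allele` holds
# the inserted sequence. SNPs carry single-base ref/alt at `pos`. The VCF
# reader converts from the left-anchored VCF representation into this dialect
# and the writer converts back (keeping the anchor base so round-trips are
# exact).

VTYPES <- c("snp", "small_ins", "small_del", "large_ins", "large_del")

#' Construct a set of variant calls
#'
#' Builds the central data frame used throughout the pipeline: one row per
#' candidate difference between the focal strain and the reference, in the
#' package's table coordinate dialect (see Details).
#'
#' @details `pos` is 1-based. For deletions `pos` is the first deleted base
#'   and `ref_allele` the deleted sequence (`alt_allele` is `""`); for
#'   insertions the inserted sequence in `alt_allele` sits after `pos`
#'   (`ref_allele` is `""`). Small indels are 1-3 bp; indels of 4 bp or more
#'   are "large" (the split mirrors the two upstream detection routes:
#'   pileup-based small-indel calling vs split-read detection of 5-10000 bp
#'   deletions and 5-30 bp insertions).
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (dialect above).
#' @param ref_allele,alt_allele allele strings over A,C,G,T (may be `""` for
#'   the empty side of an indel).
#' @param vtype one of `"snp"`, `"small_ins"`, `"small_del"`, `"large_ins"`,
#'   `"large_del"`; inferred from the alleles when `NULL`.
#' @param quality non-negative call quality scores.
#' @param ambiguous logical; did the aligner flag ambiguous placement?
#' @param source_strain strain identifier for the calls.
#' @param anchor_base reference base immediately before an insertion /
#'   deletion (used to re-anchor on VCF export); `NA` for SNPs.
#' @param gt optional genotype string per call (e.g. `"1/1"`, `"./."`).
#' @return a `data.frame` of class `"variant_calls"`.
#' @export
variant_calls <- function(chrom = character(), pos = integer(),
                          ref_allele = character(), alt_allele = character(),
                          vtype = NULL, quality = numeric(),
                          ambiguous = logical(), source_strain = "",
                          anchor_base = NA_character_, gt = NA_character_) {
  n <- length(pos)
  if (is.null(vtype)) vtype <- infer_vtype(ref_allele, alt_allele)
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref_allele = rep_len(toupper(as.character(ref_allele)), n),
    alt_allele = rep_len(toupper(as.character(alt_allele)), n),
    vtype = rep_len(as.character(vtype), n),
    length = integer(n),
    quality = rep_len(as.numeric(quality), n),
    ambiguous = rep_len(as.logical(ambiguous), n),
    source_strain = rep_len(as.character(source_strain), n),
    anchor_base = rep_len(as.character(anchor_base), n),
    gt = rep_len(as.character(gt), n),
    stringsAsFactors = FALSE
  )
  # in the dialect one side of an indel is empty, so length is the nchar of
  # the non-empty side
  x$length <- ifelse(x$vtype == "snp", 1L,
                     pmax(nchar(x$ref_allele), nchar(x$alt_allele)))
  class(x) <- c("variant_calls", "data.frame")
  validate_variant_calls(x)
}

infer_vtype <- function(ref, alt) {
  ref <- as.character(ref); alt <- as.character(alt)
  d <- nchar(alt) - nchar(ref)
  ifelse(d == 0L & nchar(ref) == 1L, "snp",
         ifelse(d > 0L, ifelse(d <= 3L, "small_ins", "large_ins"),
                ifelse(-d <= 3L, "small_del", "large_del")))
}

#' Validate a variant_calls data frame
#'
#' Checks the type invariants: SNPs have length 1 and differing single-base
#' alleles, small indels are 1-3 bp, positions are >= 1. Large indels outside
#' the upstream detection bounds (deletions 5-10000 bp, insertions 5-30 bp)
#' raise a warning, not an error.
#'
#' @param x a `variant_calls` data frame.
#' @return `x`, invisibly classed, after validation.
#' @export
validate_variant_calls <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(x)
  if (any(!x$vtype %in% VTYPES)) stop("unknown vtype")
  if (any(x$pos < 1L)) stop("pos must be >= 1")
  if (any(x$quality < 0, na.rm = TRUE)) stop("quality must be non-negative")
  snp <- x$vtype == "snp"
  if (any(snp & (nchar(x$ref_allele) != 1L | nchar(x$alt_allele) != 1L)))
    stop("snp alleles must be single bases")
  if (any(snp & x$ref_allele == x$alt_allele))
    stop("snp ref and alt alleles must differ")
  small <- x$vtype %in% c("small_ins", "small_del")
  if (any(small & (x$length < 1L | x$length > 3L)))
    stop("small indels must be 1-3 bp")
  ld <- x$vtype == "large_del"; li <- x$vtype == "large_ins"
  if (any(ld & (x$length < 5L | x$length > 10000L)) ||
      any(li & (x$length < 5L | x$length > 30L)))
    warning("large indel outside the 5-10000 bp (del) / 5-30 bp (ins) ",
            "detection bounds")
  x
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("<variant_calls> %d calls (%s)\n", nrow(x),
              paste(sprintf("%s:%d", names(table(x$vtype)), table(x$vtype)),
                    collapse = ", ")))
  NextMethod()
}

empty_variant_calls <- function() {
  variant_calls(character(), integer(), character(), character(),
                vtype = character(), quality = numeric(),
                ambiguous = logical())
}

# Site identity key: exact allele identity, never fuzzy-matched.
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$vtype, x$ref_allele, x$alt_allele, sep = "\r")
}

## ---------------------------------------------------------------- FASTA ----

#' Read a reference genome from FASTA
#'
#' @param path path to a FASTA file.
#' @return an object of class `"genome"`: a list with `sequences` (named
#'   uppercase character vector) and `L` (total length in bp).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence name in FASTA: ",
                              nm[duplicated(nm)][1])
  seqs <- toupper(setNames(as.character(ss), nm))
  genome(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param sequences named character vector of chromosome sequences
#'   (alphabet A,C,G,T,N; lowercase is uppercased).
#' @return a `"genome"` object; see [read_fasta()].
#' @export
genome <- function(sequences) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("genome alphabet must be A,C,G,T,N")
  g <- list(sequences = sequences, L = sum(nchar(sequences)))
  if (g$L <= 0) stop("genome has zero length")
  class(g) <- "genome"
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d sequence(s), L = %d bp\n",
              length(x$sequences), x$L))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome a `"genome"` object.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$sequences)) {
    s <- genome$sequences[[nm]]
    writeLines(paste0(">", nm), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

genome_base <- function(genome, chrom, pos) {
  substring(genome$sequences[[chrom]], pos, pos)
}

## ------------------------------------------------------------------ VCF ----

#' Read per-strain variant calls from a VCF file
#'
#' Reads a minimal single-sample VCF 4.x file into the package's coordinate
#' dialect. Indel type and length are inferred from the ref/alt length
#' difference; left-anchored indel records are converted so that a deletion's
#' `pos` is its first deleted base and an insertion sits after `pos`. The
#' optional INFO key `AMBIG=1` marks ambiguous aligner placement (absent
#' means unambiguous). If a genotype column is present its `GT` value is kept
#' (`"./."` records represent assayed-but-missing coverage at a site).
#'
#' @param path path to the VCF file.
#' @param strain_id strain identifier stored in `source_strain`.
#' @return a `variant_calls` data frame.
#' @export
read_vcf <- function(path, strain_id = "sample") {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0) return(empty_variant_calls())
  parse_fail <- function(i, msg) {
    stop(sprintf("VCF parse error at line %d of %s: %s", i, path, msg),
         call. = FALSE)
  }
  recs <- vector("list", length(body_idx))
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) parse_fail(i, "fewer than 8 columns")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) parse_fail(i, "non-integer POS")
    ref <- toupper(f[4]); alt <- toupper(f[5])
    if (grepl(",", alt, fixed = TRUE))
      parse_fail(i, "multi-allelic records are not supported")
    if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
      parse_fail(i, "alleles must be over {A,C,G,T}")
    if (ref == alt) parse_fail(i, "REF equals ALT")
    if (f[6] == "." || f[6] == "")
      parse_fail(i, "QUAL is required by the downstream quality filters")
    qual <- suppressWarnings(as.numeric(f[6]))
    if (is.na(qual)) parse_fail(i, "non-numeric QUAL")
    ambig <- grepl("(^|;)AMBIG=1(;|$)", f[8])
    gt <- NA_character_
    if (length(f) >= 10) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      if ("GT" %in% keys) gt <- vals[match("GT", keys)]
    }
    nr <- nchar(ref); na <- nchar(alt)
    if (nr == na) {
      if (nr != 1L) parse_fail(i, "multi-base substitutions not supported")
      recs[[j]] <- list(f[1], pos, ref, alt, "snp", qual, ambig,
                        NA_character_, gt)
    } else if (na > nr) {              # insertion
      if (substr(alt, 1L, nr) != ref)
        parse_fail(i, "insertion ALT must extend REF")
      ins <- substr(alt, nr + 1L, na)
      recs[[j]] <- list(f[1], pos + nr - 1L, "", ins,
                        if (na - nr <= 3L) "small_ins" else "large_ins",
                        qual, ambig, substr(ref, nr, nr), gt)
    } else {                           # deletion
      if (substr(ref, 1L, na) != alt)
        parse_fail(i, "deletion REF must extend ALT")
      del <- substr(ref, na + 1L, nr)
      recs[[j]] <- list(f[1], pos + na, del, "",
                        if (nr - na <= 3L) "small_del" else "large_del",
                        qual, ambig, substr(alt, na, na), gt)
    }
  }
  m <- do.call(rbind, lapply(recs, function(r) {
    data.frame(chrom = r[[1]], pos = r[[2]], ref_allele = r[[3]],
               alt_allele = r[[4]], vtype = r[[5]], quality = r[[6]],
               ambiguous = r[[7]], anchor_base = r[[8]], gt = r[[9]],
               stringsAsFactors = FALSE)
  }))
  variant_calls(m$chrom, m$pos, m$ref_allele, m$alt_allele, vtype = m$vtype,
                quality = m$quality, ambiguous = m$ambiguous,
                source_strain = strain_id, anchor_base = m$anchor_base,
                gt = m$gt)
}

#' Write variant calls to a VCF file
#'
#' Inverse of [read_vcf()]: converts the package dialect back to left-anchored
#' VCF records. Indels need the reference base before the event; it is taken
#' from the `anchor_base` column, or looked up in `genome` when absent.
#'
#' @param calls a `variant_calls` data frame.
#' @param path output path.
#' @param genome optional `"genome"` used to resolve missing anchor bases.
#' @param sample_name sample column name; when any `gt` is non-`NA` a
#'   genotype column is written.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, genome = NULL, sample_name = NULL) {
  if (is.null(sample_name))
    sample_name <- if (nrow(calls)) calls$source_strain[1] else "sample"
  with_gt <- nrow(calls) > 0 && any(!is.na(calls$gt))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AMBIG,Number=1,Type=Integer,Description=\"Ambiguous alignment placement\">",
           if (with_gt)
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (with_gt) c("FORMAT", sample_name)),
                 collapse = "\t"))
  rows <- character(nrow(calls))
  if (nrow(calls)) {
    for (j in seq_len(nrow(calls))) {
      v <- calls[j, ]
      if (v$vtype == "snp") {
        p <- v$pos; ref <- v$ref_allele; alt <- v$alt_allele
      } else {
        a <- v$anchor_base
        if (is.na(a)) {
          if (is.null(genome))
            stop("indel without anchor_base and no genome supplied")
          ap <- if (v$vtype %in% c("small_del", "large_del")) v$pos - 1L
                else v$pos
          a <- genome_base(genome, v$chrom, ap)
        }
        if (v$vtype %in% c("small_ins", "large_ins")) {
          p <- v$pos; ref <- a; alt <- paste0(a, v$alt_allele)
        } else {
          p <- v$pos - 1L; ref <- paste0(a, v$ref_allele); alt <- a
        }
      }
      info <- if (isTRUE(v$ambiguous)) "AMBIG=1" else "."
      rows[j] <- paste(c(v$chrom, p, ".", ref, alt,
                         format(v$quality, trim = TRUE, scientific = FALSE),
                         ".", info,
                         if (with_gt) c("GT", if (is.na(v$gt)) "1/1" else v$gt)),
                       collapse = "\t")
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## ----------------------------------------------------------------- GFF3 ----

#' Construct a gene model
#'
#' One transcript's worth of annotation: ordered coding exons, optional UTR
#' exons, strand, and biotype. CDS exons are stored in genomic coordinate
#' order regardless of strand.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons data frame with `start`,`end` (1-based closed intervals).
#' @param utr_exons optional data frame with `start`,`end`.
#' @param biotype `"protein_coding"` or `"pseudogene"`.
#' @return an object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, cds_exons,
                       utr_exons = NULL, biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"),
            biotype %in% c("protein_coding", "pseudogene"))
  cds_exons <- as.data.frame(cds_exons)[, c("start", "end")]
  cds_exons <- cds_exons[order(cds_exons$start), , drop = FALSE]
  rownames(cds_exons) <- NULL
  if (nrow(cds_exons) > 1 &&
      any(cds_exons$start[-1] <= cds_exons$end[-nrow(cds_exons)]))
    stop("cds_exons must be non-overlapping")
  if (any(cds_exons$end < cds_exons$start)) stop("exon end < start")
  if (is.null(utr_exons))
    utr_exons <- data.frame(start = integer(), end = integer())
  utr_exons <- as.data.frame(utr_exons)[, c("start", "end"), drop = FALSE]
  len <- sum(cds_exons$end - cds_exons$start + 1L)
  if (biotype == "protein_coding" && len %% 3L != 0L)
    warning(sprintf("CDS length of %s is not divisible by 3", transcript_id))
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, cds_exons = cds_exons,
                 utr_exons = utr_exons, biotype = biotype),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s %d CDS exon(s), %s\n", x$gene_id,
              x$transcript_id, x$chrom, x$strand, nrow(x$cds_exons),
              x$biotype))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' One `gene_model` per transcript. Biotype comes from a `biotype` attribute
#' on the transcript or parent gene, or from a parent feature of type
#' `"pseudogene"`; it defaults to `"protein_coding"`. CDS rows must name a
#' parent transcript.
#'
#' @param path path to a GFF3 file.
#' @return a named list of `gene_model` objects (names = transcript ids).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else
      NA_character_, character(1)) else rep(NA_character_, length(gr))
  biot <- if ("biotype" %in% names(md)) as.character(md$biotype) else
    rep(NA_character_, length(gr))

  is_gene <- typ %in% c("gene", "pseudogene")
  gene_type <- setNames(typ[is_gene], ids[is_gene])
  gene_biot <- setNames(biot[is_gene], ids[is_gene])
  is_tx <- typ %in% c("mRNA", "transcript", "pseudogenic_transcript")
  tx_ids <- ids[is_tx]
  out <- list()
  for (k in which(is_tx)) {
    tid <- ids[k]; gid <- parents[k]
    child <- which(parents == tid)
    cds_rows <- child[typ[child] == "CDS"]
    utr_rows <- child[typ[child] %in%
                        c("five_prime_UTR", "three_prime_UTR", "UTR")]
    bt <- biot[k]
    if (is.na(bt) && !is.na(gid)) bt <- gene_biot[[gid]]
    if (is.na(bt))
      bt <- if (!is.na(gid) && identical(gene_type[[gid]], "pseudogene"))
        "pseudogene" else "protein_coding"
    if (length(cds_rows) == 0) next
    out[[tid]] <- gene_model(
      gene_id = if (is.na(gid)) tid else gid, transcript_id = tid,
      chrom = as.character(GenomicRanges::seqnames(gr))[k],
      strand = as.character(GenomicRanges::strand(gr))[k],
      cds_exons = data.frame(start = GenomicRanges::start(gr)[cds_rows],
                             end = GenomicRanges::end(gr)[cds_rows]),
      utr_exons = data.frame(start = GenomicRanges::start(gr)[utr_rows],
                             end = GenomicRanges::end(gr)[utr_rows]),
      biotype = bt)
  }
  orphan_cds <- which(typ == "CDS" & !(parents %in% tx_ids))
  if (length(orphan_cds))
    stop("CDS row without a parent transcript in ", path)
  out
}

## ----------------------------------------------------------- out tables ----

# Homozygous-pair allele dialect of the published indel tables:
# insertions "+G/+G" (uppercase), deletions "−g/−g" (lowercase,
# minus sign U+2212). SNPs are written "A/A" with the focal-strain base.
format_focal_allele <- function(v) {
  one <- switch(v$vtype,
    snp = v$alt_allele,
    small_ins = , large_ins = paste0("+", toupper(v$alt_allele)),
    small_del = , large_del = paste0("−", tolower(v$ref_allele)))
  paste0(one, "/", one)
}

#' Read a published-dialect variant table
#'
#' Parses a TSV in the published six-column shape (see
#' [write_variant_table()]), plus an `N2_allele` column which the SNP rows
#' need to recover both alleles. Intended for recomputing summary statistics
#' from the published supplementary tables once converted to TSV; the
#' package cannot redistribute those tables.
#'
#' @param path TSV with columns `Chr`, `Variation`, `LSJ1_allele`,
#'   `N2_allele` (SNP rows), and optionally `Ancestral Status`.
#' @return a `variant_calls` data frame with an `ancestral` column when the
#'   status column is present.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                   stringsAsFactors = FALSE)
  need <- c("Chr", "Variation", "LSJ1_allele")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  tok <- sub("/.*$", "", df$LSJ1_allele)
  is_ins <- grepl("^\\+", tok)
  is_del <- grepl("^[−-]", tok)
  seqs <- toupper(sub("^[+−-]", "", tok))
  ref <- ifelse(is_del, seqs,
                ifelse(is_ins, "",
                       sub("/.*$", "", df[["N2_allele"]])))
  alt <- ifelse(is_ins, seqs, ifelse(is_del, "", seqs))
  vtype <- ifelse(is_ins, ifelse(nchar(seqs) <= 3, "small_ins", "large_ins"),
                  ifelse(is_del,
                         ifelse(nchar(seqs) <= 3, "small_del", "large_del"),
                         "snp"))
  calls <- variant_calls(df$Chr, df$Variation, ref, alt, vtype = vtype,
                         quality = 99, ambiguous = FALSE,
                         source_strain = "LSJ1")
  if ("Ancestral Status" %in% names(df)) {
    calls$ancestral <- df[["Ancestral Status"]]
    calls$derived_lineage <- c(N2 = "LSJ1", LSJ1 = "N2",
                               unknown = "unknown")[calls$ancestral]
  }
  calls
}

#' Write the annotated variant table
#'
#' Emits the published six-column table shape: `Chr`, `Variation` (position),
#' `Gene Name`, `Gene Function`, `LSJ1_allele` (homozygous-pair dialect,
#' `+G/+G` for insertions, `−g/−g` for deletions), and
#' `Ancestral Status`. Unannotated variants get blank gene columns.
#'
#' @param variants a `variant_calls` data frame, optionally with `gene_name`,
#'   `gene_function`, and `ancestral` columns from the annotation and
#'   polarization stages.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  cols <- c("Chr", "Variation", "Gene Name", "Gene Function", "LSJ1_allele",
            "Ancestral Status")
  n <- nrow(variants)
  get <- function(col) {
    if (col %in% names(variants)) {
      x <- as.character(variants[[col]]); x[is.na(x)] <- ""; x
    } else rep("", n)
  }
  tab <- data.frame(
    Chr = variants$chrom,
    Variation = variants$pos,
    gene_name = get("gene_name"),
    gene_function = get("gene_function"),
    allele = if (n) vapply(seq_len(n), function(j)
      format_focal_allele(variants[j, ]), character(1)) else character(),
    ancestral = get("ancestral"),
    stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (n) writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}
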