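# Synthetic-data generator with a planted-event truth ledger.
#
# The stated world: a founder genome gives rise to two lineages that
# accumulate Poisson(mu_eff * L * t) substitutions each (plus 1-3 bp indels
# at the configured share, with the configured 6-class spectrum); the
# published reference is the endpoint of lineage A (the N2 analog) with
# sequencing errors planted at rate e per bp; the panel strains carry the
# lineage-A endpoint observed with per-site dropout d and miscall m; the two
# outgroups carry founder alleles. Every variant record in the emitted files
# traces to exactly one ledger row (or to injected noise, flagged).
#
# All coordinates in the emitted files and the ledger are REFERENCE
# coordinates in the package's table dialect. Planted events are kept >= 10
# bp apart so site identity is exact and indel records never interact.

#' Synthetic-dataset configuration
#'
#' Defaults are the paper-magnitude desk-scale world: 6 chromosomes of
#' 5e5 bp, separation t = 1620 generations, substitution rate mu = 2.7e-9
#' scaled by `rate_scale` = 33.4 so that `2 * mu_eff * L * t` plants ~877
#' SNPs (and, at the default indel share of 331/1208, ~331 small indels);
#' reference errors at e = 2e-5 per bp (1 in 50,000); error events are
#' indels with probability 1490/2038 (the observed error composition).
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param t generations of separation between the two lineages.
#' @param mu per-bp per-generation substitution rate.
#' @param rate_scale scale factor applied to `mu` on the small genome
#'   (recorded in the truth metadata).
#' @param indel_fraction share of lineage events that are 1-3 bp indels.
#' @param spectrum_weights positive weights for the 6 strand-collapsed
#'   substitution classes (named as in [substitution_spectrum()]).
#' @param e reference-error rate per bp.
#' @param error_indel_fraction share of reference errors that are indels.
#' @param d panel per-site dropout probability (emitted as `./.` records).
#' @param m per-site miscall probability (panel and outgroups).
#' @param n_panel number of panel strains.
#' @param n_noise spurious low-confidence focal calls to inject (flagged in
#'   the ledger; the quality/ambiguity filters should remove them).
#' @param n_genes,mean_exons,pseudogene_fraction annotation density.
#' @param seed RNG seed (same seed, byte-identical output files).
#' @return a list of class `"synth_config"`.
#' @export
synth_config <- function(chrom_lengths = setNames(rep(5e5, 6),
                                                  c("I", "II", "III", "IV",
                                                    "V", "X")),
                         t = 1620, mu = 2.7e-9, rate_scale = 33.4,
                         indel_fraction = 331 / 1208,
                         spectrum_weights = c("G:C->A:T" = 2,
                                              "G:C->T:A" = 2,
                                              "G:C->C:G" = 1,
                                              "A:T->G:C" = 1,
                                              "A:T->T:A" = 1,
                                              "A:T->C:G" = 1),
                         e = 2e-5, error_indel_fraction = 1490 / 2038,
                         d = 0, m = 0, n_panel = 6L, n_noise = 0L,
                         n_genes = 40L, mean_exons = 3,
                         pseudogene_fraction = 0.1, seed = 1L) {
  stopifnot(all(chrom_lengths > 0), t >= 0, mu >= 0, rate_scale > 0,
            indel_fraction >= 0, indel_fraction < 1,
            all(spectrum_weights > 0),
            setequal(names(spectrum_weights), SPECTRUM_CLASSES),
            e >= 0, d >= 0, d <= 1, m >= 0, m <= 1, n_panel >= 1)
  structure(as.list(environment()), class = "synth_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# derived base given an ancestral base, sampled from the 6-class weights
mutate_base <- function(anc, weights) {
  vapply(anc, function(b) {
    alts <- setdiff(c("A", "C", "G", "T"), b)
    w <- weights[spectrum_class(rep(b, 3), alts)]
    sample(alts, 1, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

# n event sites, >= gap apart (and gap away from chromosome ends), avoiding
# homopolymer runs > 5 around indel sites. Resampling count is reported via
# attribute "resampled".
sample_sites <- function(n, founder, is_indel, gap = 10L) {
  lens <- nchar(founder)
  chroms <- names(founder)
  resampled <- 0L
  draw <- function(k) {
    ch <- sample(chroms, k, replace = TRUE, prob = lens)
    pos <- vapply(ch, function(c0)
      sample.int(lens[[c0]] - 2L * gap, 1L) + gap, integer(1),
      USE.NAMES = FALSE)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }
  sites <- cbind(draw(n), is_indel = is_indel)
  repeat {
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]
    same <- c(FALSE, sites$chrom[-1] == sites$chrom[-n])
    close <- c(FALSE, diff(sites$pos) < gap) & same
    ctx <- substring(founder[sites$chrom], pmax(1L, sites$pos - 5L),
                     sites$pos + 8L)
    homop <- sites$is_indel & grepl("A{6}|C{6}|G{6}|T{6}", ctx)
    bad <- close | homop
    if (!any(bad)) break
    resampled <- resampled + sum(bad)
    keep_idx <- which(!bad)
    redraw <- draw(sum(bad))
    sites[bad, c("chrom", "pos")] <- redraw
  }
  rownames(sites) <- NULL
  attr(sites, "resampled") <- resampled
  sites
}

#' Generate a complete synthetic dataset
#'
#' Emits a reference FASTA, gene-model GFF3, the focal-strain VCF, one VCF
#' per panel strain, two outgroup VCFs, and the truth ledger TSV, all under
#' `outdir`. Identical seeds give byte-identical files.
#'
#' @param config a [synth_config()].
#' @param outdir output directory (created if needed); `NULL` skips file
#'   writing and returns the in-memory objects only.
#' @return list with `truth` (ledger data frame), `genome` (the published
#'   reference), `founder` (pre-divergence sequences, for oracle checks),
#'   `genes`, `focal` (focal `variant_calls`), `panel` (named list),
#'   `outgroups` (list of 2), `files` (named paths or `NULL`), `meta`
#'   (rates, lambdas, planted counts, resample count, rate scale).
#' @export
generate_dataset <- function(config = synth_config(), outdir = NULL) {
  set.seed(config$seed)
  lens <- config$chrom_lengths
  L <- sum(lens)
  founder <- setNames(vapply(lens, random_seq, character(1)), names(lens))

  mu_eff <- config$mu * config$rate_scale
  lambda_sub <- mu_eff * L * config$t
  lambda_indel <- lambda_sub * config$indel_fraction /
    (1 - config$indel_fraction)
  lambda_err <- config$e * L
  n_sub <- rpois(2, lambda_sub)           # lineages: 1 = N2-analog, 2 = LSJ1
  n_ind <- rpois(2, lambda_indel)
  n_err <- rpois(1, lambda_err)
  n_err_ind <- rbinom(1, n_err, config$error_indel_fraction)
  n_err_sub <- n_err - n_err_ind

  classes <- c(rep("mutation_in_N2_lineage", n_sub[1] + n_ind[1]),
               rep("mutation_in_LSJ1_lineage", n_sub[2] + n_ind[2]),
               rep("reference_error", n_err),
               rep("noise", config$n_noise))
  kinds <- c(rep("sub", n_sub[1]), rep("indel", n_ind[1]),
             rep("sub", n_sub[2]), rep("indel", n_ind[2]),
             rep("sub", n_err_sub), rep("indel", n_err_ind),
             sample(c("sub", "indel"), config$n_noise, replace = TRUE))
  n_total <- length(classes)
  sites <- sample_sites(n_total, founder, kinds == "indel")
  # sample_sites sorts its rows; re-attach event classes so that indel
  # events land on indel-screened sites (random within each kind)
  perm <- function(x) x[sample.int(length(x))]
  ev <- data.frame(chrom = sites$chrom, fpos = sites$pos,
                   class = rep(NA_character_, n_total),
                   kind = ifelse(sites$is_indel, "indel", "sub"),
                   stringsAsFactors = FALSE)
  ev$class[sites$is_indel] <- perm(classes[kinds == "indel"])
  ev$class[!sites$is_indel] <- perm(classes[kinds == "sub"])

  fb <- substring(founder[ev$chrom], ev$fpos, ev$fpos)
  ev$anc <- fb
  ev$is_ins <- ev$kind == "indel" & runif(n_total) < 0.5
  ev$len <- ifelse(ev$kind == "sub", 1L,
                   sample(1:3, n_total, replace = TRUE))
  ev$derived_base <- rep(NA_character_, n_total)
  subs <- ev$kind == "sub"
  ev$derived_base[subs] <- mutate_base(ev$anc[subs], config$spectrum_weights)
  ev$ins_seq <- rep(NA_character_, n_total)
  ins <- ev$kind == "indel" & ev$is_ins
  ev$ins_seq[ins] <- vapply(ev$len[ins], random_seq, character(1))
  del <- ev$kind == "indel" & !ev$is_ins
  ev$del_seq <- rep(NA_character_, n_total)
  ev$del_seq[del] <- substring(founder[ev$chrom[del]], ev$fpos[del],
                               ev$fpos[del] + ev$len[del] - 1L)

  # --- build the published reference: founder + lineage-A events + errors
  ref_mod <- ev$class %in% c("mutation_in_N2_lineage", "reference_error")
  ref_seqs <- founder
  ev$refpos <- ev$fpos
  for (ch in names(founder)) {
    idx <- which(ev$chrom == ch & ref_mod)
    idx <- idx[order(ev$fpos[idx])]
    delta <- integer(length(idx))
    pieces <- character(0)
    cursor <- 1L
    fseq <- founder[[ch]]
    for (j in seq_along(idx)) {
      i <- idx[j]
      p <- ev$fpos[i]
      if (ev$kind[i] == "sub") {
        pieces <- c(pieces, substr(fseq, cursor, p - 1L), ev$derived_base[i])
        cursor <- p + 1L
        delta[j] <- 0L
      } else if (ev$is_ins[i]) {
        pieces <- c(pieces, substr(fseq, cursor, p), ev$ins_seq[i])
        cursor <- p + 1L
        delta[j] <- ev$len[i]
      } else {
        pieces <- c(pieces, substr(fseq, cursor, p - 1L))
        cursor <- p + ev$len[i]
        delta[j] <- -ev$len[i]
      }
    }
    pieces <- c(pieces, substr(fseq, cursor, nchar(fseq)))
    ref_seqs[[ch]] <- paste(pieces, collapse = "")
    # reference coordinate of every event on this chromosome
    all_idx <- which(ev$chrom == ch)
    if (length(idx)) {
      offs <- vapply(ev$fpos[all_idx], function(p)
        sum(delta[ev$fpos[idx] < p]), integer(1))
      ev$refpos[all_idx] <- ev$fpos[all_idx] + offs
    }
  }
  ref_genome <- genome(ref_seqs)

  # --- dialect records of each event as seen in focal-vs-reference space
  in_ref <- ref_mod                        # event allele present in reference
  ev$vtype <- ifelse(ev$kind == "sub", "snp",
                     ifelse(ev$is_ins == !in_ref, "small_ins", "small_del"))
  ev$pos <- ev$refpos
  ev$ref_allele <- rep("", n_total); ev$alt_allele <- rep("", n_total)
  ev$ref_allele[subs] <- ifelse(in_ref[subs], ev$derived_base[subs],
                                ev$anc[subs])
  ev$alt_allele[subs] <- ifelse(in_ref[subs], ev$anc[subs],
                                ev$derived_base[subs])
  # insertions absent from the reference -> small_ins records
  i1 <- ins & !in_ref
  ev$alt_allele[i1] <- ev$ins_seq[i1]
  # deletions absent from the reference (reference still has the bases)
  d1 <- del & !in_ref
  ev$ref_allele[d1] <- ev$del_seq[d1]
  # insertions present in the reference -> the true strains lack the bases
  i2 <- ins & in_ref
  ev$pos[i2] <- ev$refpos[i2] + 1L
  ev$ref_allele[i2] <- ev$ins_seq[i2]
  # deletions present in the reference -> the true strains keep the bases
  d2 <- del & in_ref
  ev$pos[d2] <- ev$refpos[d2] - 1L
  ev$alt_allele[d2] <- ev$del_seq[d2]

  ev$ancestral_state <- c(mutation_in_N2_lineage = "LSJ1",
                          mutation_in_LSJ1_lineage = "N2",
                          reference_error = NA, noise = NA)[ev$class]
  ev$derived_lineage <- c(mutation_in_N2_lineage = "N2",
                          mutation_in_LSJ1_lineage = "LSJ1",
                          reference_error = NA, noise = NA)[ev$class]

  noise <- ev$class == "noise"
  real <- !noise
  qual <- ifelse(ev$vtype == "snp", runif(n_total, 60, 200),
                 runif(n_total, 30, 150))
  # noise calls must fall to the filters: low quality or ambiguous
  noisy_amb <- noise & runif(n_total) < 0.5
  qual[noise & !noisy_amb] <- ifelse(ev$vtype[noise & !noisy_amb] == "snp",
                                     runif(sum(noise & !noisy_amb), 0, 49),
                                     runif(sum(noise & !noisy_amb), 0, 24))

  anchor <- ifelse(ev$vtype == "snp", NA_character_,
                   ifelse(ev$vtype == "small_ins",
                          substring(ref_seqs[ev$chrom], ev$pos, ev$pos),
                          substring(ref_seqs[ev$chrom], ev$pos - 1L,
                                    ev$pos - 1L)))

  make_calls <- function(idx, strain, gt = NA_character_) {
    o <- idx[order(ev$chrom[idx], ev$pos[idx])]
    variant_calls(ev$chrom[o], ev$pos[o], ev$ref_allele[o],
                  ev$alt_allele[o], vtype = ev$vtype[o], quality = qual[o],
                  ambiguous = noisy_amb[o], source_strain = strain,
                  anchor_base = anchor[o],
                  gt = if (length(gt) == 1) gt else gt[o])
  }

  focal <- make_calls(which(real | noise), "LSJ1", gt = "1/1")

  # --- panel strains: carry the lineage-A endpoint -> focal_like only at
  # error sites; dropout d gives "./." records, miscall m flips the state
  err_site <- ev$class == "reference_error"
  panel <- list()
  for (s in seq_len(config$n_panel)) {
    dropout <- real & runif(n_total) < config$d
    flip <- runif(n_total) < config$m
    shows <- real & !dropout & (err_site != flip)
    gt <- ifelse(dropout, "./.", "1/1")
    keep <- which((shows | dropout) & real)
    panel[[paste0("N2_panel_", s)]] <-
      make_calls(keep, paste0("N2_panel_", s), gt = gt)
  }

  # --- outgroups: carry founder alleles -> focal_like wherever the
  # reference diverged from the founder (lineage-A mutations and errors)
  og_focal <- ev$class %in% c("mutation_in_N2_lineage", "reference_error")
  outgroups <- list()
  for (s in 1:2) {
    flip <- runif(n_total) < config$m
    shows <- real & (og_focal != flip)
    outgroups[[c("CB4856", "ED3054")[s]]] <-
      make_calls(which(shows), c("CB4856", "ED3054")[s], gt = "1/1")
  }

  truth <- data.frame(
    chrom = ev$chrom, pos = ev$pos, event_class = ev$class,
    vtype = ev$vtype, length = ifelse(ev$kind == "sub", 1L, ev$len),
    ref_allele = ev$ref_allele, alt_allele = ev$alt_allele,
    ancestral_state = ev$ancestral_state,
    derived_lineage = ev$derived_lineage,
    founder_pos = ev$fpos, stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$pos), ]
  rownames(truth) <- NULL

  genes <- generate_genes(ref_genome, config)

  meta <- list(L = L, mu_eff = mu_eff, rate_scale = config$rate_scale,
               lambda_sub = lambda_sub, lambda_indel = lambda_indel,
               lambda_err = lambda_err,
               planted = c(sub_N2 = n_sub[1], sub_LSJ1 = n_sub[2],
                           indel_N2 = n_ind[1], indel_LSJ1 = n_ind[2],
                           errors = n_err, noise = config$n_noise),
               resampled = attr(sites, "resampled"), seed = config$seed)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    write_fasta(ref_genome, fp("ref.fa"))
    write_gff3(genes, fp("genes.gff3"))
    write_vcf(focal, fp("lsj1.vcf"))
    for (nm in names(panel))
      write_vcf(panel[[nm]], fp(paste0(tolower(nm), ".vcf")))
    write_vcf(outgroups[[1]], fp("outgroup_cb4856.vcf"))
    write_vcf(outgroups[[2]], fp("outgroup_ed3054.vcf"))
    write.table(truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(ref = fp("ref.fa"), gff = fp("genes.gff3"),
               focal = fp("lsj1.vcf"),
               setNames(fp(paste0(tolower(names(panel)), ".vcf")),
                        names(panel)),
               outgroup_1 = fp("outgroup_cb4856.vcf"),
               outgroup_2 = fp("outgroup_ed3054.vcf"),
               truth = fp("truth.tsv"))
  }
  list(truth = truth, genome = ref_genome, founder = founder,
       genes = genes, focal = focal, panel = panel, outgroups = outgroups,
       files = files, meta = meta)
}

# non-overlapping random gene models on the reference genome
generate_genes <- function(ref_genome, config) {
  genes <- list()
  lens <- nchar(ref_genome$sequences)
  occupied <- lapply(lens, function(x) integer(0))  # gene end positions
  gi <- 0L
  attempts <- 0L
  while (gi < config$n_genes && attempts < config$n_genes * 50L) {
    attempts <- attempts + 1L
    ch <- sample(names(lens), 1, prob = lens)
    n_ex <- max(1L, rpois(1, config$mean_exons - 1) + 1L)
    ex_len <- sample(seq(30L, 150L, by = 3L), n_ex, replace = TRUE)
    rem <- sum(ex_len) %% 3L
    if (rem) ex_len[n_ex] <- ex_len[n_ex] + (3L - rem)
    introns <- if (n_ex > 1) sample(20:100, n_ex - 1, replace = TRUE)
      else integer(0)
    utr5 <- sample(10:60, 1); utr3 <- sample(10:60, 1)
    span <- utr5 + sum(ex_len) + sum(introns) + utr3
    start <- sample.int(lens[[ch]] - span - 20L, 1L) + 10L
    # overlap check against genes already placed on this chromosome
    iv <- occupied[[ch]]
    if (length(iv) && any(start <= iv[seq(2, length(iv), 2)] + 20L &
                          start + span >= iv[seq(1, length(iv), 2)] - 20L))
      next
    gi <- gi + 1L
    occupied[[ch]] <- c(occupied[[ch]], start, start + span)
    cds_start <- start + utr5
    starts <- cds_start + c(0L, cumsum(ex_len[-n_ex] + introns))
    cds <- data.frame(start = starts, end = starts + ex_len - 1L)
    utr <- data.frame(start = c(start, max(cds$end) + 1L),
                      end = c(cds_start - 1L, max(cds$end) + utr3))
    biotype <- if (runif(1) < config$pseudogene_fraction) "pseudogene"
      else "protein_coding"
    id <- sprintf("gene%03d", gi)
    genes[[paste0(id, ".t1")]] <-
      gene_model(id, paste0(id, ".t1"), ch,
                 sample(c("+", "-"), 1), cds, utr, biotype)
  }
  genes
}

#' Write gene models to GFF3
#'
#' @param genes named list of [gene_model()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- c("##gff-version 3")
  for (g in genes) {
    iv <- rbind(g$cds_exons, g$utr_exons)
    lo <- min(iv$start); hi <- max(iv$end)
    gtype <- if (g$biotype == "pseudogene") "pseudogene" else "gene"
    rows <- c(rows,
      sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
              g$chrom, gtype, lo, hi, g$strand, g$gene_id, g$biotype),
      sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
              g$chrom, lo, hi, g$strand, g$transcript_id, g$gene_id,
              g$biotype))
    for (j in seq_len(nrow(g$cds_exons)))
      rows <- c(rows, sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                              g$chrom, g$cds_exons$start[j],
                              g$cds_exons$end[j], g$strand,
                              g$transcript_id))
    for (j in seq_len(nrow(g$utr_exons)))
      rows <- c(rows, sprintf("%s\tsynth\tUTR\t%d\t%d\t.\t%s\t.\tParent=%s",
                              g$chrom, g$utr_exons$start[j],
                              g$utr_exons$end[j], g$strand,
                              g$transcript_id))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Score pipeline recovery against the truth ledger
#'
#' Joins pipeline output to the planted-event ledger on exact site identity
#' and computes precision/recall/F1 for reference-error detection and
#' accuracy of ancestral-state assignment.
#'
#' @param errors,polymorphisms the two tables from [partition_variants()]
#'   (`polymorphisms` ideally after [polarize_variants()]).
#' @param truth the ledger from [generate_dataset()].
#' @return list with `status` (confusion counts, precision, recall, F1 for
#'   the reference_error class) and `ancestral` (accuracy over planted
#'   lineage mutations recovered as polymorphisms).
#' @export
score_recovery <- function(errors, polymorphisms, truth) {
  truth <- truth[truth$event_class != "noise", , drop = FALSE]
  tkey <- paste(truth$chrom, truth$pos, truth$vtype, truth$ref_allele,
                truth$alt_allele, sep = "\r")
  ekey <- variant_key(errors)
  pkey <- variant_key(polymorphisms)
  is_err <- truth$event_class == "reference_error"
  tp <- sum(tkey[is_err] %in% ekey)
  fn <- sum(is_err) - tp
  fp <- length(ekey) - tp
  precision <- if (length(ekey)) tp / length(ekey) else NA_real_
  recall <- if (any(is_err)) tp / sum(is_err) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_

  anc <- NULL
  if ("ancestral" %in% names(polymorphisms)) {
    idx <- match(pkey, tkey)
    ok <- !is.na(idx) & !is_err[idx]
    agree <- polymorphisms$ancestral[ok] == truth$ancestral_state[idx[ok]]
    anc <- list(n = sum(ok), correct = sum(agree),
                accuracy = if (any(ok)) mean(agree) else NA_real_)
  }
  list(status = list(tp = tp, fp = fp, fn = fn, precision = precision,
                     recall = recall, f1 = f1),
       ancestral = anc)
}
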