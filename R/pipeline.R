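# End-to-end convenience wrapper and the command-line interface.

#' Run the full inference chain on a set of input files
#'
#' Reads the focal-strain VCF, the panel and outgroup VCFs, the reference
#' FASTA and the gene models; applies the quality/ambiguity filters; votes
#' out reference errors; polarizes the retained polymorphisms; annotates
#' coding effects; and assembles the summary statistics.
#'
#' @param focal_vcf path to the focal-strain VCF.
#' @param panel_vcfs character vector of panel-strain VCF paths.
#' @param outgroup_vcfs character vector of exactly two outgroup VCF paths.
#' @param fasta reference FASTA path.
#' @param gff3 optional gene-model GFF3 path (skips coding annotation when
#'   `NULL`).
#' @param filter_cfg a [filter_config()].
#' @param panel_cfg a [panel_config()].
#' @param mu,g mutation rate and generation time for the divergence model.
#' @return list with `errors`, `polymorphisms` (polarized, annotated),
#'   `discarded`, `effects`, `scan`, and `summary`.
#' @export
run_pipeline <- function(focal_vcf, panel_vcfs, outgroup_vcfs, fasta,
                         gff3 = NULL, filter_cfg = filter_config(),
                         panel_cfg = panel_config(), mu = 2.7e-9, g = 4) {
  stopifnot(length(outgroup_vcfs) == 2)
  genome <- read_fasta(fasta)
  focal <- read_vcf(focal_vcf, "focal")
  panel <- lapply(panel_vcfs, read_vcf)
  names(panel) <- if (!is.null(names(panel_vcfs)) &&
                      all(nzchar(names(panel_vcfs)))) names(panel_vcfs)
    else tools::file_path_sans_ext(basename(panel_vcfs))
  og1 <- read_vcf(outgroup_vcfs[1], "outgroup_1")
  og2 <- read_vcf(outgroup_vcfs[2], "outgroup_2")

  filt <- apply_filters(focal, filter_cfg)
  parts <- partition_variants(filt$kept, panel, panel_cfg)
  poly <- polarize_variants(parts$polymorphisms, og1, og2)

  effects <- NULL
  errors <- parts$errors
  if (!is.null(gff3)) {
    genes <- read_gff3(gff3)
    errors <- annotate_effects(errors, genes, genome)
    poly <- annotate_effects(poly, genes, genome)
    effects <- summarize_effects(errors, poly)
  }
  chrom_lengths <- nchar(genome$sequences)
  scan <- if (nrow(poly))
    suppressWarnings(ks_uniformity_scan(poly, chrom_lengths)) else NULL
  list(errors = errors, polymorphisms = poly, discarded = filt$discarded,
       effects = effects, scan = scan,
       summary = summary_report(poly, nrow(errors), genome$L, mu, g))
}

## -------------------------------------------------------------- CLI -------
# exec/domestiscan dispatches here:
#   domestiscan synth --seed 42 --outdir data/
#   domestiscan filter --vcf in.vcf --q-snp 50 --q-indel 25 --out kept.tsv
#   domestiscan classify --focal lsj1.vcf --panel a.vcf,b.vcf --k 4 --outdir .
#   domestiscan polarize --focal poly.vcf --outgroups cb.vcf,ed.vcf --out x.tsv
#   domestiscan stats --vcf poly.vcf --fasta ref.fa --errors 2038 --out s.json
#   domestiscan simulate-intercross --replicates 200 --seed 1 --bias 1

cli_opt <- function(args, flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i)) return(default)
  if (i == length(args)) stop("missing value for ", flag)
  args[i + 1]
}

cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: domestiscan <synth|filter|classify|polarize|stats|",
         "simulate-intercross> [options]")
  cmd <- args[1]; args <- args[-1]
  num <- function(flag, default) as.numeric(cli_opt(args, flag, default))
  switch(cmd,
    synth = {
      cfg <- synth_config(seed = as.integer(num("--seed", 1)),
                          d = num("--dropout", 0), m = num("--miscall", 0))
      out <- generate_dataset(cfg, outdir = cli_opt(args, "--outdir", "."))
      message("planted events: ",
              paste(names(out$meta$planted), out$meta$planted,
                    collapse = ", ", sep = "="))
    },
    filter = {
      calls <- read_vcf(cli_opt(args, "--vcf"), "focal")
      cfg <- filter_config(q_snp_min = num("--q-snp", 50),
                           q_small_indel_min = num("--q-indel", 25),
                           q_large_ins_min = num("--q-large-ins", 35),
                           drop_ambiguous =
                             is.null(cli_opt(args, "--keep-ambiguous")))
      res <- apply_filters(calls, cfg)
      write.table(res$kept, cli_opt(args, "--out", "kept.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(res$discarded, cli_opt(args, "--discarded",
                                         "discarded.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      message(nrow(res$kept), " kept, ", nrow(res$discarded), " discarded")
    },
    classify = {
      focal <- read_vcf(cli_opt(args, "--focal"), "focal")
      paths <- strsplit(cli_opt(args, "--panel"), ",", fixed = TRUE)[[1]]
      panel <- setNames(lapply(paths, read_vcf),
                        tools::file_path_sans_ext(basename(paths)))
      cfg <- panel_config(k = as.integer(num("--k", 4)),
                          n = as.integer(num("--n", max(6, length(paths)))))
      parts <- partition_variants(focal, panel, cfg)
      outdir <- cli_opt(args, "--outdir", ".")
      write.table(parts$errors, file.path(outdir, "errors.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(parts$polymorphisms,
                  file.path(outdir, "polymorphisms.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      message(nrow(parts$errors), " reference errors, ",
              nrow(parts$polymorphisms), " polymorphisms")
    },
    polarize = {
      focal <- read_vcf(cli_opt(args, "--focal"), "focal")
      ogs <- strsplit(cli_opt(args, "--outgroups"), ",", fixed = TRUE)[[1]]
      stopifnot(length(ogs) == 2)
      poly <- polarize_variants(focal, read_vcf(ogs[1], "outgroup_1"),
                                read_vcf(ogs[2], "outgroup_2"))
      write_variant_table(poly, cli_opt(args, "--out", "polarized.tsv"))
      s <- summarize_polarization(poly)
      message("ancestral N2: ", s$counts[["ancestral_N2"]],
              ", ancestral LSJ1: ", s$counts[["ancestral_LSJ1"]],
              ", unknown: ", s$counts[["unknown"]])
    },
    stats = {
      calls <- read_vcf(cli_opt(args, "--vcf"), "focal")
      genome <- read_fasta(cli_opt(args, "--fasta"))
      rep <- summary_report(calls,
                            n_errors = as.integer(num("--errors", 0)),
                            L = genome$L, mu = num("--mu", 2.7e-9),
                            g = num("--gen-days", 4))
      scan <- suppressWarnings(
        ks_uniformity_scan(calls, nchar(genome$sequences)))
      out <- cli_opt(args, "--out", "stats.json")
      jsonlite::write_json(list(summary = rep, scan = scan), out,
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      message("wrote ", out)
    },
    `simulate-intercross` = {
      cfg <- sim_config(pick_bias = num("--bias", 1),
                        r = num("--r", 0.2),
                        linkage = cli_opt(args, "--linkage", "x_linked"))
      res <- replicate_fractions(cfg,
                                 replicates = as.integer(num("--replicates",
                                                             50)),
                                 seed = as.integer(num("--seed", 1)))
      out <- cli_opt(args, "--out", "intercross.json")
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      message(sprintf("mean focal-allele fraction %.3f (se %.4f)",
                      res$mean, res$se))
    },
    stop("unknown subcommand: ", cmd))
  invisible(NULL)
}
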