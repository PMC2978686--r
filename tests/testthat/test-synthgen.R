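test_that("mu = 0 and e = 0 yield empty strain VCFs", {
  ds <- generate_dataset(scaled_synth(mu = 0, e = 0, seed = 1),
                         outdir = tempfile("synth0"))
  expect_equal(nrow(ds$focal), 0L)
  expect_true(all(vapply(ds$panel, nrow, integer(1)) == 0L))
  expect_equal(nrow(read_vcf(ds$files[["focal"]])), 0L)
})

test_that("planted substitution counts are Poisson-consistent with mu*L*t", {
  cfg <- synth_config(seed = 2)
  ds <- generate_dataset(cfg)
  lambda <- ds$meta$lambda_sub
  for (lin in c("mutation_in_N2_lineage", "mutation_in_LSJ1_lineage")) {
    n <- sum(ds$truth$event_class == lin & ds$truth$vtype == "snp")
    expect_lt(abs(n - lambda), 3 * sqrt(lambda), label = lin)
  }
  n_err <- sum(ds$truth$event_class == "reference_error")
  expect_lt(abs(n_err - ds$meta$lambda_err), 3 * sqrt(ds$meta$lambda_err))
})

test_that("identical seeds give byte-identical output files", {
  d1 <- tempfile("synthA"); d2 <- tempfile("synthB")
  f1 <- generate_dataset(scaled_synth(seed = 9, d = 0.1, m = 0.01,
                                      n_noise = 5L), outdir = d1)$files
  f2 <- generate_dataset(scaled_synth(seed = 9, d = 0.1, m = 0.01,
                                      n_noise = 5L), outdir = d2)$files
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]), info = nm)
  f3 <- generate_dataset(scaled_synth(seed = 10), outdir = tempfile())$files
  expect_false(identical(readLines(f1[["focal"]]),
                         readLines(f3[["focal"]])))
})

test_that("ledger completeness: focal records reconstruct the focal genome", {
  # noiseless mode: applying every focal record to the emitted reference
  # must yield exactly the focal lineage's genome, i.e. the founder with the
  # ledger's focal-lineage events applied -- a naive whole-genome oracle
  ds <- generate_dataset(scaled_synth(seed = 12))
  lsj1 <- ds$truth[ds$truth$event_class == "mutation_in_LSJ1_lineage", ]
  for (ch in names(ds$genome$sequences)) {
    # route A: reference + all focal-vs-reference records (right to left)
    a <- ds$genome$sequences[[ch]]
    calls <- ds$focal[ds$focal$chrom == ch, ]
    calls <- calls[order(-calls$pos), ]
    for (j in seq_len(nrow(calls))) a <- apply_dialect_call(a, calls[j, ])
    # route B: founder + planted focal-lineage events in founder coordinates
    b <- ds$founder[[ch]]
    ev <- lsj1[lsj1$chrom == ch, ]
    ev <- ev[order(-ev$founder_pos), ]
    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]; e$pos <- e$founder_pos
      b <- apply_dialect_call(b, e)
    }
    expect_identical(a, b, info = ch)
    # every focal record traces to exactly one ledger row
    tkey <- paste(ds$truth$chrom, ds$truth$pos, ds$truth$vtype,
                  ds$truth$ref_allele, ds$truth$alt_allele)
    ckey <- paste(calls$chrom, calls$pos, calls$vtype, calls$ref_allele,
                  calls$alt_allele)
    expect_true(all(ckey %in% tkey))
    expect_false(anyDuplicated(ckey) > 0)
  }
})

test_that("written files round-trip through the standard readers", {
  ds <- generate_dataset(scaled_synth(seed = 13, d = 0.2),
                         outdir = tempfile("synthRT"))
  g <- read_fasta(ds$files[["ref"]])
  expect_identical(g$sequences, ds$genome$sequences)
  genes <- read_gff3(ds$files[["gff"]])
  expect_equal(length(genes), length(ds$genes))
  g1 <- genes[[1]]; g0 <- ds$genes[[names(genes)[1]]]
  expect_equal(g1$cds_exons, g0$cds_exons)
  expect_equal(g1$biotype, g0$biotype)
  p1 <- read_vcf(ds$files[["N2_panel_1"]], "N2_panel_1")
  expect_identical(p1$gt, ds$panel[["N2_panel_1"]]$gt)   # "./." preserved
})

test_that("injected noise is flagged and removed by the filters", {
  ds <- generate_dataset(scaled_synth(seed = 14, n_noise = 12L))
  expect_equal(sum(ds$truth$event_class == "noise"), 12L)
  filt <- apply_filters(ds$focal)
  nkey <- with(ds$truth[ds$truth$event_class == "noise", ],
               paste(chrom, pos))
  expect_true(all(paste(filt$discarded$chrom, filt$discarded$pos) %in% nkey))
  expect_equal(nrow(filt$discarded), 12L)
})

test_that("score_recovery arithmetic on a known misclassification", {
  ds <- generate_dataset(scaled_synth(seed = 15))
  parts <- partition_variants(ds$focal, ds$panel)
  k <- nrow(parts$errors)
  expect_gte(k, 2)           # 6 planted errors at this seed
  # demote one true error to the polymorphism table
  errs <- parts$errors[-1, ]
  poly <- rbind(parts$polymorphisms, parts$errors[1, ])
  sc <- score_recovery(errs, poly, ds$truth)
  expect_equal(sc$status$recall, (k - 1) / k)
  expect_equal(sc$status$fn, 1L)
  perfect <- score_recovery(parts$errors, parts$polymorphisms, ds$truth)
  expect_equal(perfect$status$f1, 1)
})

test_that("run_pipeline wires the whole chain from files", {
  dir <- tempfile("synthPipe")
  ds <- generate_dataset(scaled_synth(seed = 16), outdir = dir)
  out <- run_pipeline(
    focal_vcf = ds$files[["focal"]],
    panel_vcfs = ds$files[grep("N2_panel", names(ds$files))],
    outgroup_vcfs = c(ds$files[["outgroup_1"]], ds$files[["outgroup_2"]]),
    fasta = ds$files[["ref"]], gff3 = ds$files[["gff"]])
  expect_equal(nrow(out$errors) + nrow(out$polymorphisms) +
                 nrow(out$discarded), nrow(ds$focal))
  sc <- score_recovery(out$errors, out$polymorphisms, ds$truth)
  expect_equal(sc$status$f1, 1)
  expect_equal(sc$ancestral$accuracy, 1)
  expect_true(all(out$polymorphisms$effect %in%
                    domestiscan:::EFFECT_SEVERITY))
})
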