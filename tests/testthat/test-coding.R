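test_that("build_cds concatenates exons and mirrors on the minus strand", {
  gnm <- genome(c(I = "ATGAAATTTCGATAAGGC"))
  g_plus <- gene_model("g", "g.t1", "I", "+",
                       data.frame(start = c(1, 10), end = c(6, 15)))
  cds <- build_cds(g_plus, gnm)
  expect_equal(cds$seq, "ATGAAACGATAA")
  expect_equal(cds$map, c(1:6, 10:15))

  g_minus <- gene_model("g", "g.t1", "I", "-",
                        data.frame(start = c(1, 10), end = c(6, 15)))
  cdsm <- build_cds(g_minus, gnm)
  expect_equal(cdsm$seq, oracle_cds(g_minus, gnm))
  expect_equal(cdsm$map, rev(c(1:6, 10:15)))

  g_out <- gene_model("g", "g.t1", "I", "+",
                      data.frame(start = 10, end = 99))
  expect_error(build_cds(g_out, gnm), "bounds")
})

test_that("built CDS equals the per-base walk oracle on random genes", {
  set.seed(5)
  gnm <- toy_genome(len = 1500)
  for (i in 1:25) {
    g <- random_gene(paste0("g", i), "I", 10, 1400)
    expect_identical(build_cds(g, gnm)$seq, oracle_cds(g, gnm),
                     info = paste("gene", i, g$strand))
  }
})

test_that("SNP effects hit the canonical categories", {
  #             cds: ATG TAC TTT TAA
  gnm <- genome(c(I = paste0("AAAAA", "ATGTACTTTTAA", "AAAAA")))
  g <- gene_model("g", "g.t1", "I", "+", data.frame(start = 6, end = 17),
                  utr_exons = data.frame(start = c(3, 18), end = c(5, 20)))
  eff <- function(pos, alt) {
    ref <- substr(gnm$sequences[["I"]], pos, pos)
    classify_snp_effect(make_call("I", pos, ref, alt)[1, ], list(g),
                        gnm)$category
  }
  expect_equal(eff(11, "A"), "stop_gained")       # TAC -> TAA
  expect_equal(eff(14, "C"), "synonymous")        # TTT -> TTC (Phe)
  expect_equal(eff(12, "G"), "nonsynonymous")     # TAC -> TAG? no: pos12 ..
  expect_equal(eff(16, "C"), "stop_lost")         # TAA -> TCA
  expect_equal(eff(4, "C"), "utr")
  expect_equal(eff(1, "C"), "intergenic")
  # ref mismatch is an input inconsistency
  expect_error(classify_snp_effect(make_call("I", 11, "G", "A")[1, ],
                                   list(g), gnm), "mismatch")
})

test_that("random SNP consequences match the mutant-translation oracle", {
  set.seed(99)
  gnm <- toy_genome(len = 2000)
  genes <- list(random_gene("gA", "I", 10, 600),
                random_gene("gB", "I", 700, 1300, strand = "-"),
                random_gene("gC", "I", 1400, 1900))
  n_checked <- 0
  for (i in 1:300) {
    g <- genes[[sample(3, 1)]]
    span <- range(c(g$cds_exons$start - 10, g$cds_exons$end + 10))
    pos <- sample(span[1]:span[2], 1)
    ref <- substr(gnm$sequences[["I"]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_snp_effect(make_call("I", pos, ref, alt)[1, ],
                               list(g), gnm)$category
    expect_equal(got, oracle_snp_category("I", pos, alt, g, gnm),
                 info = sprintf("pos %d %s>%s strand %s", pos, ref, alt,
                                g$strand))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})

test_that("strand equivalence: mirrored construct gives the same category", {
  set.seed(13)
  s <- rand_seq(200)
  gnm_f <- genome(c(I = s))
  gnm_r <- genome(c(I = paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                           "")[[1]]), collapse = "")))
  L <- 200
  cds <- data.frame(start = 30, end = 119)               # 90 bp, one exon
  g_f <- gene_model("g", "g.t1", "I", "+", cds)
  g_r <- gene_model("g", "g.t1", "I", "-",
                    data.frame(start = L - cds$end + 1, end = L - cds$start + 1))
  for (i in 1:40) {
    pos <- sample(30:119, 1)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mirror_pos <- L - pos + 1
    eff_f <- classify_snp_effect(make_call("I", pos, ref, alt)[1, ],
                                 list(g_f), gnm_f)$category
    eff_r <- classify_snp_effect(
      make_call("I", mirror_pos, chartr("ACGT", "TGCA", ref),
                chartr("ACGT", "TGCA", alt))[1, ], list(g_r),
      gnm_r)$category
    expect_equal(eff_f, eff_r, info = paste("pos", pos))
  }
})

test_that("indel consequences: frameshift, single-aa, pseudogene rescue", {
  gnm <- genome(c(I = paste0(strrep("A", 9), "ATGTACTTTCCCTAA",
                             strrep("A", 9))))
  g <- gene_model("g", "g.t1", "I", "+", data.frame(start = 10, end = 24))
  pg <- gene_model("pg", "pg.t1", "I", "+", data.frame(start = 10, end = 24),
                   biotype = "pseudogene")
  ins1 <- make_call("I", 12, "", "C", vtype = "small_ins")
  expect_equal(classify_indel_effect(ins1[1, ], list(g), gnm)$category,
               "frameshift")
  ins3 <- make_call("I", 12, "", "CGT", vtype = "small_ins")
  expect_equal(classify_indel_effect(ins3[1, ], list(g), gnm)$category,
               "inframe_single_aa")
  del2 <- make_call("I", 13, "CT", "", vtype = "small_del")
  expect_equal(classify_indel_effect(del2[1, ], list(g), gnm)$category,
               "frameshift")
  expect_equal(classify_indel_effect(ins1[1, ], list(pg), gnm)$category,
               "pseudogene_hit")
  before <- make_call("I", 3, "", "C", vtype = "small_ins")
  expect_equal(classify_indel_effect(before[1, ], list(g), gnm)$category,
               "intergenic")
})

test_that("boundary-spanning deletions are flagged frameshifts", {
  gnm <- toy_genome(len = 300)
  g <- gene_model("g", "g.t1", "I", "+",
                  data.frame(start = c(50, 100), end = c(79, 129)))
  # deletion straddling the end of exon 1
  del <- make_call("I", 78, substr(gnm$sequences[["I"]], 78, 80), "",
                   vtype = "small_del")
  eff <- classify_indel_effect(del[1, ], list(g), gnm)
  expect_equal(eff$category, "frameshift")
  expect_true(eff$boundary)
  intron_del <- make_call("I", 85, substr(gnm$sequences[["I"]], 85, 86), "",
                          vtype = "small_del")
  expect_equal(classify_indel_effect(intron_del[1, ], list(g),
                                     gnm)$category, "intronic")
})

test_that("multi-transcript genes report the most severe consequence", {
  gnm <- genome(c(I = paste0(strrep("A", 9), "ATGTACTTTCCCTAA",
                             strrep("T", 30))))
  coding <- gene_model("g", "g.t1", "I", "+", data.frame(start = 10,
                                                         end = 24))
  # second transcript where position 12 is intronic
  alt_tx <- gene_model("g", "g.t2", "I", "+",
                       data.frame(start = c(10, 19), end = c(12, 24)),
                       utr_exons = data.frame(start = 25, end = 30))
  ins <- make_call("I", 12, "", "C", vtype = "small_ins")
  expect_equal(classify_indel_effect(ins[1, ], list(alt_tx, coding),
                                     gnm)$category, "frameshift")
})

test_that("summarize_effects counts categories and exonic subtotals", {
  ds <- generate_dataset(scaled_synth(seed = 31))
  ann <- annotate_effects(ds$focal, ds$genes, ds$genome)
  s <- summarize_effects(ann, ann)
  expect_equal(sum(s$errors), nrow(ds$focal))
  expect_identical(s$errors, s$polymorphisms)
  expect_true(s$exonic$errors[["cds_plus_utr"]] >=
                s$exonic$errors[["cds_only"]])
  s0 <- summarize_effects(NULL, NULL)
  expect_true(all(s0$errors == 0) && all(s0$polymorphisms == 0))
})
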