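test_that("read_vcf infers types, converts coordinates, enforces QUAL", {
  f <- write_vcf_text(c(
    "V\t3556386\t.\tT\tTC\t80\t.\t.",
    "X\t100\t.\tAC\tA\t60\t.\t.",
    "I\t50\t.\tG\tA\t77\t.\tAMBIG=1",
    "II\t10\t.\tA\tATTTTTT\t40\t.\t."))
  calls <- read_vcf(f, "LSJ1")
  expect_s3_class(calls, "variant_calls")
  expect_equal(nrow(calls), 4L)

  ins <- calls[calls$chrom == "V", ]
  expect_equal(ins$vtype, "small_ins")
  expect_equal(ins$length, 1L)
  expect_equal(ins$pos, 3556386L)   # insertion occurs after this coordinate
  expect_equal(ins$alt_allele, "C")

  del <- calls[calls$chrom == "X", ]
  expect_equal(del$vtype, "small_del")
  expect_equal(del$length, 1L)
  expect_equal(del$pos, 101L)       # first deleted base, after the anchor
  expect_equal(del$ref_allele, "C")

  expect_true(calls$ambiguous[calls$chrom == "I"])
  expect_false(calls$ambiguous[calls$chrom == "V"])
  expect_equal(calls$vtype[calls$chrom == "II"], "large_ins")
  expect_equal(calls$source_strain, rep("LSJ1", 4))
})

test_that("read_vcf rejects malformed records with the line number", {
  expect_error(read_vcf(write_vcf_text("I\t100\t.\tA\tA\t50\t.\t.")),
               "line 3.*REF equals ALT")
  expect_error(read_vcf(write_vcf_text("I\t100\t.\tA\tG\t.\t.\t.")),
               "QUAL")
  expect_error(read_vcf(write_vcf_text("I\t100\t.\tA\tG,T\t50\t.\t.")),
               "multi-allelic")
  expect_error(read_vcf(write_vcf_text("I\tx\t.\tA\tG\t50\t.\t.")),
               "POS")
})

test_that("deletion coordinate convention matches a brute-force string edit", {
  s0 <- "AAAACGGGGG"
  # VCF semantics: replace "AC" at pos 4 by "A", i.e. drop the C at 5
  edited_vcf <- apply_vcf_record(s0, 4L, "AC", "A")
  f <- write_vcf_text("I\t4\t.\tAC\tA\t60\t.\t.")
  call <- read_vcf(f)[1, ]
  expect_equal(call$pos, 5L)
  expect_equal(call$ref_allele, "C")
  edited_dialect <- apply_dialect_call(s0, call)
  expect_identical(edited_dialect, edited_vcf)
})

test_that("dialect edits equal VCF-anchored edits for random indels", {
  set.seed(42)
  for (rep in 1:50) {
    s0 <- rand_seq(60)
    pos <- sample(10:40, 1)
    len <- sample(1:3, 1)
    if (runif(1) < 0.5) {   # deletion record
      ref <- substr(s0, pos, pos + len)
      rec <- sprintf("I\t%d\t.\t%s\t%s\t60\t.\t.", pos, ref,
                     substr(ref, 1, 1))
    } else {                # insertion record
      ins <- rand_seq(len)
      rec <- sprintf("I\t%d\t.\t%s\t%s\t60\t.\t.", pos,
                     substr(s0, pos, pos), paste0(substr(s0, pos, pos), ins))
    }
    fields <- strsplit(rec, "\t")[[1]]
    call <- read_vcf(write_vcf_text(rec))[1, ]
    expect_identical(apply_dialect_call(s0, call),
                     apply_vcf_record(s0, as.integer(fields[2]), fields[4],
                                      fields[5]))
  }
})

test_that("VCF round-trip is exact for every vtype", {
  calls <- variant_calls(
    chrom = c("I", "I", "II", "II", "X"),
    pos = c(20L, 35L, 50L, 61L, 80L),
    ref_allele = c("A", "", "TG", "", "CCCCCC"),
    alt_allele = c("G", "TT", "", "ACGTAGG", ""),
    vtype = c("snp", "small_ins", "small_del", "large_ins", "large_del"),
    quality = c(88, 51.5, 25, 36, 1),
    ambiguous = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    source_strain = "LSJ1",
    anchor_base = c(NA, "A", "C", "G", "T"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, f)
  back <- read_vcf(f, "LSJ1")
  for (col in c("chrom", "pos", "ref_allele", "alt_allele", "vtype",
                "length", "quality", "ambiguous", "anchor_base"))
    expect_identical(back[[col]], calls[[col]], info = col)
})

test_that("variant_calls validates its invariants", {
  expect_error(make_call("I", 5, "A", "A"), "differ")
  expect_error(make_call("I", 0, "A", "G"), "pos")
  expect_error(make_call("I", 5, "A", "G", quality = -1),
               "non-negative")
  expect_error(variant_calls("I", 5, "", "ACGT", vtype = "small_ins",
                             quality = 9, ambiguous = FALSE),
               "1-3 bp")
  expect_warning(variant_calls("I", 5, "", "ACGT", vtype = "large_ins",
                               quality = 9, ambiguous = FALSE),
                 "detection bounds")
})

test_that("read_fasta reads, uppercases, and totals lengths", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgtacgtac", ">chr2", "GGGGGCCCCC"), f)
  g <- read_fasta(f)
  expect_equal(g$L, 20L)
  expect_identical(g$sequences[["chr1"]], "ACGTACGTAC")

  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("read_gff3 builds gene models with strand, order, and biotype", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "I\tsynth\tgene\t10\t100\t.\t+\t.\tID=gA;biotype=protein_coding",
    "I\tsynth\tmRNA\t10\t100\t.\t+\t.\tID=gA.t1;Parent=gA",
    "I\tsynth\tCDS\t60\t92\t.\t+\t0\tParent=gA.t1",
    "I\tsynth\tCDS\t20\t40\t.\t+\t0\tParent=gA.t1",
    "II\tsynth\tpseudogene\t10\t100\t.\t-\t.\tID=gB",
    "II\tsynth\tmRNA\t10\t100\t.\t-\t.\tID=gB.t1;Parent=gB",
    "II\tsynth\tCDS\t10\t100\t.\t-\t0\tParent=gB.t1"), f)
  genes <- read_gff3(f)
  expect_named(genes, c("gA.t1", "gB.t1"))
  # exons stored in genomic order even though the file lists them reversed
  expect_equal(genes[["gA.t1"]]$cds_exons$start, c(20L, 60L))
  expect_equal(genes[["gB.t1"]]$strand, "-")
  # pseudogene biotype inherited from the parent feature type
  expect_equal(genes[["gB.t1"]]$biotype, "pseudogene")

  writeLines(c("##gff-version 3",
               "I\tsynth\tCDS\t20\t40\t.\t+\t0\tParent=nosuch"), f)
  expect_error(read_gff3(f), "parent")
})

test_that("gene_model enforces exon ordering invariants", {
  expect_error(gene_model("g", "t", "I", "+",
                          data.frame(start = c(1, 5), end = c(6, 9))),
               "non-overlapping")
  expect_warning(gene_model("g", "t", "I", "+",
                            data.frame(start = 1, end = 4)),
                 "divisible by 3")
})

test_that("write_variant_table emits the published dialect", {
  calls <- variant_calls(
    chrom = c("V", "X", "I"),
    pos = c(3556386L, 3293918L, 77L),
    ref_allele = c("", "C", "T"),
    alt_allele = c("C", "", "G"),
    vtype = c("small_ins", "small_del", "snp"),
    quality = 99, ambiguous = FALSE, source_strain = "LSJ1")
  calls$gene_name <- c("grd-30", "hsp-2", NA)
  calls$gene_function <- c("ground-like related", "heat shock protein", NA)
  calls$ancestral <- c("LSJ1", "LSJ1", "N2")
  f <- tempfile(fileext = ".tsv")
  write_variant_table(calls, f)
  lines <- readLines(f, encoding = "UTF-8")
  expect_equal(lines[1], paste("Chr", "Variation", "Gene Name",
                               "Gene Function", "LSJ1_allele",
                               "Ancestral Status", sep = "\t"))
  expect_match(lines[2], "^V\t3556386\tgrd-30\t.*\t\\+C/\\+C\tLSJ1$")
  expect_match(lines[3], "\t−c/−c\t", fixed = TRUE)
  expect_match(lines[4], "\tG/G\t", fixed = TRUE)     # blanks, no crash
  expect_equal(strsplit(lines[4], "\t")[[1]][3], "")

  write_variant_table(empty_calls <- calls[0, ], f)
  expect_equal(length(readLines(f)), 1L)              # header only
})
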