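# annotation loading, sequence resolution and the exclusion database

write_lines <- function(x, path) { writeLines(x, path); path }

gff_line <- function(chrom, start1, end1, strand, name) {
  sprintf("%s\ttest\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
          chrom, start1, end1, strand, paste0(name, "_", start1), name)
}

test_that("records sharing a name merge into one multi-locus miRNA", {
  dir <- withr::local_tempdir()
  gff <- write_lines(c(
    "##gff-version 3",
    gff_line("chr7", 130562226, 130562248, "+", "hsa-mir-29b"),
    gff_line("chr1", 207975795, 207975817, "+", "hsa-mir-29b"),
    gff_line("chr9", 21512157, 21512177, "+", "hsa-mir-31")
  ), file.path(dir, "ann.gff3"))
  fa <- file.path(dir, "mature.fa")
  write_fasta_chr(c("hsa-mir-29b" = "TAGCACCATTTGAAATCAGTGTT",
                    "hsa-mir-31" = "AGGCAAGATGCTGGCATAGCT"), fa)

  m <- load_mirna_annotation(gff, mature_fasta = fa)
  expect_equal(nrow(m), 2L)
  r29 <- m[m$name == "hsa-mir-29b", ]
  expect_equal(r29$n_loci, 2L)
  loci <- attr(m, "loci")
  l29 <- loci[loci$name == "hsa-mir-29b", ]
  # printed 1-based inclusive coordinates become 0-based half-open
  expect_setequal(l29$chrom, c("chr7", "chr1"))
  expect_equal(sort(l29$start), sort(c(130562226L, 207975795L) - 1L))
  expect_equal(sort(l29$end), sort(c(130562248L, 207975817L)))
})

test_that("mature sequences resolve from the genome with strand handling", {
  dir <- withr::local_tempdir()
  ins <- "ACGTACGTACGTACGTACGTAC"            # 22 nt planted sequence
  genome <- paste0(strrep("G", 30), ins, strrep("C", 30))
  write_fasta_chr(c(chrZ = genome), file.path(dir, "genome.fa"))
  gff <- write_lines(c(
    "##gff-version 3",
    gff_line("chrZ", 31, 52, "+", "mir-plus"),
    gff_line("chrZ", 31, 52, "-", "mir-minus")
  ), file.path(dir, "ann.gff3"))

  m <- load_mirna_annotation(gff, genome_fasta = file.path(dir, "genome.fa"))
  expect_equal(m$mature_seq[m$name == "mir-plus"], ins)
  # hand reverse-complement of the planted 22-mer, frozen
  expect_equal(m$mature_seq[m$name == "mir-minus"],
               "GTACGTACGTACGTACGTACGT")
})

test_that("a mature FASTA takes precedence over genome extraction", {
  dir <- withr::local_tempdir()
  genome <- paste0(strrep("G", 30), "ACGTACGTACGTACGTACGTAC", strrep("C", 30))
  write_fasta_chr(c(chrZ = genome), file.path(dir, "genome.fa"))
  write_fasta_chr(c("mir-x" = "uggaauguaaagaaguauguau"),  # RNA input
                  file.path(dir, "mature.fa"))
  gff <- write_lines(c("##gff-version 3",
                       gff_line("chrZ", 31, 52, "+", "mir-x")),
                     file.path(dir, "ann.gff3"))
  m <- load_mirna_annotation(gff, mature_fasta = file.path(dir, "mature.fa"),
                             genome_fasta = file.path(dir, "genome.fa"))
  expect_equal(m$mature_seq, "TGGAATGTAAAGAAGTATGTAT")  # U -> T, uppercased
})

test_that("a named miRNA without a resolvable sequence is a hard error", {
  dir <- withr::local_tempdir()
  gff <- write_lines(c("##gff-version 3",
                       gff_line("chr1", 100, 121, "+", "mir-missing")),
                     file.path(dir, "ann.gff3"))
  write_fasta_chr(c("mir-other" = "ACGTACGTACGTACGTACGTAC"),
                  file.path(dir, "mature.fa"))
  expect_error(
    load_mirna_annotation(gff, mature_fasta = file.path(dir, "mature.fa")),
    "mir-missing")
})

test_that("annotation round-trips and is order-independent", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_mirnas = 6L, n_multilocus = 2L, n_exons = 3L,
                    exon_len = 120L, reads_per_sample = 10L, seed = 3L)
  mr <- make_reference(cfg, dir = dir)
  m1 <- load_mirna_annotation(mr$files[["annotation"]],
                              mature_fasta = mr$files[["mature"]])
  # round-trip: write back out, reload, identical collection
  out2 <- file.path(dir, "rt.gff3")
  write_mirna_annotation(m1, out2, mature_fasta = file.path(dir, "rt.fa"))
  m2 <- load_mirna_annotation(out2, mature_fasta = file.path(dir, "rt.fa"))
  expect_equal(m2, m1, ignore_attr = FALSE)

  # shuffled annotation lines yield the same bundle
  ln <- readLines(mr$files[["annotation"]])
  hdr <- grepl("^#", ln)
  shuf <- c(ln[hdr], withr::with_seed(9, sample(ln[!hdr])))
  out3 <- file.path(dir, "shuf.gff3")
  writeLines(shuf, out3)
  m3 <- load_mirna_annotation(out3, mature_fasta = mr$files[["mature"]])
  expect_equal(m3$name, m1$name)
  expect_equal(m3$mature_seq, m1$mature_seq)
  expect_equal(attr(m3, "loci"), attr(m1, "loci"))
})

test_that("genome-extracted sequences match the annotation's loci", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_mirnas = 5L, n_multilocus = 1L, n_exons = 2L,
                    exon_len = 100L, reads_per_sample = 10L, seed = 5L)
  mr <- make_reference(cfg, dir = dir)
  m_gen <- load_mirna_annotation(mr$files[["annotation"]],
                                 genome_fasta = mr$files[["genome"]])
  expect_equal(setNames(m_gen$mature_seq, m_gen$name),
               setNames(mr$bundle$mirnas$mature_seq, mr$bundle$mirnas$name))
})

test_that("exclusion lookups agree with a brute-force scan", {
  withr::with_seed(11, {
    exons <- random_dna(rep(50L, 1000L))
    db <- exclusion_db(exons)
    queries <- c(
      random_dna(rep(22L, 120L)),                         # mostly absent
      vapply(sample(exons, 80L), function(e) {
        st <- sample.int(50L - 21L, 1L)
        substr(e, st, st + 21L)                           # planted 22-mers
      }, character(1), USE.NAMES = FALSE)
    )
    got <- db_contains(db, queries)
    want <- vapply(queries, function(q) brute_contains(exons, q),
                   logical(1), USE.NAMES = FALSE)
    expect_identical(got, want)
    expect_true(any(want) && !all(want))  # both outcomes exercised
  })
})

test_that("central k-mers of an exon are contained, absent k-mers are not", {
  exon <- paste0(strrep("AC", 20), "TGGATTCGAACCGTAGCATGCA", strrep("GT", 19))
  db <- exclusion_db(c(e1 = exon))
  expect_true(db_contains(db, substr(exon, 40, 61)))
  expect_false(db_contains(db, "TTTTGGGGCCCCAAAATTTTGG"))
})

test_that("an empty exclusion FASTA warns and excludes nothing", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.fa"); file.create(f)
  expect_warning(db <- load_exclusion_db(f), "no-op")
  expect_false(any(db_contains(db, c("ACGTACGTACGTACGT"))))
})
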