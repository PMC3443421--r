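# tag classification: exclusion precedence, miRNA containment matching,
# and the C/M bookkeeping feeding the RPKM statistic

test_that("a tag equal to a mature sequence is assigned that miRNA", {
  b <- toy_bundle()
  tags <- data.frame(seq = b$mirnas$mature_seq[1], count = 5L)
  asg <- classify_tags(tags, b)
  expect_identical(asg$status, "MIRNA")
  expect_identical(asg$hits, "sim-mir-t1")
  expect_identical(asg$n_hits, 1L)
})

test_that("mRNA exclusion takes precedence over a miRNA match", {
  b <- toy_bundle(decoy = TRUE)  # exon_1 contains sim-mir-t1's sequence
  tags <- data.frame(seq = b$mirnas$mature_seq[1:2], count = c(3L, 4L))
  asg <- classify_tags(tags, b)
  expect_identical(asg$status[1], "EXCLUDED_MRNA")
  expect_identical(asg$hits[1], "")       # hits stay empty despite the match
  expect_identical(asg$status[2], "MIRNA")
})

test_that("adding a tag's sequence to the exon set can only exclude it", {
  b <- toy_bundle()
  tag <- b$mirnas$mature_seq[3]
  before <- classify_tags(data.frame(seq = tag, count = 1L), b)$status
  b2 <- reference_bundle(b$mirnas,
                         exclusion_db(c(b$exclusion$seqs, extra = tag)))
  after <- classify_tags(data.frame(seq = tag, count = 1L), b2)$status
  expect_identical(before, "MIRNA")
  expect_identical(after, "EXCLUDED_MRNA")
})

test_that("containment matching works in both directions", {
  b <- toy_bundle()
  m <- b$mirnas$mature_seq[2]
  tags <- data.frame(
    seq = c(substr(m, 3, 20),                       # tag inside mature
            paste0("GT", m, "CA"),                  # mature inside tag
            "CGCGCGCGATATATATCGCG"),                # neither
    count = c(1L, 1L, 1L))
  asg <- classify_tags(tags, b)
  expect_identical(asg$status, c("MIRNA", "MIRNA", "UNALIGNED"))
  expect_identical(asg$hits[1:2], rep("sim-mir-t2", 2))
})

test_that("classification agrees with the brute-force oracle", {
  withr::with_seed(31, {
    cfg <- sim_config(n_mirnas = 12L, n_multilocus = 3L, n_exons = 8L,
                      exon_len = 120L, reads_per_sample = 10L, seed = 31L)
    b <- make_reference(cfg)$bundle
    mat <- setNames(b$mirnas$mature_seq, b$mirnas$name)
    exons <- b$exclusion$seqs
    tags <- unique(c(
      random_dna(rep(22L, 200L)),
      unname(mat),
      vapply(mat, function(m) substr(m, 2, nchar(m) - 1L), character(1)),
      paste0("GG", mat, "TT"),
      vapply(sample(exons, 100L, replace = TRUE), function(e) {
        st <- sample.int(nchar(e) - 21L, 1L); substr(e, st, st + 21L)
      }, character(1), USE.NAMES = FALSE)
    ))
    asg <- classify_tags(data.frame(seq = tags, count = 1L), b)
    for (i in seq_along(tags)) {
      want <- brute_classify(tags[i], exons, mat)
      expect_identical(asg$status[i], want$status)
      got_hits <- if (nzchar(asg$hits[i])) {
        sort(strsplit(asg$hits[i], ",", fixed = TRUE)[[1]])
      } else character(0)
      expect_identical(got_hits, want$hits)
    }
    expect_true(all(c("EXCLUDED_MRNA", "MIRNA", "UNALIGNED") %in% asg$status))
  })
})

test_that("classification is independent of tag order", {
  ts <- toy_sim(reads = 1500L, seed = 37L)
  pp <- preprocess_reads(ts$sim$fastq[["a"]])
  a1 <- classify_tags(pp$tags, ts$bundle)
  shuf <- withr::with_seed(2, sample.int(nrow(pp$tags)))
  a2 <- classify_tags(pp$tags[shuf, ], ts$bundle)
  a2 <- a2[order(a2$seq, method = "radix"), ]
  rownames(a2) <- NULL
  expect_equal(a2, a1)
})

test_that("C and M bookkeeping follows hand enumeration", {
  # three miRNAs: m1 single locus, m2 two loci, plus a shared-core pair
  z <- "GGATTCGAACCGTAGCAT"                      # 18 nt shared core
  mat <- c(m1 = "TGCATGCATGCATGCATGCATG",
           m2 = "ACCGTTACCGGTTAACCGGTTA",
           mA = paste0("CCG", z), mB = paste0(z, "ATT"))
  mirnas <- data.frame(name = names(mat), mature_seq = unname(mat),
                       length = nchar(mat), n_loci = c(1L, 2L, 1L, 1L),
                       stringsAsFactors = FALSE)
  attr(mirnas, "loci") <- data.frame(
    name = c("m1", "m2", "m2", "mA", "mB"),
    chrom = paste0("c", 1:5), start = 0L,
    end = nchar(mat)[c(1, 2, 2, 3, 4)], strand = "+",
    stringsAsFactors = FALSE)
  b <- reference_bundle(mirnas, exclusion_db(character(0)))

  tags <- data.frame(seq = c(mat[["m1"]], mat[["m2"]], z), count = c(7L, 10L, 4L))
  asg <- classify_tags(tags, b)
  expect_identical(asg$n_hits, c(1L, 1L, 2L))     # z hits both mA and mB

  cm <- mirna_hit_multiplicity(asg, b)
  expect_equal(setNames(cm$C, cm$name), c(m1 = 7, m2 = 10, mA = 4, mB = 4))
  expect_equal(setNames(cm$M, cm$name), c(m1 = 1, m2 = 2, mA = 1, mB = 1))

  # optional per-read splitting divides the shared tag's count evenly
  cm2 <- mirna_hit_multiplicity(asg, b, split_multi_hits = TRUE)
  expect_equal(setNames(cm2$C, cm2$name), c(m1 = 7, m2 = 10, mA = 2, mB = 2))

  # tag-count mode counts unique tags once
  cm3 <- mirna_hit_multiplicity(asg, b, count_mode = "tags")
  expect_equal(setNames(cm3$C, cm3$name), c(m1 = 1, m2 = 1, mA = 1, mB = 1))
})
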