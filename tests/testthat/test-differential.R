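# signed fold convention, sentinel, threshold calling, ranking, and the
# on-disk differential tables

test_that("signed_fold reproduces the published convention", {
  # printed pairs and folds from the shipped tables, full precision
  expect_equal(signed_fold(347.53278, 15717.314), 45.22541442,
               tolerance = 1e-8)
  expect_equal(signed_fold(358.35938, 26.206163), -13.67462226,
               tolerance = 1e-8)
  expect_equal(signed_fold(3.3418648, 3083.2217), 922.6051575,
               tolerance = 1e-8)
  expect_equal(signed_fold(17177.37, 6494.583), -2.644876507,
               tolerance = 1e-8)
  expect_identical(signed_fold(0, 495.64316), 9.90e307)   # zero denominator
  expect_identical(signed_fold(495.64316, 0), -9.90e307)
  expect_identical(signed_fold(7.5, 7.5), 1)              # identity ratio
  expect_true(is.na(signed_fold(0, 0)))
})

test_that("signed_fold is antisymmetric with magnitude at least 1", {
  withr::with_seed(51, {
    a <- c(rexp(200, 1 / 500), 0, 123.4)
    b <- c(rexp(200, 1 / 500), 567.8, 0)
    f_ab <- signed_fold(a, b)
    f_ba <- signed_fold(b, a)
    expect_equal(f_ab, -f_ba)
    expect_true(all(abs(f_ab) >= 1))
  })
})

test_that("calling applies the abundance (max over conditions) and fold rules", {
  cfg <- diff_config()
  qa <- data.frame(name = c("x1", "x2", "x3", "x4", "x5"),
                   rpkm = c(50, 200, 0, 1.24, 400))
  qb <- data.frame(name = c("x1", "x2", "x3", "x4", "x5"),
                   rpkm = c(60, 250, 495.6, 1174.4, 220))
  d <- call_differential(qa, qb, cfg)
  d <- d[match(paste0("x", 1:5), d$name), ]
  expect_identical(d$side,
                   c("NONE",        # both below 100
                     "NONE",        # fold 1.25 < 1.5
                     "B_ENRICHED",  # sentinel, abundance via max
                     "B_ENRICHED",  # one condition far below 100 is fine
                     "A_ENRICHED"))
  expect_identical(d$is_sentinel, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(d$side != "NONE", d$passes_abundance & d$passes_fold)
})

test_that("the fold threshold is inclusive at the published boundary rows", {
  d <- call_differential(
    data.frame(name = c("b140", "b151"), rpkm = c(334.1866, 610.3607)),
    data.frame(name = c("b140", "b151"), rpkm = c(501.82477, 405.608)))
  expect_identical(sort(d$side), c("A_ENRICHED", "B_ENRICHED"))
})

test_that("raising either threshold never adds a call", {
  withr::with_seed(53, {
    nm <- sprintf("m%03d", 1:300)
    qa <- data.frame(name = nm, rpkm = rexp(300, 1 / 300) *
                       rbinom(300, 1, 0.9))
    qb <- data.frame(name = nm, rpkm = rexp(300, 1 / 300) *
                       rbinom(300, 1, 0.9))
    base <- call_differential(qa, qb, diff_config())
    called0 <- base$name[base$side != "NONE"]
    for (cfg in list(diff_config(rpkm_threshold = 200),
                     diff_config(fold_threshold = 2),
                     diff_config(rpkm_threshold = 300, fold_threshold = 3))) {
      d <- call_differential(qa, qb, cfg)
      expect_true(all(d$name[d$side != "NONE"] %in% called0))
    }
  })
})

test_that("mismatched miRNA universes are a hard error naming the difference", {
  qa <- data.frame(name = c("a", "b"), rpkm = c(1, 2))
  qb <- data.frame(name = c("a", "c"), rpkm = c(1, 2))
  expect_error(call_differential(qa, qb), "only in A: \\[b\\]")
})

test_that("ranking is ordinal with lexicographic tie-breaks", {
  q <- data.frame(name = c("mz", "ma", "mb"), rpkm = c(10, 5, 5))
  expect_identical(rank_mirnas(q), c(mz = 1L, ma = 2L, mb = 3L))
  shuf <- q[c(2, 3, 1), ]
  expect_identical(rank_mirnas(shuf)[names(rank_mirnas(q))], rank_mirnas(q))
})

test_that("diff tables round-trip and keep the published ordering", {
  rows <- load_printed_tables()
  d <- call_differential(
    data.frame(name = rows$name, rpkm = rows$pb_rpkm),
    data.frame(name = rows$name, rpkm = rows$cb_rpkm))
  dir <- withr::local_tempdir()
  paths <- write_diff_tables(d, dir)
  b_tab <- read.delim(paths[["b_enriched"]], comment.char = "#")
  a_tab <- read.delim(paths[["a_enriched"]], comment.char = "#")
  # B-enriched: sentinel row first, weakest fold last (published order)
  expect_identical(b_tab$name[1], "hsa-mir-136")
  expect_identical(b_tab$name[nrow(b_tab)], "hsa-mir-140-5p")
  expect_identical(a_tab$name[1], "hsa-let-7b*")  # most negative fold first
  # round-trip reproduces the called records
  back <- read_diff_tables(dir)
  called <- d[d$side != "NONE", ]
  back <- back[match(called$name, back$name), ]
  expect_equal(back$rpkm_a, called$rpkm_a, tolerance = 1e-12)
  expect_equal(back$rpkm_b, called$rpkm_b, tolerance = 1e-12)
  expect_equal(back$fold, called$fold, tolerance = 1e-12)
  expect_identical(back$side, called$side)

  # empty record set gives headers-only files
  d0 <- d[0, ]
  attr(d0, "cfg") <- attr(d, "cfg")
  p0 <- write_diff_tables(d0, file.path(dir, "empty"))
  expect_identical(nrow(read.delim(p0[["b_enriched"]], comment.char = "#")), 0L)
})
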