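# Two-condition differential calling on per-miRNA RPKMs.
#
# Fold convention (condition A = PB, condition B = CB in the shipped
# tables): fold = B/A when B >= A, and -(A/B) otherwise, so |fold| >= 1
# always and the sign encodes the enriched side (positive = B). A zero
# denominator yields the finite sentinel 9.90E+307 with the matching
# sign; records carry an explicit is_sentinel flag so downstream code
# never treats the sentinel as a real ratio.
#
# A miRNA is called differential when max(rpkm_a, rpkm_b) exceeds the
# abundance threshold (strictly; RPKM > 100 by default — the max, not
# both, since published rows include a zero-RPKM condition) and
# |fold| >= fold threshold (inclusive; 1.5 by default, the published
# boundary rows sit exactly at 1.50).

#' Differential-calling configuration
#'
#' @param rpkm_threshold abundance filter: called miRNAs need
#'   `max(rpkm_a, rpkm_b) > rpkm_threshold`.
#' @param fold_threshold fold filter: `|fold| >= fold_threshold`.
#' @param sentinel finite value standing in for an infinite ratio when
#'   one condition's RPKM is zero.
#' @return a `DiffConfig` list.
#' @export
diff_config <- function(rpkm_threshold = 100, fold_threshold = 1.5,
                        sentinel = 9.90e307) {
  stopifnot(rpkm_threshold > 0, fold_threshold >= 1, sentinel > 0)
  structure(list(rpkm_threshold = rpkm_threshold,
                 fold_threshold = fold_threshold,
                 sentinel = sentinel),
            class = "DiffConfig")
}

#' Signed fold change between two RPKM values
#'
#' `fold = b/a` when `b >= a` (positive, B-enriched) and `-(a/b)`
#' otherwise, so the magnitude is always at least 1. A zero denominator
#' yields `+/- sentinel`; a pair that is zero in both conditions is
#' undefined and returns `NA`.
#'
#' @param a,b RPKM in conditions A and B (vectorized).
#' @param sentinel stand-in for an infinite ratio.
#' @return numeric vector of signed folds.
#' @export
signed_fold <- function(a, b, sentinel = 9.90e307) {
  stopifnot(all(a >= 0), all(b >= 0))
  ifelse(a == 0 & b == 0, NA_real_,
         ifelse(b >= a,
                ifelse(a == 0, sentinel, b / a),
                ifelse(b == 0, -sentinel, -(a / b))))
}

#' Call differentially expressed miRNAs between two conditions
#'
#' @param quants_a,quants_b per-condition data.frames with `name` and
#'   `rpkm` columns (e.g. from [quantify_sample()]); both must cover the
#'   same miRNA universe.
#' @param cfg a [diff_config()].
#' @param log2_fold also emit a plain `log2_fold` column (log2(b/a),
#'   infinite for sentinel rows).
#' @return data.frame, one row per miRNA: `name`, `rpkm_a`, `rpkm_b`,
#'   `fold`, `is_sentinel`, `passes_abundance`, `passes_fold`, `side`
#'   (`B_ENRICHED`/`A_ENRICHED`/`NONE`), `rank_a`, `rank_b`. Rows zero in
#'   both conditions have `fold = NA` and are never called.
#' @export
call_differential <- function(quants_a, quants_b, cfg = diff_config(),
                              log2_fold = FALSE) {
  stopifnot(inherits(cfg, "DiffConfig"))
  if (!setequal(quants_a$name, quants_b$name) ||
      anyDuplicated(quants_a$name) || anyDuplicated(quants_b$name)) {
    only_a <- setdiff(quants_a$name, quants_b$name)
    only_b <- setdiff(quants_b$name, quants_a$name)
    stop("condition universes differ; only in A: [",
         paste(only_a, collapse = ", "), "]; only in B: [",
         paste(only_b, collapse = ", "), "]")
  }
  nm <- sort(unique(quants_a$name), method = "radix")
  a <- quants_a$rpkm[match(nm, quants_a$name)]
  b <- quants_b$rpkm[match(nm, quants_b$name)]

  fold <- signed_fold(a, b, cfg$sentinel)
  is_sentinel <- (a == 0) != (b == 0)  # exactly one zero
  passes_abundance <- pmax(a, b) > cfg$rpkm_threshold
  passes_fold <- !is.na(fold) & abs(fold) >= cfg$fold_threshold
  called <- passes_abundance & passes_fold
  side <- ifelse(!called, "NONE",
                 ifelse(fold > 0, "B_ENRICHED", "A_ENRICHED"))

  out <- data.frame(
    name = nm, rpkm_a = a, rpkm_b = b, fold = fold,
    is_sentinel = is_sentinel,
    passes_abundance = passes_abundance, passes_fold = passes_fold,
    side = side,
    rank_a = unname(rank_mirnas(data.frame(name = nm, rpkm = a))[nm]),
    rank_b = unname(rank_mirnas(data.frame(name = nm, rpkm = b))[nm]),
    stringsAsFactors = FALSE
  )
  if (log2_fold) {
    out$log2_fold <- ifelse(is.na(fold), NA_real_, log2(b / a))
  }
  attr(out, "cfg") <- cfg
  out
}

#' Ordinal RPKM ranks within one condition
#'
#' Rank 1 is the highest RPKM; ties are broken lexicographically by
#' miRNA name so ranking is deterministic and independent of input
#' order. Zero-RPKM miRNAs are ranked too.
#'
#' @param quants data.frame with `name` and `rpkm`.
#' @return named integer vector of ranks.
#' @export
rank_mirnas <- function(quants) {
  stopifnot(nrow(quants) > 0)
  ord <- order(-quants$rpkm, quants$name, method = "radix")
  rk <- integer(nrow(quants))
  rk[ord] <- seq_len(nrow(quants))
  setNames(rk, quants$name)
}

#' Write the two enriched-side differential tables
#'
#' Called records are split by enriched side into two TSVs mirroring the
#' published layout: the B-enriched table sorted by descending fold (the
#' sentinel row, if any, first) and the A-enriched table by ascending
#' fold (most negative first). Thresholds are recorded in leading `#`
#' comment lines.
#'
#' @param records data.frame from [call_differential()].
#' @param dir output directory (created if missing).
#' @return character vector of the two file paths, invisibly.
#' @export
write_diff_tables <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(records, "cfg") %||% diff_config()
  cols <- c("name", "rpkm_a", "rpkm_b", "fold", "is_sentinel",
            "rank_a", "rank_b")
  hdr <- sprintf("# rpkm_threshold=%g fold_threshold=%g sentinel=%g",
                 cfg$rpkm_threshold, cfg$fold_threshold, cfg$sentinel)
  paths <- c(
    b_enriched = file.path(dir, "diff_b_enriched.tsv"),
    a_enriched = file.path(dir, "diff_a_enriched.tsv")
  )
  b <- records[records$side == "B_ENRICHED", cols, drop = FALSE]
  b <- b[order(-b$fold, b$name, method = "radix"), , drop = FALSE]
  a <- records[records$side == "A_ENRICHED", cols, drop = FALSE]
  a <- a[order(a$fold, a$name, method = "radix"), , drop = FALSE]
  for (side in c("b_enriched", "a_enriched")) {
    tab <- if (side == "b_enriched") b else a
    con <- file(paths[[side]], "w")
    writeLines(hdr, con)
    write.table(format(tab, digits = 15, scientific = NA, trim = TRUE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read back differential tables written by [write_diff_tables()]
#'
#' @param dir directory holding the two TSVs.
#' @return data.frame of the called records (both sides), with `side`
#'   reconstructed.
#' @export
read_diff_tables <- function(dir) {
  out <- lapply(c(b_enriched = "diff_b_enriched.tsv",
                  a_enriched = "diff_a_enriched.tsv"), function(f) {
    read.delim(file.path(dir, f), comment.char = "#",
               stringsAsFactors = FALSE)
  })
  out$b_enriched$side <- if (nrow(out$b_enriched)) "B_ENRICHED" else character(0)
  out$a_enriched$side <- if (nrow(out$a_enriched)) "A_ENRICHED" else character(0)
  res <- rbind(out$b_enriched, out$a_enriched)
  res$is_sentinel <- as.logical(res$is_sentinel)
  res
}
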