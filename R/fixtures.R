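# Machine-readable copy of the published differential miRNA tables
# (CB-EPC vs PB-EPC comparison): 54 CB-enriched and 50 PB-enriched rows
# with name, chromosome location(s), PB RPKM, CB RPKM, signed fold and
# per-condition ranks, transcribed verbatim at full printed precision.
# The fixture is the acceptance surface for the fold convention, the
# zero-denominator sentinel and the 104 = 54 + 50 differential counts.

.fixture_md5 <- c(
  table1_cb_enriched.tsv = "ec6545b9063feb5c39de91ab1901a47f",
  table2_pb_enriched.tsv = "26fd8108d8d25548bd456a1b8f24381c"
)

#' Load the published differential miRNA tables
#'
#' Returns the transcribed published tables of the CB-EPC/PB-EPC
#' comparison: 54 CB-enriched plus 50 PB-enriched miRNAs. File integrity
#' is enforced by checksum, so the fixture cannot drift silently.
#'
#' @param which `"both"` (default), `"cb"` (CB-enriched table) or `"pb"`
#'   (PB-enriched table).
#' @return data.frame with columns `name`, `locations` (comma-joined
#'   printed coordinate strings), `pb_rpkm`, `cb_rpkm`, `fold_printed`,
#'   `pb_rank`, `cb_rank`, `table` (`"cb"`/`"pb"`).
#' @export
load_printed_tables <- function(which = c("both", "cb", "pb")) {
  which <- match.arg(which)
  files <- c(cb = "table1_cb_enriched.tsv", pb = "table2_pb_enriched.tsv")
  take <- if (which == "both") c("cb", "pb") else which
  out <- lapply(take, function(tb) {
    f <- files[[tb]]
    path <- system.file("extdata", f, package = "smrnapipe", mustWork = TRUE)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.fixture_md5[[f]]))) {
      stop("fixture checksum mismatch for ", f, " (got ", md5,
           "); packaged table has been altered")
    }
    d <- read.delim(path, colClasses = "character",
                    stringsAsFactors = FALSE)
    data.frame(
      name = d$name,
      locations = d$locations,
      pb_rpkm = as.numeric(d$pb_rpkm),
      cb_rpkm = as.numeric(d$cb_rpkm),
      fold_printed = as.numeric(d$fold_printed),
      pb_rank = as.integer(d$pb_rank),
      cb_rank = as.integer(d$cb_rank),
      table = tb,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Verify the printed tables against the differential module
#'
#' Recomputes the signed fold for every printed (PB RPKM, CB RPKM) pair
#' and re-runs differential calling, then compares with the printed fold
#' column and table membership.
#'
#' @param rows data.frame from [load_printed_tables()] (default: the
#'   full 104-row fixture).
#' @param cfg a [diff_config()]; defaults to the published thresholds
#'   (RPKM > 100, fold >= 1.5, sentinel 9.90E+307).
#' @param rel_tol relative fold-error above which a row is flagged.
#' @return list: `n_rows`, `max_rel_fold_error` (over finite rows),
#'   `sentinel_ok`, `n_called`, `n_b_enriched`, `n_a_enriched`,
#'   `flagged` (names of rows whose recomputed fold or call disagrees),
#'   and `records` (the [call_differential()] output, fixture order).
#' @export
verify_printed_tables <- function(rows = load_printed_tables(),
                                  cfg = diff_config(), rel_tol = 1e-6) {
  records <- call_differential(
    data.frame(name = rows$name, rpkm = rows$pb_rpkm),
    data.frame(name = rows$name, rpkm = rows$cb_rpkm),
    cfg
  )
  records <- records[match(rows$name, records$name), , drop = FALSE]
  rownames(records) <- NULL

  finite <- !records$is_sentinel & !is.na(records$fold)
  rel_err <- rep(NA_real_, nrow(rows))
  rel_err[finite] <- abs(records$fold[finite] - rows$fold_printed[finite]) /
    abs(rows$fold_printed[finite])
  sentinel_rows <- which(records$is_sentinel)
  sentinel_ok <- all(abs(records$fold[sentinel_rows]) == cfg$sentinel &
                       rows$fold_printed[sentinel_rows] ==
                       sign(records$fold[sentinel_rows]) * cfg$sentinel)

  expected_side <- ifelse(rows$table == "cb", "B_ENRICHED", "A_ENRICHED")
  flagged <- rows$name[
    (finite & rel_err > rel_tol) | records$side != expected_side
  ]

  list(
    n_rows = nrow(rows),
    max_rel_fold_error = if (any(finite)) max(rel_err[finite]) else NA_real_,
    sentinel_ok = sentinel_ok,
    n_called = sum(records$side != "NONE"),
    n_b_enriched = sum(records$side == "B_ENRICHED"),
    n_a_enriched = sum(records$side == "A_ENRICHED"),
    flagged = flagged,
    records = records
  )
}
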