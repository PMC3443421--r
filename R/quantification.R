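# Multi-mapping-corrected RPKM: RPKM = C / (L * M * N) * 1e9, with
#   C = reads aligned to the miRNA's genomic region(s),
#   L = mature miRNA length (nt),
#   M = multi-mapping number (distinct annotated loci of the mature seq),
#   N = total mapped reads in the sample.
# The M divisor stops a mature sequence encoded at several loci from
# being over-counted relative to single-locus miRNAs.

#' Compute the multi-mapping-corrected RPKM
#'
#' @param C aligned read count(s) for the miRNA (non-negative; fractional
#'   only when cross-miRNA count splitting is enabled upstream).
#' @param L mature miRNA length in nt (>= 1).
#' @param M multi-mapping number, i.e. distinct annotated loci (>= 1).
#' @param N total mapped reads in the sample (>= 1).
#' @return `C / (L * M * N) * 1e9`; vectorized with recycling.
#' @export
compute_rpkm <- function(C, L, M, N) {
  if (any(L <= 0) || any(M <= 0) || any(N <= 0)) {
    stop("RPKM undefined: L, M and N must all be positive")
  }
  if (any(C < 0)) stop("negative read count C")
  C / (L * M * N) * 1e9
}

#' Quantify one sample from tag assignments
#'
#' Produces one record per annotated miRNA (zero-count miRNAs included)
#' with its C, L, M, N terms and the resulting RPKM, sorted by RPKM
#' descending (ties by name).
#'
#' The library-size term N cannot be taken literally as genome-wide
#' mapped reads without a genome aligner, so two desk-scale policies are
#' exposed: `"aligned"` (default) counts admitted reads assigned to any
#' reference sequence (miRNA or excluded mRNA); `"admitted"` counts all
#' admitted reads including unaligned tags. The policy used is recorded
#' in the `n_policy` attribute.
#'
#' @param assignments data.frame from [classify_tags()].
#' @param ref the `ReferenceBundle`.
#' @param n_policy `"aligned"` or `"admitted"` (see Details).
#' @param split_multi_hits,count_mode passed to
#'   [mirna_hit_multiplicity()].
#' @return data.frame `name`, `C`, `L`, `M`, `N`, `rpkm`. An empty sample
#'   (N = 0) yields all-zero RPKMs rather than an error, so empty inputs
#'   complete gracefully.
#' @export
quantify_sample <- function(assignments, ref,
                            n_policy = c("aligned", "admitted"),
                            split_multi_hits = FALSE,
                            count_mode = c("reads", "tags")) {
  n_policy <- match.arg(n_policy)
  count_mode <- match.arg(count_mode)
  cm <- mirna_hit_multiplicity(assignments, ref,
                               split_multi_hits = split_multi_hits,
                               count_mode = count_mode)
  unit <- if (count_mode == "reads") assignments$count else
    rep(1L, nrow(assignments))
  N <- if (n_policy == "aligned") {
    sum(unit[assignments$status %in% c("MIRNA", "EXCLUDED_MRNA")])
  } else {
    sum(unit)
  }
  rpkm <- if (N > 0) compute_rpkm(cm$C, cm$L, cm$M, N) else
    rep(0, nrow(cm))
  out <- data.frame(name = cm$name, C = cm$C, L = cm$L, M = cm$M,
                    N = N, rpkm = rpkm, stringsAsFactors = FALSE)
  out <- out[order(-out$rpkm, out$name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_policy") <- n_policy
  out
}

#' Write a per-sample quantification table
#'
#' TSV sorted by RPKM descending, with the N policy recorded in a
#' leading `#` comment line.
#'
#' @param quants data.frame from [quantify_sample()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(quants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_policy=",
                    attr(quants, "n_policy") %||% "unknown"), con)
  write.table(quants, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
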