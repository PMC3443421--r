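# Tag classification: mRNA exclusion first, then mature-miRNA assignment.
#
# A collapsed tag is (1) EXCLUDED_MRNA when it occurs as a substring of
# any exon sequence — degraded-mRNA fragments are removed before miRNA
# assignment, so exclusion takes absolute precedence; (2) MIRNA when it
# matches at least one annotated mature sequence (containment in either
# direction: tag within mature, or mature within tag); (3) UNALIGNED
# otherwise. Matching is exact by default; a mismatch knob exists for
# sensitivity analyses.

#' Classify collapsed tags against a reference bundle
#'
#' @param tags data.frame with `seq` and `count` (from [collapse_tags()]).
#' @param ref a `ReferenceBundle`.
#' @param max_mismatch allowed mismatches in miRNA matching (0 = exact;
#'   mismatches apply to the contained sequence at each alignment offset).
#' @return data.frame with `seq`, `count`, `status` (one of
#'   `EXCLUDED_MRNA`, `MIRNA`, `UNALIGNED`), `hits` (comma-joined miRNA
#'   names, `""` unless status is `MIRNA`) and `n_hits`.
#' @export
classify_tags <- function(tags, ref, max_mismatch = 0L) {
  stopifnot(inherits(ref, "ReferenceBundle"))
  seqs <- normalize_seq(tags$seq)
  nt <- length(seqs)
  status <- rep("UNALIGNED", nt)
  hits <- vector("list", nt)

  excluded <- db_contains(ref$exclusion, seqs)
  status[excluded] <- "EXCLUDED_MRNA"

  mat <- ref$mirnas$mature_seq
  mnames <- ref$mirnas$name
  if (length(mat) && any(!excluded)) {
    hit_mat <- matrix(FALSE, nrow = nt, ncol = length(mat))
    if (max_mismatch == 0L) {
      # mature contained in tag: one fixed-pattern scan per mature
      for (j in seq_along(mat)) {
        hit_mat[, j] <- grepl(mat[j], seqs, fixed = TRUE)
      }
      # tag contained in a mature: cheap pre-screen on joined text, then
      # resolve which matures for the (few) screened-in tags
      mtext <- paste(mat, collapse = "#")
      in_any <- vapply(seqs, function(tg) grepl(tg, mtext, fixed = TRUE),
                       logical(1), USE.NAMES = FALSE)
      for (i in which(in_any & !excluded)) {
        hit_mat[i, ] <- hit_mat[i, ] |
          vapply(mat, function(m) grepl(seqs[i], m, fixed = TRUE),
                 logical(1), USE.NAMES = FALSE)
      }
    } else {
      tset <- Biostrings::DNAStringSet(seqs)
      mset <- Biostrings::DNAStringSet(mat)
      for (j in seq_along(mat)) {
        hit_mat[, j] <- Biostrings::vcountPattern(
          mat[j], tset, max.mismatch = max_mismatch) > 0L
      }
      for (i in seq_len(nt)) {
        hit_mat[i, ] <- hit_mat[i, ] | (Biostrings::vcountPattern(
          seqs[i], mset, max.mismatch = max_mismatch) > 0L)
      }
    }
    for (i in which(!excluded)) {
      h <- mnames[hit_mat[i, ]]
      if (length(h)) {
        status[i] <- "MIRNA"
        hits[[i]] <- h
      }
    }
  }

  data.frame(
    seq = seqs,
    count = tags$count,
    status = status,
    hits = vapply(hits, function(h) paste(h %||% character(0), collapse = ","),
                  character(1)),
    n_hits = vapply(hits, function(h) length(h %||% character(0)), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Per-miRNA aligned read counts and multi-mapping numbers
#'
#' Aggregates tag assignments into the C and M terms of the RPKM
#' statistic. C for a miRNA is the total read count of tags assigned to
#' it (a tag hitting several distinct miRNA names contributes its full
#' count to each, unless `split_multi_hits` divides it evenly). M is the
#' miRNA's number of distinct annotated genomic loci: a mature sequence
#' encoded at two places in the genome has M = 2 and each of its reads is
#' counted once in C.
#'
#' @param assignments data.frame from [classify_tags()].
#' @param ref the `ReferenceBundle` used for classification.
#' @param split_multi_hits divide each tag's count by its number of
#'   distinct miRNA hits instead of counting it fully for each.
#' @param count_mode `"reads"` (default) sums read multiplicities;
#'   `"tags"` counts each unique tag once.
#' @return data.frame with one row per annotated miRNA: `name`, `C`, `M`,
#'   `L` (mature length); C = 0 for miRNAs with no assigned tag.
#' @export
mirna_hit_multiplicity <- function(assignments, ref,
                                   split_multi_hits = FALSE,
                                   count_mode = c("reads", "tags")) {
  count_mode <- match.arg(count_mode)
  C <- setNames(numeric(nrow(ref$mirnas)), ref$mirnas$name)
  hit_rows <- which(assignments$status == "MIRNA")
  for (i in hit_rows) {
    h <- strsplit(assignments$hits[i], ",", fixed = TRUE)[[1]]
    w <- if (count_mode == "reads") assignments$count[i] else 1
    if (split_multi_hits) w <- w / length(h)
    C[h] <- C[h] + w
  }
  data.frame(
    name = ref$mirnas$name,
    C = unname(C),
    M = ref$mirnas$n_loci,
    L = ref$mirnas$length,
    stringsAsFactors = FALSE
  )
}

#' Write a per-tag assignment table
#'
#' @param assignments data.frame from [classify_tags()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
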