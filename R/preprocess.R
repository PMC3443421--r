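# Read admission rules, 3' adapter trimming, and tag collapsing.
#
# Admission requires a read to be free of poly-A, ambiguous bases and 5'
# adapter carry-over, and to end in 6-18 nt of 3' adapter sequence (which
# is trimmed off to recover the insert). The rules are applied in a fixed
# order (poly-A, ambiguous, 5' adapter, 3' adapter) and the first failing
# rule assigns the read's fate, so the filter report is a partition.

#' Read a FASTQ file
#'
#' @param path FASTQ path (plain or gzip).
#' @return data.frame with columns `id`, `seq` (uppercased, U normalized
#'   to T), `qual`. Zero rows for an empty file.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  out <- data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = unname(normalize_seq(as.character(x))),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Poly-A read filter
#'
#' Drops reads carrying a homopolymer run of at least `min_run` A's or
#' composed of at least `max_frac_A` adenine overall; covers both oligo-dA
#' library artefacts and full poly-A reads.
#'
#' @param seqs character vector of read sequences (normalized).
#' @param min_run minimum A-run length that triggers removal.
#' @param max_frac_A A-fraction at or above which a read is removed.
#' @return logical vector, `TRUE` = drop.
#' @export
filter_polyA <- function(seqs, min_run = 10L, max_frac_A = 0.8) {
  grepl(strrep("A", min_run), seqs, fixed = TRUE) |
    char_frac(seqs, "A") >= max_frac_A
}

#' Ambiguous-base read filter
#'
#' @param seqs character vector of read sequences (normalized).
#' @return logical vector, `TRUE` = drop (read contains at least one N).
#' @export
filter_ambiguous <- function(seqs) {
  grepl("N", seqs, fixed = TRUE)
}

#' 5' adapter carry-over filter
#'
#' Drops reads in which the first `probe_len` nt of the 5' adapter occur
#' as a substring anywhere in the read, within `max_mismatch` mismatches.
#'
#' @param seqs character vector of read sequences (normalized).
#' @param adapter5 5' adapter sequence; must be at least `probe_len` nt.
#' @param probe_len length of the adapter prefix used as the probe.
#' @param max_mismatch allowed mismatches in the probe match.
#' @return logical vector, `TRUE` = drop.
#' @export
filter_5p_adapter <- function(seqs, adapter5, probe_len = 8L,
                              max_mismatch = 0L) {
  adapter5 <- normalize_seq(adapter5)
  if (nchar(adapter5) < probe_len) {
    stop("adapter5 (", nchar(adapter5), " nt) shorter than probe_len (",
         probe_len, ")")
  }
  probe <- substr(adapter5, 1L, probe_len)
  if (max_mismatch == 0L) {
    grepl(probe, seqs, fixed = TRUE)
  } else {
    Biostrings::vcountPattern(probe, Biostrings::DNAStringSet(seqs),
                              max.mismatch = max_mismatch) > 0L
  }
}

#' 3' adapter detection and trimming
#'
#' Finds the longest read suffix that exactly equals a prefix of the 3'
#' adapter. A read is admitted when that flank is `min_flank`-`max_flank`
#' nt long and the remaining insert falls inside the insert-length window;
#' the flank is trimmed off and the insert returned.
#'
#' @param seqs character vector of read sequences (normalized).
#' @param adapter3 3' adapter sequence; at least `min_flank` nt.
#' @param min_flank,max_flank admissible adapter-flank length range (nt).
#' @param insert_min,insert_max admissible trimmed insert length (nt);
#'   the default window retains 15-30 nt (mature miRNAs are 18-24, with
#'   slack for length variants).
#' @return data.frame with `insert` (`NA` when rejected), `flank_len`
#'   (longest adapter flank found, 0 if none), `admitted`.
#' @export
trim_3p_adapter <- function(seqs, adapter3, min_flank = 6L, max_flank = 18L,
                            insert_min = 15L, insert_max = 30L) {
  adapter3 <- normalize_seq(adapter3)
  if (nchar(adapter3) < min_flank) {
    stop("adapter3 (", nchar(adapter3), " nt) shorter than min_flank (",
         min_flank, ")")
  }
  n <- nchar(seqs)
  flank <- integer(length(seqs))
  fl_max <- min(nchar(adapter3), if (length(n)) max(n) else 0L)
  for (fl in seq_len(fl_max)) {
    pref <- substr(adapter3, 1L, fl)
    hit <- n >= fl & substr(seqs, n - fl + 1L, n) == pref
    flank[hit] <- fl  # ascending loop leaves the longest matching flank
  }
  ins_len <- n - flank
  admitted <- flank >= min_flank & flank <= max_flank &
    ins_len >= insert_min & ins_len <= insert_max
  data.frame(
    insert = ifelse(admitted, substr(seqs, 1L, ins_len), NA_character_),
    flank_len = flank,
    admitted = admitted,
    stringsAsFactors = FALSE
  )
}

#' Collapse identical inserts into counted unique tags
#'
#' @param inserts character vector of admitted insert sequences.
#' @return data.frame with `seq` (unique, lexicographic order) and
#'   `count`; counts sum to `length(inserts)`.
#' @export
collapse_tags <- function(inserts) {
  if (length(inserts) == 0L) {
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  sq <- sort(names(tab), method = "radix")
  data.frame(seq = sq, count = as.integer(tab[sq]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Preprocess a small-RNA sample: filter, trim, collapse
#'
#' Applies the admission rules in order (poly-A, ambiguous bases, 5'
#' adapter, 3' adapter flank), trims the 3' adapter from admitted reads
#' and collapses identical inserts into counted tags. The first failing
#' rule assigns each read's fate, so the report counts partition the
#' input.
#'
#' @param reads FASTQ path or a data.frame from [read_fastq()].
#' @param adapter3,adapter5 adapter sequences (mandatory; the shipped
#'   defaults in [default_adapters()] are standard Illumina small-RNA
#'   adapters and must be replaced to match the actual library chemistry).
#' @param min_run,max_frac_A poly-A rule knobs (see [filter_polyA()]).
#' @param probe_len,max_mismatch_5p 5' adapter rule knobs.
#' @param min_flank,max_flank,insert_min,insert_max 3' trim knobs.
#' @return list with `tags` (collapsed tag data.frame), `report` (one-row
#'   data.frame of fate counts) and `inserts` (admitted insert vector, in
#'   input order).
#' @export
preprocess_reads <- function(reads,
                             adapter3 = default_adapters()$adapter3,
                             adapter5 = default_adapters()$adapter5,
                             min_run = 10L, max_frac_A = 0.8,
                             probe_len = 8L, max_mismatch_5p = 0L,
                             min_flank = 6L, max_flank = 18L,
                             insert_min = 15L, insert_max = 30L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  seqs <- normalize_seq(reads$seq)
  n_input <- length(seqs)

  fate <- rep("admitted", n_input)
  live <- rep(TRUE, n_input)

  drop <- live & filter_polyA(seqs, min_run, max_frac_A)
  fate[drop] <- "polyA"; live[drop] <- FALSE

  drop <- live & filter_ambiguous(seqs)
  fate[drop] <- "ambiguous"; live[drop] <- FALSE

  drop <- live & filter_5p_adapter(seqs, adapter5, probe_len, max_mismatch_5p)
  fate[drop] <- "adapter5"; live[drop] <- FALSE

  trim <- trim_3p_adapter(seqs, adapter3, min_flank, max_flank,
                          insert_min, insert_max)
  drop <- live & !trim$admitted
  fate[drop] <- "no_adapter3"; live[drop] <- FALSE

  inserts <- trim$insert[live]
  report <- data.frame(
    n_input = n_input,
    n_polyA_removed = sum(fate == "polyA"),
    n_ambiguous_removed = sum(fate == "ambiguous"),
    n_5p_adapter_removed = sum(fate == "adapter5"),
    n_no_3p_adapter_removed = sum(fate == "no_adapter3"),
    n_admitted = sum(live)
  )
  list(tags = collapse_tags(inserts), report = report, inserts = inserts,
       fate = fate)
}

#' Default adapter sequences
#'
#' Standard Illumina small-RNA library adapters, shipped as example
#' defaults only: real analyses must supply the adapters of the library
#' chemistry actually used.
#'
#' @return list with `adapter3` and `adapter5`.
#' @export
default_adapters <- function() {
  list(adapter3 = "ATCTCGTATGCCGTCTTCTGCTTG",
       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
}

#' Write collapsed tags as FASTA with counts in headers
#'
#' Header dialect: `>tag_<i>_x<count>`.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  write_fasta_chr(
    setNames(tags$seq, sprintf("tag_%d_x%d", seq_len(nrow(tags)), tags$count)),
    path)
}
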