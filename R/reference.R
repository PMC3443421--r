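# Reference model: mature miRNA annotation, sequences, and the
# degraded-mRNA exclusion database.
#
# Coordinate convention: loci are held 0-based half-open internally.
# GFF3 (1-based inclusive) and printed browser-style coordinates are
# converted on load; BED is already 0-based half-open.

#' Load a mature-miRNA annotation
#'
#' Reads a GFF3 (with `Name=` attributes) or 6-column BED annotation of
#' mature miRNA loci and resolves one mature sequence per miRNA name.
#' Records sharing a name are merged into a single miRNA with multiple
#' genomic loci (one mature sequence can be encoded at several places in
#' the genome); the multi-mapping number M used by the RPKM statistic is
#' the number of such loci.
#'
#' Sequence resolution: if `mature_fasta` is given, the record whose FASTA
#' id equals the miRNA name is used (this takes precedence, matching the
#' use of a curated mature catalogue as the reference). Otherwise the
#' sequence is extracted from `genome_fasta` at the first annotated locus,
#' reverse-complemented on the minus strand.
#'
#' @param annotation_path path to a GFF3 (`.gff`/`.gff3`) or BED file.
#' @param mature_fasta optional FASTA of mature sequences keyed by name.
#' @param genome_fasta optional genome FASTA (chromosome sequences).
#' @return data.frame with columns `name`, `mature_seq`, `length`,
#'   `n_loci`, plus attribute `loci`: a data.frame (`name`, `chrom`,
#'   `start`, `end`, `strand`) in 0-based half-open coordinates.
#' @export
load_mirna_annotation <- function(annotation_path, mature_fasta = NULL,
                                  genome_fasta = NULL) {
  if (is.null(mature_fasta) && is.null(genome_fasta)) {
    stop("supply at least one of mature_fasta or genome_fasta")
  }
  loci <- read_annotation_loci(annotation_path)
  bad <- loci$end <= loci$start
  if (any(bad)) {
    stop("malformed interval (end <= start) at annotation record(s) ",
         paste(which(bad), collapse = ", "))
  }
  if (any(loci$end - loci$start > 35L)) {
    stop("annotation interval longer than 35 nt at record(s) ",
         paste(which(loci$end - loci$start > 35L), collapse = ", "),
         "; mature miRNA loci expected (18-24 nt, slack to 35)")
  }

  # order-independent merge: canonical locus order within each name
  loci <- loci[order(loci$name, loci$chrom, loci$start, method = "radix"), ,
               drop = FALSE]
  rownames(loci) <- NULL
  names_u <- sort(unique(loci$name), method = "radix")

  mat <- NULL
  if (!is.null(mature_fasta)) {
    mat <- read_fasta_chr(mature_fasta)
  }
  genome <- if (!is.null(genome_fasta)) read_fasta_chr(genome_fasta) else NULL

  seqs <- vapply(names_u, function(nm) {
    if (!is.null(mat) && nm %in% names(mat)) return(unname(mat[nm]))
    if (!is.null(mat) && is.null(genome)) {
      stop("no mature sequence for miRNA '", nm, "' in ", mature_fasta)
    }
    l <- loci[loci$name == nm, , drop = FALSE][1, ]
    if (is.null(genome) || !(l$chrom %in% names(genome))) {
      stop("no sequence source for miRNA '", nm, "' (chromosome '",
           l$chrom, "' not in genome FASTA)")
    }
    s <- substr(genome[[l$chrom]], l$start + 1L, l$end)
    if (nchar(s) < l$end - l$start) {
      stop("locus of miRNA '", nm, "' extends beyond chromosome '",
           l$chrom, "'")
    }
    if (l$strand == "-") s <- revcomp(s)
    s
  }, character(1))

  spans <- vapply(names_u, function(nm) {
    l <- loci[loci$name == nm, , drop = FALSE]
    list(min = min(l$end - l$start), max = max(l$end - l$start))
  }, vector("list", 2))
  len <- nchar(seqs)
  lo <- unlist(spans["min", ]); hi <- unlist(spans["max", ])
  off <- pmax(abs(len - lo), abs(len - hi))
  if (any(off > 2L)) {
    warning("mature sequence length differs from locus span by >2 nt for: ",
            paste(names_u[off > 2L], collapse = ", "))
  }

  mirnas <- data.frame(
    name = names_u,
    mature_seq = unname(seqs),
    length = unname(len),
    n_loci = as.integer(table(loci$name)[names_u]),
    stringsAsFactors = FALSE
  )
  rownames(mirnas) <- NULL
  attr(mirnas, "loci") <- loci
  mirnas
}

# Import GFF3/BED via rtracklayer; return 0-based half-open loci data.frame.
read_annotation_loci <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e))
  )
  nm <- if (fmt == "gff3") {
    as.character(S4Vectors::mcols(gr)$Name)
  } else {
    as.character(S4Vectors::mcols(gr)$name)
  }
  if (length(gr) == 0L) stop("annotation '", path, "' contains no records")
  if (any(is.na(nm)) || any(!nzchar(nm))) {
    stop("annotation record(s) without a name attribute at record(s) ",
         paste(which(is.na(nm) | !nzchar(nm)), collapse = ", "))
  }
  data.frame(
    name = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    stringsAsFactors = FALSE
  )
}

#' Write a mature-miRNA annotation back to disk
#'
#' Inverse of [load_mirna_annotation()] for the annotation part; used for
#' round-trip checks and by the simulator.
#'
#' @param mirnas result of [load_mirna_annotation()] (or simulator bundle
#'   `$mirnas`).
#' @param annotation_path output GFF3 or BED path (format from extension).
#' @param mature_fasta optional output FASTA path of mature sequences.
#' @return `annotation_path`, invisibly.
#' @export
write_mirna_annotation <- function(mirnas, annotation_path,
                                   mature_fasta = NULL) {
  loci <- attr(mirnas, "loci")
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand
  )
  if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    S4Vectors::mcols(gr)$type <- "miRNA"
    S4Vectors::mcols(gr)$Name <- loci$name
    S4Vectors::mcols(gr)$ID <- paste0(loci$name, "_", seq_along(gr))
    rtracklayer::export(gr, annotation_path, format = "gff3")
  } else {
    S4Vectors::mcols(gr)$name <- loci$name
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, annotation_path, format = "bed")
  }
  if (!is.null(mature_fasta)) {
    write_fasta_chr(setNames(mirnas$mature_seq, mirnas$name), mature_fasta)
  }
  invisible(annotation_path)
}

#' Load the degraded-mRNA exclusion database
#'
#' Reads an exon-sequence FASTA into a queryable substring set. Tags found
#' anywhere in these sequences are treated as degraded-mRNA fragments and
#' excluded before miRNA assignment.
#'
#' @param fasta_path exon FASTA; an empty file yields a warning and a
#'   no-op database (nothing excluded).
#' @return an `ExclusionDB` object.
#' @export
load_exclusion_db <- function(fasta_path) {
  seqs <- tryCatch(read_fasta_chr(fasta_path), error = function(e) {
    stop("failed to parse exclusion FASTA '", fasta_path, "': ",
         conditionMessage(e))
  })
  if (length(seqs) == 0L) {
    warning("exclusion FASTA '", fasta_path,
            "' is empty; mRNA exclusion is a no-op")
  }
  exclusion_db(seqs)
}

#' Build an exclusion database from in-memory sequences
#'
#' @param seqs named character vector of exon sequences (DNA; normalized
#'   internally).
#' @return an `ExclusionDB`: supports [db_contains()] substring queries
#'   whose answers equal a brute-force scan over every sequence.
#' @export
exclusion_db <- function(seqs) {
  seqs <- normalize_seq(seqs)
  # exact scan over a separator-joined text; '#' cannot occur in a tag, so
  # no query can straddle a sequence boundary
  structure(
    list(seqs = seqs,
         text = paste(seqs, collapse = "#"),
         n = length(seqs)),
    class = "ExclusionDB"
  )
}

#' Test substring containment against an exclusion database
#'
#' @param db an `ExclusionDB`.
#' @param tags character vector of query sequences.
#' @return logical vector: is each tag a substring of any database entry?
#' @export
db_contains <- function(db, tags) {
  stopifnot(inherits(db, "ExclusionDB"))
  if (db$n == 0L || length(tags) == 0L) return(rep(FALSE, length(tags)))
  tags <- normalize_seq(tags)
  vapply(tags, function(tg) grepl(tg, db$text, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

#' @export
print.ExclusionDB <- function(x, ...) {
  cat("ExclusionDB:", x$n, "sequence(s),",
      sum(nchar(x$seqs)), "nt total\n")
  invisible(x)
}

#' Assemble a reference bundle
#'
#' Bundles the annotated mature miRNAs, the exclusion database and
#' (optionally) genome sequences into the single object consumed by the
#' alignment and quantification steps.
#'
#' @param mirnas result of [load_mirna_annotation()].
#' @param exclusion an `ExclusionDB` (use `exclusion_db(character(0))` for
#'   no exclusion).
#' @param genome_seqs optional named character vector of chromosomes.
#' @return a `ReferenceBundle` object.
#' @export
reference_bundle <- function(mirnas, exclusion, genome_seqs = NULL) {
  stopifnot(is.data.frame(mirnas), inherits(exclusion, "ExclusionDB"))
  if (anyDuplicated(mirnas$name)) {
    stop("duplicate miRNA names in bundle: ",
         paste(unique(mirnas$name[duplicated(mirnas$name)]), collapse = ", "))
  }
  structure(
    list(mirnas = mirnas, exclusion = exclusion, genome_seqs = genome_seqs),
    class = "ReferenceBundle"
  )
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat("ReferenceBundle:", nrow(x$mirnas), "mature miRNA(s) (",
      sum(x$mirnas$n_loci), "loci ),", x$exclusion$n, "exclusion sequence(s)\n")
  invisible(x)
}

# --- FASTA helpers (Biostrings-backed, character in/out) ---------------------

read_fasta_chr <- function(path) {
  if (file.exists(path) && file.size(path) == 0L) {
    return(setNames(character(0), character(0)))
  }
  x <- Biostrings::readBStringSet(path)
  s <- normalize_seq(as.character(x))
  names(s) <- sub("\\s.*$", "", names(x))  # id = first token of header
  s
}

write_fasta_chr <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(normalize_seq(seqs)), path)
  invisible(path)
}
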