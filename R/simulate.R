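# Synthetic small-RNA-seq data with known truth.
#
# The simulator emulates every read class the admission filters target:
# true miRNA inserts flanked by 6-18 nt of 3' adapter, poly-A
# contaminants, ambiguous-base reads, 5'-adapter carry-over reads and
# degraded-mRNA fragments, over a toy reference in which at least one
# mature sequence is encoded at two genomic loci. Classes are generated
# mutually exclusively (each read violates exactly the rule of its
# class, or none), so the filter report is predictable from the truth
# table exactly.

#' Simulation configuration
#'
#' Defaults describe a desk-scale but realistic small-RNA library: 30
#' miRNAs (3 of them two-locus) whose abundances decay geometrically and
#' absorb 70% of reads, 20% contaminants (5% poly-A, 2% ambiguous, 3%
#' 5'-adapter carry-over, 10% degraded mRNA) and a 10% remainder of
#' unalignable inserts.
#'
#' @param n_mirnas number of mature miRNAs in the toy reference.
#' @param n_multilocus how many of them are planted at two genomic loci.
#' @param n_exons,exon_len exclusion-database exon count and length (nt).
#' @param reads_per_sample reads simulated per condition.
#' @param abundance_a,abundance_b per-miRNA expected read fractions
#'   (length `n_mirnas`, each summing to <= 1); default geometric decay
#'   `0.9^i` scaled to 0.70 total, identical in both conditions.
#' @param frac_polyA,frac_ambiguous,frac_adapter5,frac_mrna contaminant
#'   class fractions.
#' @param flank_range inclusive range the 3'-adapter flank length is
#'   drawn from; must lie within the admissible 6-18 window.
#' @param adapter3,adapter5 adapter sequences used to synthesize reads.
#' @param decoy also plant one exon containing the first mature sequence
#'   (for exclusion-precedence tests).
#' @param seed integer RNG seed; every simulator output is a pure
#'   function of the config including this seed.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_mirnas = 30L, n_multilocus = 3L,
                       n_exons = 20L, exon_len = 300L,
                       reads_per_sample = 50000L,
                       abundance_a = NULL, abundance_b = NULL,
                       frac_polyA = 0.05, frac_ambiguous = 0.02,
                       frac_adapter5 = 0.03, frac_mrna = 0.10,
                       flank_range = c(6L, 18L),
                       adapter3 = default_adapters()$adapter3,
                       adapter5 = default_adapters()$adapter5,
                       decoy = FALSE, seed = 1L) {
  default_ab <- function(n) {
    w <- 0.9^(seq_len(n) - 1)
    w / sum(w) * 0.70
  }
  abundance_a <- abundance_a %||% default_ab(n_mirnas)
  abundance_b <- abundance_b %||% default_ab(n_mirnas)
  fr <- c(polyA = frac_polyA, ambiguous = frac_ambiguous,
          adapter5 = frac_adapter5, mrna = frac_mrna)
  stopifnot(
    n_mirnas >= n_multilocus, n_multilocus >= 0,
    length(abundance_a) == n_mirnas, length(abundance_b) == n_mirnas,
    all(abundance_a >= 0), all(abundance_b >= 0),
    all(fr >= 0), all(fr <= 1),
    sum(abundance_a) + sum(fr) <= 1 + 1e-12,
    sum(abundance_b) + sum(fr) <= 1 + 1e-12,
    flank_range[1] >= 6L, flank_range[2] <= 18L,
    flank_range[1] <= flank_range[2],
    seed == as.integer(seed)
  )
  structure(list(
    n_mirnas = as.integer(n_mirnas), n_multilocus = as.integer(n_multilocus),
    n_exons = as.integer(n_exons), exon_len = as.integer(exon_len),
    reads_per_sample = as.integer(reads_per_sample),
    abundance_a = abundance_a, abundance_b = abundance_b,
    contaminant_fractions = fr,
    flank_range = as.integer(flank_range),
    adapter3 = normalize_seq(adapter3), adapter5 = normalize_seq(adapter5),
    decoy = isTRUE(decoy), seed = as.integer(seed)
  ), class = "SimConfig")
}

# Rejection-sample random DNA strings that would not trip any admission
# rule on their own: no long A-run, moderate A fraction, no 5'-adapter
# probe. `avoid` is an optional extra predicate on candidates.
random_clean <- function(n, len_range, cfg, avoid = NULL, budget = 100L) {
  if (n == 0L) return(character(0))
  probe <- substr(cfg$adapter5, 1L, 8L)
  out <- character(n)
  todo <- seq_len(n)
  for (it in seq_len(budget)) {
    lens <- len_range[1] +
      sample.int(len_range[2] - len_range[1] + 1L, length(todo),
                 replace = TRUE) - 1L
    cand <- random_dna(lens)
    bad <- grepl("AAAAAAAA", cand, fixed = TRUE) |
      char_frac(cand, "A") >= 0.7 |
      grepl(probe, cand, fixed = TRUE)
    if (!is.null(avoid)) bad <- bad | avoid(cand)
    out[todo[!bad]] <- cand[!bad]
    todo <- todo[bad]
    if (!length(todo)) return(out)
  }
  stop("rejection sampling exceeded its retry budget; ",
       "reduce the requested sizes")
}

#' Build the toy reference bundle (and optionally its files)
#'
#' Mature sequences are random 18-24 nt strings, rejection-sampled to be
#' pairwise non-substring of each other; the first `n_multilocus` of
#' them are planted at two genomic loci (the second on the minus
#' strand). Exon sequences are guaranteed not to contain any mature
#' sequence unless `decoy = TRUE` requests one that does.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory; when given, a GFF3 annotation plus
#'   mature, genome and exon FASTAs are written there.
#' @return list with `bundle` (a `ReferenceBundle`) and `files` (named
#'   paths, or `NULL`).
#' @export
make_reference <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    # pairwise non-substring mature sequences
    mat <- character(0)
    for (i in seq_len(cfg$n_mirnas)) {
      s <- random_clean(1L, c(18L, 24L), cfg, avoid = function(cand) {
        vapply(cand, function(x) {
          any(vapply(mat, function(m) {
            grepl(x, m, fixed = TRUE) || grepl(m, x, fixed = TRUE)
          }, logical(1))) ||
            grepl(x, cfg$adapter3, fixed = TRUE)
        }, logical(1), USE.NAMES = FALSE)
      })
      mat <- c(mat, s)
    }
    names(mat) <- sprintf("sim-mir-%02d", seq_len(cfg$n_mirnas))

    # one chromosome per locus: 50 nt pads around the planted mature
    loci <- list(); chroms <- character(0); k <- 0L
    for (i in seq_len(cfg$n_mirnas)) {
      n_loc <- if (i <= cfg$n_multilocus) 2L else 1L
      for (l in seq_len(n_loc)) {
        k <- k + 1L
        strand <- if (l == 2L) "-" else "+"
        planted <- if (strand == "-") revcomp(mat[i]) else mat[i]
        pads <- random_clean(2L, c(50L, 50L), cfg, avoid = function(cand) {
          bad <- logical(length(cand))
          for (m in mat) bad <- bad | grepl(m, cand, fixed = TRUE)
          bad
        })
        chrom_name <- sprintf("chrS%03d", k)
        chroms[chrom_name] <- paste0(pads[1], planted, pads[2])
        loci[[k]] <- data.frame(
          name = names(mat)[i], chrom = chrom_name,
          start = 50L, end = 50L + nchar(mat[i]), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    loci <- do.call(rbind, loci)
    loci <- loci[order(loci$name, loci$chrom, loci$start, method = "radix"), ]
    rownames(loci) <- NULL

    # exons free of mature sequences (plus one decoy if requested)
    exons <- random_clean(cfg$n_exons, rep(cfg$exon_len, 2L), cfg,
                          avoid = function(cand) {
      bad <- logical(length(cand))
      for (m in mat) bad <- bad | grepl(m, cand, fixed = TRUE)
      bad
    })
    names(exons) <- sprintf("exon_%03d", seq_len(cfg$n_exons))
    if (cfg$decoy) {
      pads <- random_clean(2L, c(40L, 40L), cfg)
      exons <- c(exons, decoy_exon = paste0(pads[1], mat[1], pads[2]))
    }

    mirnas <- data.frame(
      name = names(mat), mature_seq = unname(mat),
      length = nchar(mat), n_loci = as.integer(table(loci$name)[names(mat)]),
      stringsAsFactors = FALSE)
    rownames(mirnas) <- NULL
    attr(mirnas, "loci") <- loci

    bundle <- reference_bundle(mirnas, exclusion_db(exons),
                               genome_seqs = chroms)
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- c(annotation = file.path(dir, "mirna_annotation.gff3"),
                 mature = file.path(dir, "mature.fa"),
                 genome = file.path(dir, "genome.fa"),
                 exons = file.path(dir, "exons.fa"))
      write_mirna_annotation(mirnas, files[["annotation"]],
                             mature_fasta = files[["mature"]])
      write_fasta_chr(chroms, files[["genome"]])
      write_fasta_chr(exons, files[["exons"]])
    }
    list(bundle = bundle, files = files)
  })
}

#' Simulate two-condition small-RNA FASTQ files with ground truth
#'
#' Draws each read's class from a multinomial over the per-miRNA
#' abundances, the contaminant fractions and an unalignable remainder,
#' then synthesizes the read for its class: miRNA and decoy-free mRNA
#' inserts get a uniform 6-18 nt 3'-adapter flank; poly-A, ambiguous and
#' 5'-adapter reads violate exactly their own admission rule.
#'
#' @param cfg a [sim_config()].
#' @param bundle `ReferenceBundle` from [make_reference()] (same config).
#' @param dir output directory for the two FASTQ files.
#' @param adversarial_flank draw miRNA flank lengths from {5, 19} (just
#'   outside the admissible window) instead of `cfg$flank_range`, to
#'   exercise the 3'-adapter rejection boundary.
#' @return list: `fastq` (named paths for samples `a` and `b`), `truth`
#'   (per-read data.frame: `read_id`, `sample`, `class`, `mirna`,
#'   `flank_len`), `counts` (per-miRNA true read counts per sample).
#' @export
simulate_fastq <- function(cfg, bundle, dir, adversarial_flank = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"), inherits(bundle, "ReferenceBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- setNames(bundle$mirnas$mature_seq, bundle$mirnas$name)
  exons <- bundle$exclusion$seqs
  probe <- substr(cfg$adapter5, 1L, 8L)

  sim_one <- function(sample, ab, seed_off) {
    with_seed(cfg$seed + seed_off, {
      n <- cfg$reads_per_sample
      p <- c(ab, cfg$contaminant_fractions)
      p <- c(p, unaligned = 1 - sum(p))
      classes <- c(names(mat), names(cfg$contaminant_fractions), "unaligned")
      cnt <- as.integer(rmultinom(1L, n, p))
      names(cnt) <- classes

      flanks_for <- function(k) {
        if (adversarial_flank) sample(c(5L, 19L), k, replace = TRUE)
        else cfg$flank_range[1] +
          sample.int(cfg$flank_range[2] - cfg$flank_range[1] + 1L, k,
                     replace = TRUE) - 1L
      }
      add_flank <- function(ins, fl) paste0(ins, substr(cfg$adapter3, 1L, fl))

      seqs <- character(0); cls <- character(0)
      mirna_of <- character(0); flank_of <- integer(0)

      # true miRNA reads
      for (nm in names(mat)) {
        k <- cnt[[nm]]
        if (!k) next
        fl <- flanks_for(k)
        seqs <- c(seqs, add_flank(rep(mat[[nm]], k), fl))
        cls <- c(cls, rep("mirna", k))
        mirna_of <- c(mirna_of, rep(nm, k))
        flank_of <- c(flank_of, fl)
      }
      # poly-A contaminants
      k <- cnt[["polyA"]]
      if (k) {
        seqs <- c(seqs, strrep("A", sample(26:36, k, replace = TRUE)))
        cls <- c(cls, rep("polyA", k))
        mirna_of <- c(mirna_of, rep(NA_character_, k))
        flank_of <- c(flank_of, rep(0L, k))
      }
      # ambiguous-base reads: clean insert + flank, then plant one N
      k <- cnt[["ambiguous"]]
      if (k) {
        ins <- random_clean(k, c(20L, 24L), cfg)
        fl <- flanks_for(k)
        rd <- add_flank(ins, fl)
        pos <- vapply(nchar(ins), function(L) sample.int(L, 1L), integer(1))
        substr(rd, pos, pos) <- "N"
        seqs <- c(seqs, rd)
        cls <- c(cls, rep("ambiguous", k))
        mirna_of <- c(mirna_of, rep(NA_character_, k))
        flank_of <- c(flank_of, fl)
      }
      # 5'-adapter carry-over: probe + clean insert + flank
      k <- cnt[["adapter5"]]
      if (k) {
        ins <- random_clean(k, c(12L, 16L), cfg)
        fl <- flanks_for(k)
        seqs <- c(seqs, add_flank(paste0(probe, ins), fl))
        cls <- c(cls, rep("adapter5", k))
        mirna_of <- c(mirna_of, rep(NA_character_, k))
        flank_of <- c(flank_of, fl)
      }
      # degraded-mRNA fragments: exon substring + flank
      k <- cnt[["mrna"]]
      if (k) {
        if (!length(exons)) stop("mrna fraction > 0 but no exons in bundle")
        frag <- character(k)
        todo <- seq_len(k)
        for (it in 1:100) {
          ex <- sample(exons, length(todo), replace = TRUE)
          fln <- sample(18:24, length(todo), replace = TRUE)
          st <- vapply(nchar(ex) - fln + 1L, function(m) sample.int(m, 1L),
                       integer(1))
          cand <- substr(ex, st, st + fln - 1L)
          bad <- grepl("AAAAAAAA", cand, fixed = TRUE) |
            char_frac(cand, "A") >= 0.7 | grepl(probe, cand, fixed = TRUE)
          frag[todo[!bad]] <- cand[!bad]
          todo <- todo[bad]
          if (!length(todo)) break
        }
        if (length(todo)) stop("could not draw clean mRNA fragments")
        fl <- flanks_for(k)
        seqs <- c(seqs, add_flank(frag, fl))
        cls <- c(cls, rep("mrna", k))
        mirna_of <- c(mirna_of, rep(NA_character_, k))
        flank_of <- c(flank_of, fl)
      }
      # unalignable inserts: clean, not in exons, no miRNA containment
      k <- cnt[["unaligned"]]
      if (k) {
        mtext <- paste(mat, collapse = "#")
        ins <- random_clean(k, c(20L, 24L), cfg, avoid = function(cand) {
          bad <- db_contains(bundle$exclusion, cand)
          for (m in mat) bad <- bad | grepl(m, cand, fixed = TRUE)
          bad | vapply(cand, function(x) grepl(x, mtext, fixed = TRUE),
                       logical(1), USE.NAMES = FALSE)
        })
        fl <- flanks_for(k)
        seqs <- c(seqs, add_flank(ins, fl))
        cls <- c(cls, rep("unaligned", k))
        mirna_of <- c(mirna_of, rep(NA_character_, k))
        flank_of <- c(flank_of, fl)
      }

      ord <- sample.int(length(seqs))
      reads <- data.frame(
        id = sprintf("sim_%s_%07d", sample, seq_along(seqs)),
        seq = seqs[ord],
        qual = strrep("I", nchar(seqs[ord])),
        stringsAsFactors = FALSE)
      truth <- data.frame(
        read_id = reads$id, sample = sample,
        class = cls[ord], mirna = mirna_of[ord], flank_len = flank_of[ord],
        stringsAsFactors = FALSE)
      path <- file.path(dir, paste0("sample_", sample, ".fastq"))
      write_fastq(reads, path)
      list(path = path, truth = truth, counts = cnt[names(mat)])
    })
  }

  a <- sim_one("a", cfg$abundance_a, 1L)
  b <- sim_one("b", cfg$abundance_b, 2L)
  counts <- data.frame(
    name = names(mat),
    count_a = as.integer(a$counts), count_b = as.integer(b$counts),
    stringsAsFactors = FALSE)
  list(fastq = c(a = a$path, b = b$path),
       truth = rbind(a$truth, b$truth),
       counts = counts)
}

#' RPKMs implied by the simulator's ground truth
#'
#' Computes, per sample, the RPKM each miRNA should receive given the
#' true per-read class labels: C is the true miRNA read count and N
#' follows the same policy as the pipeline (`"aligned"` = true miRNA +
#' mRNA-fragment reads; `"admitted"` adds the unalignable inserts).
#'
#' @param sim result of [simulate_fastq()].
#' @param bundle the matching `ReferenceBundle`.
#' @param n_policy library-size policy, as in [quantify_sample()].
#' @return data.frame `name`, `sample`, `C`, `N`, `rpkm`.
#' @export
truth_rpkm <- function(sim, bundle, n_policy = c("aligned", "admitted")) {
  n_policy <- match.arg(n_policy)
  out <- lapply(c("a", "b"), function(s) {
    tr <- sim$truth[sim$truth$sample == s, , drop = FALSE]
    cls_n <- if (n_policy == "aligned") c("mirna", "mrna") else
      c("mirna", "mrna", "unaligned")
    N <- sum(tr$class %in% cls_n)
    C <- setNames(numeric(nrow(bundle$mirnas)), bundle$mirnas$name)
    tb <- table(tr$mirna[tr$class == "mirna"])
    C[names(tb)] <- as.numeric(tb)
    rpkm <- if (N > 0) {
      compute_rpkm(C, bundle$mirnas$length, bundle$mirnas$n_loci, N)
    } else rep(0, length(C))
    data.frame(name = names(C), sample = s, C = unname(C), N = N,
               rpkm = unname(rpkm), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
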