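# Brute-force oracles and hand-built toy references shared across tests.
# Oracles deliberately use naive per-sequence scans, independent of the
# package's indexed lookups.

# naive substring scan: is q contained in any of seqs?
brute_contains <- function(seqs, q) {
  any(vapply(seqs, function(s) grepl(q, s, fixed = TRUE), logical(1)))
}

# naive classification per the pipeline's rules: exclusion first, then
# containment in either direction against every mature sequence
brute_classify <- function(tag, exon_seqs, matures) {
  if (brute_contains(exon_seqs, tag)) {
    return(list(status = "EXCLUDED_MRNA", hits = character(0)))
  }
  hit <- names(matures)[vapply(matures, function(m) {
    grepl(tag, m, fixed = TRUE) || grepl(m, tag, fixed = TRUE)
  }, logical(1))]
  if (length(hit)) list(status = "MIRNA", hits = sort(hit))
  else list(status = "UNALIGNED", hits = character(0))
}

# hand-built bundle: three miRNAs (mir-t2 at two loci), two exons; with
# decoy = TRUE the first exon contains mir-t1's mature sequence
toy_bundle <- function(decoy = FALSE) {
  mat <- c(
    "sim-mir-t1" = "TGCATGCATGCATGCATGCATG",   # 22 nt
    "sim-mir-t2" = "ACCGTTACCGGTTAACCGGTTA",   # 22 nt, two loci
    "sim-mir-t3" = "GGATCCGGATCGATCGGA"        # 18 nt
  )
  loci <- data.frame(
    name = c("sim-mir-t1", "sim-mir-t2", "sim-mir-t2", "sim-mir-t3"),
    chrom = c("chrT1", "chrT2", "chrT3", "chrT1"),
    start = c(50L, 50L, 50L, 120L),
    end = c(50L + 22L, 50L + 22L, 50L + 22L, 120L + 18L),
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE
  )
  mirnas <- data.frame(
    name = names(mat), mature_seq = unname(mat), length = nchar(mat),
    n_loci = c(1L, 2L, 1L), stringsAsFactors = FALSE
  )
  attr(mirnas, "loci") <- loci
  exons <- c(
    exon_1 = paste0(strrep("CT", 30),
                    if (decoy) mat[["sim-mir-t1"]] else "GACTGACTGACTGACTGACTGG",
                    strrep("TC", 30)),
    exon_2 = paste0(strrep("GA", 25), "CCCGGGTTTACGTAGCTAGC", strrep("AG", 25))
  )
  reference_bundle(mirnas, exclusion_db(exons))
}

# small simulated dataset reused by preprocessing/pipeline tests
toy_sim <- function(reads = 4000L, seed = 42L, ...) {
  cfg <- sim_config(n_mirnas = 10L, n_multilocus = 2L, n_exons = 6L,
                    exon_len = 150L, reads_per_sample = reads,
                    seed = seed, ...)
  mr <- make_reference(cfg)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulate_fastq(cfg, mr$bundle, dir = dir)
  list(cfg = cfg, bundle = mr$bundle, sim = sim, dir = dir)
}
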