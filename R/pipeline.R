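# End-to-end pipeline: reference load -> preprocess -> classify ->
# quantify -> differential calling, with all outputs and a metadata
# sidecar written to one directory. Single-threaded and deterministic:
# identical inputs and configuration give byte-identical outputs.

#' Run the full two-condition small-RNA pipeline
#'
#' @param fastq_a,fastq_b FASTQ paths for conditions A and B (the
#'   published comparison maps A = PB-EPC, B = CB-EPC).
#' @param ref a `ReferenceBundle`, or `NULL` to build one from
#'   `annotation`/`mature_fasta`/`genome_fasta`/`exon_fasta` paths.
#' @param outdir output directory (created).
#' @param annotation,mature_fasta,genome_fasta,exon_fasta reference file
#'   paths, used when `ref` is `NULL`.
#' @param adapter3,adapter5 adapter sequences (see [default_adapters()]).
#' @param min_flank,max_flank,insert_min,insert_max preprocessing knobs.
#' @param max_mismatch miRNA matching mismatch allowance (0 = exact).
#' @param n_policy library-size policy (see [quantify_sample()]).
#' @param cfg a [diff_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `report_a`, `report_b`, `quant_a`,
#'   `quant_b`, `diff` and `outdir`.
#' @export
run_pipeline <- function(fastq_a, fastq_b, ref = NULL, outdir,
                         annotation = NULL, mature_fasta = NULL,
                         genome_fasta = NULL, exon_fasta = NULL,
                         adapter3 = default_adapters()$adapter3,
                         adapter5 = default_adapters()$adapter5,
                         min_flank = 6L, max_flank = 18L,
                         insert_min = 15L, insert_max = 30L,
                         max_mismatch = 0L,
                         n_policy = c("aligned", "admitted"),
                         cfg = diff_config(), quiet = FALSE) {
  n_policy <- match.arg(n_policy)
  for (p in c(fastq_a, fastq_b)) {
    if (!file.exists(p)) stop("input FASTQ not found: ", p)
  }
  if (is.null(ref)) {
    if (is.null(annotation) || is.null(exon_fasta)) {
      stop("either `ref` or annotation + exon_fasta paths are required")
    }
    mirnas <- load_mirna_annotation(annotation, mature_fasta, genome_fasta)
    ref <- reference_bundle(mirnas, load_exclusion_db(exon_fasta))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  res <- lapply(c(a = fastq_a, b = fastq_b), function(fq) {
    say("preprocessing ", fq)
    pp <- preprocess_reads(fq, adapter3 = adapter3, adapter5 = adapter5,
                           min_flank = min_flank, max_flank = max_flank,
                           insert_min = insert_min, insert_max = insert_max)
    say("  ", pp$report$n_admitted, "/", pp$report$n_input,
        " reads admitted; ", nrow(pp$tags), " unique tags")
    asg <- classify_tags(pp$tags, ref, max_mismatch = max_mismatch)
    q <- quantify_sample(asg, ref, n_policy = n_policy)
    list(report = pp$report, assignments = asg, quant = q)
  })

  for (s in c("a", "b")) {
    write.table(res[[s]]$report,
                file.path(outdir, paste0("filter_report_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_quant_tsv(res[[s]]$quant,
                    file.path(outdir, paste0("quant_", s, ".tsv")))
    write_assignment_tsv(res[[s]]$assignments,
                         file.path(outdir, paste0("assignments_", s, ".tsv")))
  }

  diff <- call_differential(res$a$quant, res$b$quant, cfg)
  write_diff_tables(diff, outdir)
  say("differential: ", sum(diff$side == "B_ENRICHED"), " B-enriched, ",
      sum(diff$side == "A_ENRICHED"), " A-enriched")

  meta <- list(
    package = "smrnapipe",
    version = as.character(utils::packageVersion("smrnapipe")),
    inputs = list(fastq_a = fastq_a, fastq_b = fastq_b),
    adapters = list(adapter3 = adapter3, adapter5 = adapter5),
    flank = c(min_flank, max_flank),
    insert_window = c(insert_min, insert_max),
    max_mismatch = max_mismatch,
    n_policy = n_policy,
    n_a = unname(res$a$quant$N[1]), n_b = unname(res$b$quant$N[1]),
    thresholds = list(rpkm = cfg$rpkm_threshold, fold = cfg$fold_threshold,
                      sentinel = cfg$sentinel)
  )
  yaml::write_yaml(meta, file.path(outdir, "run_metadata.yaml"))

  invisible(list(report_a = res$a$report, report_b = res$b$report,
                 quant_a = res$a$quant, quant_b = res$b$quant,
                 diff = diff, outdir = outdir))
}
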