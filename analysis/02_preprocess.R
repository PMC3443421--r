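#!/usr/bin/env Rscript
# Step 2: admission filtering, 3' adapter trimming and tag collapsing of
# the two simulated libraries; checks the filter report against the
# simulator's per-read class labels.

suppressMessages(library(smrnapipe))

out <- "results/preprocess"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
truth <- read.delim("results/sim/truth_reads.tsv")

for (s in c("a", "b")) {
  pp <- preprocess_reads(file.path("results/sim/fastq",
                                   paste0("sample_", s, ".fastq")))
  write.table(pp$report, file.path(out, paste0("filter_report_", s, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pp$tags, file.path(out, paste0("tags_", s, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_tag_fasta(pp$tags, file.path(out, paste0("tags_", s, ".fa")))

  tr <- truth[truth$sample == s, ]
  message("sample ", s, ": ", pp$report$n_admitted, "/", pp$report$n_input,
          " admitted, ", nrow(pp$tags), " unique tags")
  stopifnot(
    pp$report$n_polyA_removed == sum(tr$class == "polyA"),
    pp$report$n_ambiguous_removed == sum(tr$class == "ambiguous"),
    pp$report$n_5p_adapter_removed == sum(tr$class == "adapter5"),
    sum(pp$tags$count) == pp$report$n_admitted
  )
}
message("filter reports agree exactly with the simulated class labels")
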