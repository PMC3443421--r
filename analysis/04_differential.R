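#!/usr/bin/env Rscript
# Step 4: two-condition differential calling on the simulated pair at
# the published thresholds (RPKM > 100 in at least one condition,
# |fold| >= 1.5), and a check that the planted 4-fold miRNA is called.

suppressMessages(library(smrnapipe))

out <- "results/differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_quant <- function(s) {
  read.delim(file.path("results/quant", paste0("quant_", s, ".tsv")),
             comment.char = "#")
}
d <- call_differential(read_quant("a"), read_quant("b"),
                       diff_config(rpkm_threshold = 100,
                                   fold_threshold = 1.5))
write_diff_tables(d, out)
write.table(d, file.path(out, "diff_all.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sum(d$side == "B_ENRICHED"), " B-enriched, ",
        sum(d$side == "A_ENRICHED"), " A-enriched of ", nrow(d), " miRNAs")
planted <- "sim-mir-16"
message("planted miRNA ", planted, ": fold = ",
        format(d$fold[d$name == planted], digits = 5),
        ", side = ", d$side[d$name == planted])
stopifnot(d$side[d$name == planted] == "B_ENRICHED")
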