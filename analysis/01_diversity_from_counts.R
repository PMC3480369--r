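#!/usr/bin/env Rscript
# Per-population haplotype diversity and the region-level differentiation
# analysis, computed from the packaged 50-population oak survey counts.
# Finding: diversity concentrates in Central-Eastern China (Hd up to 0.821
# in XY, 0.764 in HY) while most island populations are fixed; overall the
# marker is strongly structured (GST = 0.852, HT = 0.888, HS = 0.131),
# Central-Eastern China least so (GST = 0.690).

suppressMessages(library(cpphylo))
dir.create("results", showWarnings = FALSE)

ht <- load_table1_fixture()
cfg <- pipeline_config(counts = "table1", out_dir = "results",
                       n_perm = 1000, seed = 20260918)
res <- run_pipeline(cfg)

t3 <- read.delim(file.path("results", "table3_permut.tsv"))
cat("Differentiation by region (counts mode):\n")
print(t3, row.names = FALSE)

pd <- permut_diversity(ht)
cat(sprintf("\nOverall: HS = %.3f, HT = %.3f, GST = %.3f, Nm = %.3f\n",
            pd$HS, pd$HT, pd$GST, nm_from_gst(pd$GST)))
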