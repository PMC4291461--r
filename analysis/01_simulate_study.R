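#!/usr/bin/env Rscript
# Step 1 — plant the synthetic developmental study.
#
# A U5-like family of 7 genes (165 nt, 6 variable sites, all sequences
# distinct) is sampled together with a 5-stage mixture trajectory in which
# isoform 1 progressively dominates. Each stage gets Illumina-style 48-nt
# error-free read samples: embryo stages x4 replicates, larva x2, pharate
# adult x4. Everything is written under results/study/data/.

library(snquant)

seed <- 1L
out <- "results/study/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

stage_plan <- c(early_emb = 4, mid_emb = 4, late_emb = 4, L3 = 2, pharate = 4)
reads_per_sample <- 10000L
read_length <- 48L

fam <- generate_family(7, 165, 6, family = "SYN", seed = seed)
write_fasta(setNames(fam$genes$sequence, fam$genes$gene_id),
            file.path(out, "family.fasta"))
cat("Planted family: 7 genes, variable columns at",
    paste(fam$sites$column_1based, collapse = ", "), "\n")

groups <- collapse_identical(fam$genes)
mix <- generate_mixture_trajectory(nrow(groups), names(stage_plan),
                                   seed = seed + 1)
truth <- mix$fractions
colnames(truth) <- groups$group_id
write.table(data.frame(stage = rep(rownames(truth), each = ncol(truth)),
                       group = rep(colnames(truth), nrow(truth)),
                       fraction = as.vector(t(truth))),
            file.path(out, "mixture_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Dominant isoform trajectory:",
    paste(sprintf("%s=%.2f", rownames(truth), truth[, 1]), collapse = "  "), "\n")

sheet <- list(); i <- 0
for (stg in names(stage_plan)) {
  for (rep_i in seq_len(stage_plan[[stg]])) {
    i <- i + 1
    sid <- sprintf("%s_rep%d", stg, rep_i)
    sim <- simulate_reads(setNames(groups$sequence, groups$group_id),
                          truth[stg, ], reads_per_sample, read_length,
                          seed = seed + 100 + i, read_id_prefix = sid)
    write_fastq(sim, file.path(out, paste0(sid, ".fastq")))
    write.table(sim$truth, file.path(out, paste0(sid, ".truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sheet[[i]] <- data.frame(sample_id = sid,
                             fastq = file.path(out, paste0(sid, ".fastq")),
                             stage = stg, family = "SYN")
  }
}
write.table(do.call(rbind, sheet), file.path(out, "sample_sheet.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote", i, "samples x", reads_per_sample, "reads to", out, "\n")
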