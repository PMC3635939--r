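#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs with known ground truth.
#
# Emulates the study design: a reference genotype's 3'-cDNA contig
# assembly, 8 cultivated + 2 wild panel genotypes mutated from it
# (transition-biased, wild divergence mostly on a shared species branch),
# and per-genotype base-count pileups at the per-line mean read depths the
# study reported (8-31x). Everything downstream reads the files written
# here; the truth tables are kept for scoring.

suppressPackageStartupMessages(library(lenspipe))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- generate_reference(contig_spec(n_contigs = 300, dup_rate = 0.01,
                                      seed = 1001))
pan <- mutate_panel(ref, panel_spec(seed = 1002))
depths <- c(LC01 = 12, LC02 = 10, LC03 = 17, LC04 = 11, LC05 = 13,
            LC06 = 8, LC07 = 31, LC08 = 15, LE01 = 10, LE02 = 10)

write_contigs_fasta(ref$contigs, file.path(out, "reference_contigs.fa"))
write_anchors_gff3(ref$anchors, file.path(out, "gene_anchors.gff3"))
write_anchor_tsv(ref$duplicate_pairs, file.path(out, "duplicate_pairs.tsv"))
utils::write.table(ref$ssr_truth, file.path(out, "truth_ssrs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pan$truth, file.path(out, "truth_variants.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (g in pan$genotypes) {
  pu <- simulate_pileups(pan$haplotypes[g], depth_mean = depths[[g]],
                         error_rate = 0.002,
                         seed = 1010 + match(g, pan$genotypes))[[1]]
  write_pileup(pu, file.path(out, sprintf("pileup_%s.tsv", g)))
}

cat(sprintf(
  "simulated %d contigs (%.0f kb), %d genotypes, %d planted variants\n",
  length(ref$contigs), sum(nchar(ref$contigs)) / 1e3,
  length(pan$genotypes), nrow(unique(pan$truth[c("contig", "pos", "alt")]))))
cat(sprintf("planted SSR contigs: %d; duplicate pairs: %d\n",
            nrow(ref$ssr_truth), nrow(ref$duplicate_pairs)))
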