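#!/usr/bin/env Rscript
# Step 2: call SNPs per genotype from the pileups and merge them into the
# non-redundant multi-genotype table.
#
# The confidence rule is the study's: an alternate call needs >= 3 reads
# and >= 80% of the reads at the site; failures with any non-reference
# evidence are reported below-threshold at positions confident in some
# other genotype. Also scans the reference for SSRs.

suppressPackageStartupMessages(library(lenspipe))

src <- "results/simulated"
out <- "results/snps"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_contigs_fasta(file.path(src, "reference_contigs.fa"))
genos <- sub("^pileup_(.*)\\.tsv$", "\\1",
             list.files(src, pattern = "^pileup_.*\\.tsv$"))
calls <- lapply(genos, function(g) {
  pu <- read_pileup(file.path(src, sprintf("pileup_%s.tsv", g)))
  call_snps_per_genotype(pu, ref, g, min_reads = 3, min_fraction = 0.8)
})
tab <- suppressWarnings(merge_nonredundant(calls, ref))
write_snp_vcf(tab, file.path(out, "snps.vcf"))

s <- snp_summary(tab)
cult <- grep("^LC", genos, value = TRUE)
summary_df <- data.frame(
  n_snps = s$n_snps, n_transitions = s$n_transitions,
  n_transversions = s$n_transversions,
  transition_pct = round(100 * s$n_transitions / s$n_snps, 1),
  n_polymorphic_contigs = s$n_polymorphic_contigs,
  mean_alt_freq_all = round(allele_frequency_summary(tab), 3),
  mean_alt_freq_cultivated =
    round(allele_frequency_summary(tab, subset = cult), 3))
utils::write.table(summary_df, file.path(out, "snp_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

ssrs <- find_ssrs(ref)
utils::write.table(ssrs, file.path(out, "ssrs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth <- utils::read.table(file.path(src, "truth_variants.tsv"),
                           header = TRUE, sep = "\t")
truth_key <- unique(paste0(truth$contig, ":", truth$pos, ":", truth$alt))
called_key <- paste0(tab$snps$contig, ":", tab$snps$pos, ":",
                     tab$snps$alt)
cat(sprintf(
  "%d non-redundant SNPs on %d contigs (%.1f%% transitions)\n",
  s$n_snps, s$n_polymorphic_contigs, 100 * s$n_transitions / s$n_snps))
cat(sprintf("recall vs planted truth %.2f%%, precision %.2f%%\n",
            100 * mean(truth_key %in% called_key),
            100 * mean(called_key %in% truth_key)))
cat(sprintf("mean alt-allele frequency: %.3f all, %.3f cultivated\n",
            summary_df$mean_alt_freq_all,
            summary_df$mean_alt_freq_cultivated))
cat(sprintf("SSR-bearing contigs: %d (%.1f%%)\n",
            length(unique(ssrs$contig)),
            100 * length(unique(ssrs$contig)) / length(ref)))
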