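#!/usr/bin/env Rscript
# Step 4: select SNP candidates for a fixed-content genotyping array.
#
# Filters follow the study's assay-design rules: keep SNPs polymorphic in
# at least two cultivated genotypes versus the reference, drop SNPs with
# < 60 clean bp to the nearest contig end / other SNP / splice site, keep
# one SNP per predicted haplotype per contig and at most one assay per
# duplicated contig pair, then thin to the panel size by greedy
# farthest-point spread over the model-genome anchor coordinates. Emits
# the panel table and KASP-style bracketed flank sequences.

suppressPackageStartupMessages(library(lenspipe))

src <- "results/simulated"
out <- "results/array"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_contigs_fasta(file.path(src, "reference_contigs.fa"))
anchors <- read_anchors_gff3(file.path(src, "gene_anchors.gff3"))
dups <- read_anchor_tsv(file.path(src, "duplicate_pairs.tsv"))

genos <- sub("^pileup_(.*)\\.tsv$", "\\1",
             list.files(src, pattern = "^pileup_.*\\.tsv$"))
calls <- lapply(genos, function(g)
  call_snps_per_genotype(read_pileup(file.path(src,
                                               sprintf("pileup_%s.tsv", g))),
                         ref, g))
tab <- suppressWarnings(merge_nonredundant(calls, ref))
cult <- grep("^LC", genos, value = TRUE)

poly <- polymorphism_filter(tab, cult)
ff <- flank_filter(poly, ref, anchors, min_flank = 60)
keep <- poly$snps$snp_id %in% ff$snp_id[ff$pass]
cand <- poly
cand$snps <- poly$snps[keep, , drop = FALSE]
cand$status <- poly$status[keep, , drop = FALSE]

n_target <- 96
panel <- suppressWarnings(
  select_final(cand, anchors, n_target = n_target,
               duplicate_pairs = dups))
utils::write.table(panel, file.path(out, "array_panel.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

flank_lines <- vapply(seq_len(nrow(panel)), function(i) {
  kf <- kasp_flanks(ref[[panel$contig[i]]], panel$pos[i], panel$ref[i],
                    panel$alt[i], window = 60)
  sprintf(">%s%s\n%s", panel$snp_id[i],
          if (kf$truncated_left || kf$truncated_right) " [truncated]" else "",
          kf$flank)
}, character(1))
writeLines(flank_lines, file.path(out, "kasp_flanks.txt"))

cat(sprintf(
  "%d SNPs -> %d after cultivated-polymorphism filter -> %d after 60 bp flank rule\n",
  nrow(tab$snps), nrow(poly$snps), nrow(cand$snps)))
cat(sprintf("selected %d assays on %d contigs (target %d)\n",
            nrow(panel), length(unique(panel$contig)), n_target))
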