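#' Default amino-acid property groups
#'
#' Four physico-chemical groups used to grade non-synonymous changes:
#' acidic \{D,E\}, basic \{K,R,H\}, polar uncharged \{S,T,N,Q,C,Y\},
#' nonpolar \{A,V,L,I,M,F,W,G,P\}. The grouping is a configurable default,
#' not a fixed constant: pass any named vector mapping one-letter amino
#' acids to group labels.
#'
#' @return Named character vector: amino acid -> property group.
#' @export
aa_property_groups <- function() {
  c(D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic",
    S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
    Y = "polar",
    A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
    M = "nonpolar", F = "nonpolar", W = "nonpolar", G = "nonpolar",
    P = "nonpolar")
}

# assemble a gene_anchor_set data frame from anchor rows + structure truth
build_gene_anchor_set <- function(anc_df, contig_table, per_contig) {
  idx <- match(anc_df$contig, contig_table$contig)
  names(per_contig) <- vapply(per_contig, function(p) p$contig, character(1))
  jx <- vapply(anc_df$contig, function(ct) {
    j <- per_contig[[ct]]$junctions
    if (length(j)) paste(j, collapse = ",") else ""
  }, character(1))
  df <- data.frame(
    contig = anc_df$contig, gene_id = anc_df$gene_id,
    strand = anc_df$strand,
    cds_start = contig_table$cds_start[idx],
    cds_end = contig_table$cds_end[idx],
    utr3_start = contig_table$utr3_start[idx],
    utr3_end = contig_table$utr3_end[idx],
    junctions = unname(jx),
    model_chrom = anc_df$model_chrom, model_pos = anc_df$model_pos,
    align_len = anc_df$align_len, identity = anc_df$identity,
    stringsAsFactors = FALSE)
  rownames(df) <- df$contig
  class(df) <- c("gene_anchor_set", "data.frame")
  df
}

anchor_for <- function(anchors, contig) {
  if (!contig %in% rownames(anchors)) return(NULL)
  anchors[contig, , drop = FALSE]
}

parse_junctions <- function(x) {
  if (is.na(x) || !nzchar(x)) integer(0)
  else as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Anchor contigs onto a model gene database by exact-seed matching
#'
#' A light-weight anchorer adequate for synthetic and low-divergence data:
#' for each contig, `k`-mer probes are matched exactly (both strands)
#' against the gene mRNA sequences; a hit fixes the offset of an ungapped
#' overlap alignment whose identity and aligned length score the anchor.
#' At most one anchor is retained per contig (best aligned length x
#' identity). For real cross-species data a dedicated spliced aligner
#' should produce the anchor table instead; see [read_anchors_gff3()] for
#' ingesting precomputed anchors.
#'
#' @param contigs Named character vector of contig sequences.
#' @param gene_db Named character vector of model gene mRNA sequences.
#' @param k Probe k-mer length (default 21).
#' @param min_identity Minimum overlap identity to accept (default 0.8).
#' @param min_overlap Minimum overlap length in bp (default 100).
#' @return Data frame `contig`, `gene_id`, `strand`, `align_len`,
#'   `identity`; unanchored contigs are listed in the `unanchored`
#'   attribute.
#' @export
anchor_contigs <- function(contigs, gene_db, k = 21, min_identity = 0.8,
                           min_overlap = 100) {
  if (anyDuplicated(names(contigs))) stop_input("contig ids must be unique")
  score_pair <- function(ctg, gene) {
    # probe k-mers every 50 bp
    L <- nchar(ctg)
    starts <- unique(pmin(seq(1L, max(L - k + 1L, 1L), by = 50L), L - k + 1L))
    best <- NULL
    for (s in starts) {
      probe <- substr(ctg, s, s + k - 1L)
      hit <- regexpr(probe, gene, fixed = TRUE)[1]
      if (hit < 0L) next
      off <- hit - s  # gene = contig + off
      a1 <- max(1L, 1L + off); a2 <- min(nchar(gene), L + off)
      ov <- a2 - a1 + 1L
      if (ov < min_overlap) next
      cs <- substr(ctg, a1 - off, a2 - off)
      gs <- substr(gene, a1, a2)
      idt <- mean(strsplit(cs, "", fixed = TRUE)[[1]] ==
                    strsplit(gs, "", fixed = TRUE)[[1]])
      cand <- c(len = ov, identity = idt)
      if (is.null(best) || cand["len"] * cand["identity"] >
          best["len"] * best["identity"]) best <- cand
      break  # one seed fixes the ungapped offset
    }
    best
  }
  rows <- list(); unanchored <- character(0)
  for (ct in names(contigs)) {
    best <- NULL
    for (strand in c("+", "-")) {
      ctg <- if (strand == "+") contigs[[ct]] else revcomp(contigs[[ct]])
      for (gid in names(gene_db)) {
        sc <- score_pair(ctg, gene_db[[gid]])
        if (is.null(sc) || sc["identity"] < min_identity) next
        cand <- list(gene_id = gid, strand = strand,
                     align_len = unname(sc["len"]),
                     identity = unname(sc["identity"]))
        if (is.null(best) ||
            cand$align_len * cand$identity >
            best$align_len * best$identity) best <- cand
      }
    }
    if (is.null(best)) unanchored <- c(unanchored, ct)
    else rows[[ct]] <- data.frame(contig = ct, gene_id = best$gene_id,
                                  strand = best$strand,
                                  align_len = best$align_len,
                                  identity = best$identity,
                                  stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), gene_id = character(),
               strand = character(), align_len = numeric(),
               identity = numeric())
  rownames(res) <- NULL
  structure(res, unanchored = unanchored)
}

#' Classify a SNP position as CDS, 3'-UTR or unassigned
#'
#' @param contig,pos SNP location (contig id, 1-based position).
#' @param anchors A `gene_anchor_set`.
#' @return `"CDS"`, `"UTR3"` or `"UNASSIGNED"` (vectorised over inputs).
#' @export
classify_region <- function(contig, pos, anchors) {
  mapply(function(ct, p) {
    a <- anchor_for(anchors, ct)
    if (is.null(a)) return("UNASSIGNED")
    if (p >= a$cds_start && p <= a$cds_end) "CDS"
    else if (!is.na(a$utr3_start) && p >= a$utr3_start && p <= a$utr3_end)
      "UTR3"
    else "UNASSIGNED"
  }, contig, pos, USE.NAMES = FALSE)
}

#' Classify the impact of a single-base codon change
#'
#' Translates the reference and alternate codons with the standard genetic
#' code and grades the change: `SYNONYMOUS` (same amino acid, neither a
#' stop), `STOP_GAIN` (alternate codon is a stop; overrides the other
#' classes), `NONSYN_SAME_PROP` / `NONSYN_DIFF_PROP` (different amino acid
#' with the same / a different physico-chemical property group). Changes in
#' a reference stop codon, or codons containing N, return `NA`.
#'
#' @param codon_ref,codon_alt Upper-case codon triplets.
#' @param properties Amino-acid property map (default
#'   [aa_property_groups()]).
#' @return Character vector of impact classes (vectorised).
#' @export
classify_codon_change <- function(codon_ref, codon_alt,
                                  properties = aa_property_groups()) {
  gc <- Biostrings::GENETIC_CODE
  mapply(function(cr, ca) {
    if (is.na(cr) || is.na(ca) || grepl("[^ACGT]", cr) || grepl("[^ACGT]", ca))
      return(NA_character_)
    aa_r <- unname(gc[cr]); aa_a <- unname(gc[ca])
    if (is.na(aa_r) || is.na(aa_a)) return(NA_character_)
    if (aa_r == "*") return(NA_character_)   # stop-loss/retained: unclassed
    if (aa_a == "*") return("STOP_GAIN")
    if (aa_r == aa_a) return("SYNONYMOUS")
    if (identical(unname(properties[aa_r]), unname(properties[aa_a])))
      "NONSYN_SAME_PROP" else "NONSYN_DIFF_PROP"
  }, codon_ref, codon_alt, USE.NAMES = FALSE)
}

# strand-corrected codon extraction: returns codon_ref/codon_alt/codon_pos
# for a SNP inside the anchored CDS, or NULL if frame is not determinable
extract_codon <- function(seq, anchor, pos, ref, alt) {
  cs <- anchor$cds_start; ce <- anchor$cds_end
  if (pos < cs || pos > ce) return(NULL)
  if (anchor$strand == "-") {
    L <- nchar(seq)
    seq <- revcomp(seq)
    p2 <- L - pos + 1L
    iv <- flip_interval(cs, ce, L)
    cs <- iv[1]; ce <- iv[2]
    pos <- p2
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  cds_off <- pos - cs             # 0-based offset into CDS
  codon_i <- cds_off %/% 3L
  codon_pos <- cds_off %% 3L
  c_start <- cs + codon_i * 3L
  if (c_start + 2L > ce) return(NULL)  # trailing partial codon
  codon_ref <- substr(seq, c_start, c_start + 2L)
  if (substr(codon_ref, codon_pos + 1L, codon_pos + 1L) != ref)
    return(NULL)  # reference mismatch: frame not trustworthy
  codon_alt <- codon_ref
  substr(codon_alt, codon_pos + 1L, codon_pos + 1L) <- alt
  list(codon_ref = codon_ref, codon_alt = codon_alt, codon_pos = codon_pos)
}

#' Annotate a SNP table with region and codon impact
#'
#' For every SNP: the region (CDS / 3'-UTR / unassigned) from the contig's
#' gene anchor, and, for CDS SNPs with a determinable frame, the
#' strand-corrected reference and alternate codons, amino acids and impact
#' class from [classify_codon_change()].
#'
#' @param snp_table A `snp_table`.
#' @param reference Named character vector of contig sequences.
#' @param anchors A `gene_anchor_set`.
#' @param properties Amino-acid property map.
#' @return The `snp_table` with its `snps` data frame gaining columns
#'   `region`, `codon_ref`, `codon_alt`, `codon_pos`, `aa_ref`, `aa_alt`,
#'   `impact`.
#' @export
annotate_snps <- function(snp_table, reference, anchors,
                          properties = aa_property_groups()) {
  snps <- snp_table$snps
  gc <- Biostrings::GENETIC_CODE
  snps$region <- classify_region(snps$contig, snps$pos, anchors)
  snps$codon_ref <- snps$codon_alt <- NA_character_
  snps$codon_pos <- NA_integer_
  snps$aa_ref <- snps$aa_alt <- NA_character_
  snps$impact <- NA_character_
  cds_rows <- which(snps$region == "CDS")
  for (i in cds_rows) {
    a <- anchor_for(anchors, snps$contig[i])
    cx <- extract_codon(reference[[snps$contig[i]]], a, snps$pos[i],
                        snps$ref[i], snps$alt[i])
    if (is.null(cx)) next
    snps$codon_ref[i] <- cx$codon_ref
    snps$codon_alt[i] <- cx$codon_alt
    snps$codon_pos[i] <- cx$codon_pos
    snps$aa_ref[i] <- unname(gc[cx$codon_ref])
    snps$aa_alt[i] <- unname(gc[cx$codon_alt])
    snps$impact[i] <- classify_codon_change(cx$codon_ref, cx$codon_alt,
                                            properties)
  }
  snp_table$snps <- snps
  snp_table
}
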