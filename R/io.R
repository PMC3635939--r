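#' Read and write reference contigs as FASTA
#'
#' Thin wrappers over Biostrings; sequences are handled in-package as named
#' character vectors.
#'
#' @param contigs Named character vector of sequences.
#' @param path File path.
#' @return `read_contigs_fasta()` returns a named character vector.
#' @export
write_contigs_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_contigs_fasta
#' @export
read_contigs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write and read per-genotype pileups as TSV
#'
#' Columns `contig`, `pos` (1-based), `depth`, `A`, `C`, `G`, `T`.
#'
#' @param pileup Pileup data frame.
#' @param path File path.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "integer",
                                   "integer", "integer", "integer",
                                   "integer"))
}

#' Export gene anchors (with contig gene structure) as GFF3
#'
#' Each anchored contig is written as an `mRNA` feature spanning the
#' contig, `CDS` feature(s) with phase (split at exon junctions), and a
#' `three_prime_UTR` feature, all in contig coordinates. Model-genome
#' placement (`model_chrom`, `model_pos`, `align_len`, `identity`) rides
#' along as attributes of the mRNA. [read_anchors_gff3()] reconstructs the
#' `gene_anchor_set`.
#'
#' @param anchors A `gene_anchor_set`.
#' @param path Output GFF3 path.
#' @export
write_anchors_gff3 <- function(anchors, path) {
  feats <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    contig_len <- max(a$cds_end, a$utr3_end, na.rm = TRUE)
    jx <- parse_junctions(a$junctions)
    mrna <- data.frame(seqnames = a$contig, start = 1L, end = contig_len,
                       strand = a$strand, type = "mRNA",
                       ID = paste0(a$contig, ".mRNA"),
                       gene_id = a$gene_id, model_chrom = a$model_chrom,
                       model_pos = a$model_pos, align_len = a$align_len,
                       identity = a$identity, phase = NA_integer_,
                       stringsAsFactors = FALSE)
    cuts <- sort(unique(c(jx[jx >= a$cds_start & jx < a$cds_end])))
    starts <- c(a$cds_start, cuts + 1L)
    ends <- c(cuts, a$cds_end)
    # phase: bases to skip to reach a codon start, in transcription order
    lens <- ends - starts + 1L
    if (a$strand == "-") { starts <- rev(starts); ends <- rev(ends)
      lens <- rev(lens) }
    off <- cumsum(c(0L, lens[-length(lens)]))
    phase <- (3L - off %% 3L) %% 3L
    cds <- data.frame(seqnames = a$contig, start = starts, end = ends,
                      strand = a$strand, type = "CDS",
                      ID = paste0(a$contig, ".CDS", seq_along(starts)),
                      gene_id = a$gene_id, model_chrom = NA, model_pos = NA,
                      align_len = NA, identity = NA, phase = phase,
                      stringsAsFactors = FALSE)
    utr <- if (!is.na(a$utr3_start) && a$utr3_end >= a$utr3_start)
      data.frame(seqnames = a$contig, start = a$utr3_start,
                 end = a$utr3_end, strand = a$strand,
                 type = "three_prime_UTR",
                 ID = paste0(a$contig, ".UTR3"), gene_id = a$gene_id,
                 model_chrom = NA, model_pos = NA, align_len = NA,
                 identity = NA, phase = NA_integer_,
                 stringsAsFactors = FALSE) else NULL
    feats[[i]] <- rbind(mrna, cds, utr)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, ID = df$ID, gene_id = df$gene_id,
    model_chrom = df$model_chrom, model_pos = df$model_pos,
    align_len = df$align_len, identity = df$identity, phase = df$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_anchors_gff3
#' @param path GFF3 path written by [write_anchors_gff3()].
#' @return A `gene_anchor_set`.
#' @export
read_anchors_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop_input("GFF3 parse error in ", path, ": ",
                              conditionMessage(e)))
  df <- as.data.frame(gr)
  rows <- list()
  for (ct in unique(as.character(df$seqnames))) {
    sub <- df[df$seqnames == ct, ]
    mrna <- sub[sub$type == "mRNA", ][1, ]
    cds <- sub[sub$type == "CDS", ]
    utr <- sub[sub$type == "three_prime_UTR", ]
    jx <- if (nrow(cds) > 1L) sort(cds$end)[-nrow(cds)] else integer(0)
    rows[[ct]] <- data.frame(
      contig = ct, gene_id = as.character(mrna$gene_id),
      strand = as.character(mrna$strand),
      cds_start = min(cds$start), cds_end = max(cds$end),
      utr3_start = if (nrow(utr)) utr$start[1] else NA_integer_,
      utr3_end = if (nrow(utr)) utr$end[1] else NA_integer_,
      junctions = if (length(jx)) paste(jx, collapse = ",") else "",
      model_chrom = as.character(mrna$model_chrom),
      model_pos = as.numeric(mrna$model_pos),
      align_len = as.numeric(mrna$align_len),
      identity = as.numeric(mrna$identity),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$contig
  class(out) <- c("gene_anchor_set", "data.frame")
  out
}

#' Write a SNP table as VCF v4.2
#'
#' `CHROM` is the contig, `POS` 1-based, with per-sample `GT:FT` fields:
#' genotype `0/0`, `1/1` or `./.` and filter `PASS`, `LOWCONF` (below the
#' confidence thresholds) or `MISSING`. INFO carries `TSTV` and, when the
#' table is annotated, `REGION`, `IMPACT`, `CODON` and `AA`.
#'
#' @param snp_table A `snp_table`.
#' @param path Output path.
#' @param reference_name Name recorded for the reference genotype column
#'   (not emitted as a sample).
#' @export
write_snp_vcf <- function(snp_table, path, reference_name = "REF") {
  snps <- snp_table$snps
  st <- snp_table$status
  genos <- colnames(st)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=lenspipe;reference=%s", reference_name),
    "##INFO=<ID=TSTV,Number=1,Type=String,Description=\"transition or transversion\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"CDS, UTR3 or UNASSIGNED\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"codon impact class\">",
    "##INFO=<ID=CODON,Number=1,Type=String,Description=\"ref>alt codon\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"ref>alt amino acid\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"PASS, LOWCONF or MISSING\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genos), collapse = "\t")), con)
  if (nrow(snps)) {
    info <- paste0("TSTV=", snps$class)
    if ("region" %in% names(snps)) {
      info <- paste0(info, ";REGION=", snps$region)
      has_imp <- !is.na(snps$impact)
      info[has_imp] <- paste0(
        info[has_imp], ";IMPACT=", snps$impact[has_imp],
        ";CODON=", snps$codon_ref[has_imp], ">", snps$codon_alt[has_imp],
        ";AA=", snps$aa_ref[has_imp], ">", snps$aa_alt[has_imp])
    }
    gt <- matrix("", nrow(snps), length(genos))
    for (j in seq_along(genos)) {
      s <- st[, j]
      gt[, j] <- ifelse(s == "ALT", "1/1:PASS",
                        ifelse(s == "REF", "0/0:PASS",
                               ifelse(s == "BELOW_THRESHOLD", "./.:LOWCONF",
                                      "./.:MISSING")))
    }
    lines <- paste(snps$contig, snps$pos, snps$snp_id, snps$ref, snps$alt,
                   ".", "PASS", info, "GT:FT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write/read a marker genotype matrix TSV
#'
#' Rows are markers, columns individuals, calls in `A`/`B`/`H`/`U`.
#'
#' @param calls Character matrix.
#' @param path File path.
#' @export
write_genotype_matrix <- function(calls, path) {
  df <- data.frame(marker = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$marker
  m
}

#' Write/read a synteny anchor TSV
#'
#' Columns `marker`, `lg`, `cM`, `model_chrom`, `model_pos`, `align_len`,
#' `identity` (or, for contig anchors, `contig` in place of
#' `marker`/`lg`/`cM`).
#'
#' @param anchors Anchor data frame.
#' @param path File path.
#' @export
write_anchor_tsv <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchor_tsv
#' @export
read_anchor_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a linkage map TSV (`group  marker  cM`)
#'
#' @param linkage_map A `linkage_map` from [build_linkage_map()].
#' @param path File path.
#' @export
write_map_tsv <- function(linkage_map, path) {
  utils::write.table(linkage_map$map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
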