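#' Keep SNPs polymorphic among cultivated genotypes versus the reference
#'
#' A SNP survives iff at least two cultivated genotypes carry a confident
#' alternate allele relative to the reference; alternate alleles seen only
#' in wild accessions are removed.
#'
#' @param snp_table A `snp_table`.
#' @param cultivated Cultivated genotype names (columns of the status
#'   matrix).
#' @param min_alt Minimum cultivated genotypes with confident ALT
#'   (default 2).
#' @return The `snp_table` restricted to surviving records.
#' @export
polymorphism_filter <- function(snp_table, cultivated, min_alt = 2) {
  unknown <- setdiff(cultivated, colnames(snp_table$status))
  if (length(unknown))
    stop_input("genotype(s) not in panel: ", paste(unknown, collapse = ", "))
  n_alt <- rowSums(snp_table$status[, cultivated, drop = FALSE] == "ALT")
  keep <- n_alt >= min_alt
  snp_table$snps <- snp_table$snps[keep, , drop = FALSE]
  snp_table$status <- snp_table$status[keep, , drop = FALSE]
  rownames(snp_table$snps) <- NULL
  snp_table
}

#' Flanking-region filter for array assay design
#'
#' For each SNP, the distance (in bp between positions, exclusive of the
#' SNP base) to the nearest contig end, other recorded SNP, and splice
#' site is computed on each side; the SNP fails if the minimum on either
#' side is below `min_flank`. A distance of exactly `min_flank` passes.
#'
#' @param snp_table A `snp_table`.
#' @param reference Named character vector of contig sequences.
#' @param anchors Optional `gene_anchor_set` supplying splice-site
#'   (exon-junction) positions per contig.
#' @param min_flank Minimum clean flank in bp (default 60).
#' @return Data frame `snp_id`, `left_flank`, `right_flank`, `pass`,
#'   `fail_reason`.
#' @export
flank_filter <- function(snp_table, reference, anchors = NULL,
                         min_flank = 60) {
  snps <- snp_table$snps
  out <- data.frame(snp_id = snps$snp_id,
                    left_flank = NA_real_, right_flank = NA_real_,
                    pass = NA, fail_reason = NA_character_,
                    stringsAsFactors = FALSE)
  by_contig <- split(seq_len(nrow(snps)), snps$contig)
  for (ct in names(by_contig)) {
    idx <- by_contig[[ct]]
    pos <- snps$pos[idx]
    len <- nchar(reference[[ct]])
    jx <- if (!is.null(anchors) && ct %in% rownames(anchors))
      parse_junctions(anchors[ct, "junctions"]) else integer(0)
    for (k in seq_along(idx)) {
      p <- pos[k]
      others <- pos[-k]
      left_cands <- c(p - 1L,                       # to contig start
                      p - others[others < p],       # to nearer SNPs
                      p - jx[jx < p])               # to splice sites
      right_cands <- c(len - p,
                       others[others > p] - p,
                       jx[jx >= p] - p)
      # splice site between jx and jx+1: site at p counts on the right
      lf <- min(left_cands); rf <- min(right_cands)
      pass <- lf >= min_flank && rf >= min_flank
      reason <- if (pass) NA_character_
      else if (lf < min_flank) "left" else "right"
      out[idx[k], c("left_flank", "right_flank")] <- c(lf, rf)
      out$pass[idx[k]] <- pass
      out$fail_reason[idx[k]] <- reason
    }
  }
  out
}

# per-contig haplotype id: the pattern of per-genotype statuses
haplotype_ids <- function(snp_table) {
  apply(snp_table$status, 1L, function(s) paste(s, collapse = "|"))
}

#' Select the final fixed-content array panel
#'
#' Applies, in order: optional external design-score exclusion (scores
#' `<= 0.4` are dropped; scores `> 0.6` are preferred), one SNP per
#' predicted haplotype per contig (the haplotype is the exact per-genotype
#' status vector), at most one assay per duplicated-contig pair, then
#' greedy farthest-point thinning on model-genome anchor coordinates until
#' `n_target` assays remain. High-scoring candidates (> 0.6, or all
#' candidates when no scores are supplied) are spread first; remaining
#' slots are filled from the lower tier. Deterministic: ties break
#' lexicographically on SNP id, and initialisation is the smallest
#' concatenated-genome coordinate.
#'
#' @param snp_table A `snp_table` (post [polymorphism_filter()] and
#'   [flank_filter()]).
#' @param anchors A `gene_anchor_set` giving `model_chrom`/`model_pos` per
#'   contig; unanchored contigs are only drawn on after anchored ones.
#' @param n_target Panel size (default 1536).
#' @param scores Optional named numeric vector of external design scores in
#'   `[0,1]` keyed by `snp_id`.
#' @param duplicate_pairs Optional data frame `contig`, `duplicate` of
#'   near-identical contig pairs contributing at most one assay.
#' @return Data frame of selected records: `snp_id`, `contig`, `pos`,
#'   `ref`, `alt`, `haplotype_id`, `model_chrom`, `model_pos`, `score`.
#' @export
select_final <- function(snp_table, anchors, n_target = 1536, scores = NULL,
                         duplicate_pairs = NULL) {
  snps <- snp_table$snps
  if (!nrow(snps)) return(snps)
  hap <- haplotype_ids(snp_table)
  sc <- if (is.null(scores)) rep(NA_real_, nrow(snps)) else
    unname(scores[snps$snp_id])
  cand <- cbind(snps, haplotype_id = hap, score = sc,
                stringsAsFactors = FALSE)

  if (!is.null(scores)) cand <- cand[is.na(cand$score) | cand$score > 0.4, ]

  # one per haplotype per contig: prefer high score, then lexicographic id
  pref <- order(cand$contig, cand$haplotype_id,
                -ifelse(is.na(cand$score), 0.5, cand$score), cand$snp_id)
  cand <- cand[pref, ]
  cand <- cand[!duplicated(cand[c("contig", "haplotype_id")]), ]

  # duplicated contigs contribute at most one assay
  if (!is.null(duplicate_pairs) && nrow(duplicate_pairs)) {
    grp <- stats::setNames(duplicate_pairs$contig, duplicate_pairs$duplicate)
    family <- ifelse(cand$contig %in% names(grp), grp[cand$contig],
                     cand$contig)
    keep1 <- order(-ifelse(is.na(cand$score), 0.5, cand$score), cand$snp_id)
    cand <- cand[keep1, ][!duplicated(family[keep1]), ]
  }

  # anchor coordinates on a concatenated genome axis
  has_anchor <- cand$contig %in% rownames(anchors)
  mc <- rep(NA_character_, nrow(cand)); mp <- rep(NA_real_, nrow(cand))
  mc[has_anchor] <- anchors[cand$contig[has_anchor], "model_chrom"]
  mp[has_anchor] <- anchors[cand$contig[has_anchor], "model_pos"]
  cand$model_chrom <- mc; cand$model_pos <- mp
  if (nrow(cand) <= n_target) {
    if (nrow(cand) < n_target)
      warning("fewer candidates (", nrow(cand), ") than n_target (",
              n_target, "); returning all")
    rownames(cand) <- NULL
    return(cand[order(cand$snp_id), ])
  }

  chroms <- sort(unique(stats::na.omit(mc)))
  offset <- stats::setNames(seq_along(chroms) * 1e9, chroms)
  coord <- ifelse(has_anchor, offset[mc] + mp, NA_real_)

  high <- if (is.null(scores)) rep(TRUE, nrow(cand)) else
    !is.na(cand$score) & cand$score > 0.6

  pick_spread <- function(pool_idx, n_pick, already) {
    anch <- pool_idx[!is.na(coord[pool_idx])]
    rest <- pool_idx[is.na(coord[pool_idx])]
    sel <- integer(0)
    if (length(anch)) {
      chosen <- already[!is.na(coord[already])]
      dmin <- rep(Inf, length(anch))
      for (cp in coord[chosen]) dmin <- pmin(dmin, abs(coord[anch] - cp))
      if (!length(chosen)) {
        first <- order(coord[anch], cand$snp_id[anch])[1]
        sel <- anch[first]
        dmin <- pmin(dmin, abs(coord[anch] - coord[anch[first]]))
        dmin <- dmin[-first]; anch <- anch[-first]
      }
      while (length(sel) < n_pick && length(anch)) {
        best <- which(dmin == max(dmin))
        best <- best[order(cand$snp_id[anch[best]])][1]
        newc <- coord[anch[best]]
        sel <- c(sel, anch[best])
        dmin <- dmin[-best]; anch <- anch[-best]
        if (length(anch)) dmin <- pmin(dmin, abs(coord[anch] - newc))
      }
    }
    if (length(sel) < n_pick && length(rest)) {
      rest <- rest[order(cand$snp_id[rest])]
      sel <- c(sel, rest[seq_len(min(n_pick - length(sel), length(rest)))])
    }
    sel
  }

  sel <- pick_spread(which(high), min(n_target, sum(high)), integer(0))
  if (length(sel) < n_target)
    sel <- c(sel, pick_spread(which(!high), n_target - length(sel), sel))
  res <- cand[sort(sel), ]
  rownames(res) <- NULL
  res
}

#' KASP-style flank string for a SNP
#'
#' Emits the standard submission format `LEFT[REF/ALT]RIGHT` with `window`
#' bp of contig sequence on each side; flanks truncated at contig ends are
#' flagged.
#'
#' @param contig_seq Contig sequence (character string).
#' @param pos 1-based SNP position.
#' @param ref,alt Alleles.
#' @param window Flank width in bp (default 60).
#' @return List `flank` (the string), `truncated_left`, `truncated_right`.
#' @export
kasp_flanks <- function(contig_seq, pos, ref, alt, window = 60) {
  L <- nchar(contig_seq)
  if (pos < 1L || pos > L) stop_input("SNP position outside contig")
  if (substr(contig_seq, pos, pos) != ref)
    stop_input("reference allele does not match the contig sequence")
  lstart <- max(1L, pos - window)
  rend <- min(L, pos + window)
  list(flank = paste0(substr(contig_seq, lstart, pos - 1L),
                      "[", ref, "/", alt, "]",
                      substr(contig_seq, pos + 1L, rend)),
       truncated_left = lstart > pos - window,
       truncated_right = rend < pos + window)
}

#' Parse a KASP flank string back into its parts
#'
#' Inverse of [kasp_flanks()]: recovers the left/right flank sequences and
#' the two alleles from `LEFT[REF/ALT]RIGHT`.
#'
#' @param flank Flank string.
#' @return List `left`, `ref`, `alt`, `right`.
#' @export
parse_kasp_flank <- function(flank) {
  m <- regmatches(flank,
                  regexec("^([ACGT]*)\\[([ACGT])/([ACGT])\\]([ACGT]*)$",
                          flank))[[1]]
  if (length(m) != 5L) stop_input("not a valid flank string")
  list(left = m[2], ref = m[3], alt = m[4], right = m[5])
}
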