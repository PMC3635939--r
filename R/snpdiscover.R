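#' Filter a reference contig set for SNP calling
#'
#' Removes contigs flagged as repeat-class and contigs shorter than
#' `min_len` (length filter inclusive: a 200 bp contig is kept at the
#' default). Removal reasons are attached as the `"removed"` attribute.
#'
#' @param contigs Named character vector of contig sequences, or a
#'   `DNAStringSet`.
#' @param min_len Minimum retained length in bp (default 200).
#' @param repeat_class Character vector of contig ids flagged repeat-class.
#' @return Named character vector of retained contigs, with a `removed`
#'   attribute data frame (`contig`, `reason`).
#' @export
filter_reference <- function(contigs, min_len = 200, repeat_class = character(0)) {
  if (methods::is(contigs, "DNAStringSet")) {
    nm <- names(contigs)
    contigs <- as.character(contigs)
    names(contigs) <- nm
  }
  if (length(contigs) == 0L) {
    warning("empty contig set")
    return(structure(contigs, removed = data.frame(contig = character(),
                                                   reason = character())))
  }
  if (is.null(names(contigs))) stop_input("contigs must be named")
  too_short <- nchar(contigs) < min_len
  is_rep <- names(contigs) %in% repeat_class
  removed <- data.frame(
    contig = names(contigs)[too_short | is_rep],
    reason = ifelse(is_rep[too_short | is_rep], "repeat_class", "too_short"),
    stringsAsFactors = FALSE)
  keep <- contigs[!(too_short | is_rep)]
  structure(keep, removed = removed)
}

#' Call substitution SNPs for one genotype from a base-count pileup
#'
#' Implements the read-depth confidence rule: a site is a confident
#' alternate-allele call iff the most frequent non-reference base is
#' supported by at least `min_reads` reads *and* by at least `min_fraction`
#' of all reads at the site (both boundaries inclusive, so the failing set
#' is "<80% or <3 reads"). Sites with at least one non-reference read that
#' fail either rule are recorded as below-threshold; zero-depth sites are
#' missing.
#'
#' @param pileup Data frame `contig`, `pos`, `depth`, `A`, `C`, `G`, `T`.
#' @param reference Named character vector of contig sequences.
#' @param genotype Genotype label carried through to the calls.
#' @param min_reads Minimum alternate-supporting reads (default 3).
#' @param min_fraction Minimum alternate fraction of all reads at the site
#'   (default 0.8).
#' @return An object of class `genotype_calls`: list with `genotype`,
#'   `calls` (data frame `contig`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_reads`, `status` in `ALT`/`BELOW`), and `covered` (logical map of
#'   depth>0 sites keyed `"contig:pos"`).
#' @export
call_snps_per_genotype <- function(pileup, reference, genotype = "sample",
                                   min_reads = 3, min_fraction = 0.8) {
  need <- c("contig", "pos", "depth", DNA_BASES)
  if (!all(need %in% names(pileup)))
    stop_input("pileup needs columns contig, pos, depth, A, C, G, T")
  unknown <- setdiff(unique(pileup$contig), names(reference))
  if (length(unknown))
    stop_input("pileup contig(s) absent from reference: ",
               paste(unknown, collapse = ", "))
  bad <- pileup$pos < 1L | pileup$pos > nchar(reference)[
    match(pileup$contig, names(reference))]
  if (any(bad)) stop_input("pileup positions outside reference contigs")

  counts <- as.matrix(pileup[DNA_BASES])
  if (!all(rowSums(counts) == pileup$depth))
    stop_input("base counts must sum to depth")
  ref <- base_at(reference, pileup$contig, pileup$pos)
  ridx <- match(ref, DNA_BASES)
  nonref <- counts
  nonref[cbind(seq_len(nrow(counts)), ridx)] <- -1L
  top <- max.col(nonref, ties.method = "first")
  alt_reads <- nonref[cbind(seq_len(nrow(counts)), top)]
  alt_reads[alt_reads < 0L] <- 0L
  alt <- DNA_BASES[top]

  has_evidence <- alt_reads > 0L
  confident <- alt_reads >= min_reads &
    alt_reads >= min_fraction * pileup$depth
  status <- ifelse(confident & has_evidence, "ALT",
                   ifelse(has_evidence, "BELOW", NA_character_))
  keep <- !is.na(status)
  calls <- data.frame(contig = pileup$contig[keep], pos = pileup$pos[keep],
                      ref = ref[keep], alt = alt[keep],
                      depth = pileup$depth[keep],
                      alt_reads = alt_reads[keep], status = status[keep],
                      stringsAsFactors = FALSE)
  covered <- pileup$depth > 0L
  covered_key <- paste0(pileup$contig[covered], ":", pileup$pos[covered])
  structure(list(genotype = genotype, calls = calls,
                 covered = covered_key,
                 params = list(min_reads = min_reads,
                               min_fraction = min_fraction)),
            class = "genotype_calls")
}

#' Merge per-genotype calls into a non-redundant SNP table
#'
#' One record is created per (contig, pos, alt) combination that is a
#' confident alternate call in at least one genotype. Every other genotype
#' receives a status at that record: `ALT` (confident, same alternate),
#' `BELOW_THRESHOLD` (non-reference evidence at the position that is either
#' below the confidence rule or supports a different base), `REF` (covered,
#' no conflicting evidence), or `MISSING` (no sequence data).
#' Below-threshold evidence is only ever reported at positions confident in
#' some genotype. Sites where two genotypes are confident for different
#' alternate bases become separate biallelic records and raise a
#' multi-allelic warning.
#'
#' @param calls_list List of `genotype_calls` from
#'   [call_snps_per_genotype()].
#' @param reference Named character vector of contig sequences.
#' @return A `snp_table`: list with `snps` (data frame `snp_id`, `contig`,
#'   `pos`, `ref`, `alt`, `class`) and `status` (character matrix records x
#'   genotypes).
#' @export
merge_nonredundant <- function(calls_list, reference) {
  if (!length(calls_list)) stop_input("no genotype calls supplied")
  genos <- vapply(calls_list, function(x) x$genotype, character(1))
  if (anyDuplicated(genos)) stop_input("duplicate genotype labels")
  names(calls_list) <- genos

  conf <- do.call(rbind, lapply(calls_list, function(x) {
    k <- x$calls[x$calls$status == "ALT", c("contig", "pos", "ref", "alt")]
    if (nrow(k)) k$genotype <- x$genotype
    k
  }))
  if (is.null(conf) || nrow(conf) == 0L) {
    empty <- data.frame(snp_id = character(), contig = character(),
                        pos = integer(), ref = character(),
                        alt = character(), class = character())
    return(structure(list(snps = empty,
                          status = matrix(character(0), 0, length(genos),
                                          dimnames = list(NULL, genos))),
                     class = "snp_table"))
  }

  recs <- unique(conf[c("contig", "pos", "ref", "alt")])
  recs <- recs[order(recs$contig, recs$pos, recs$alt), ]
  site_key <- paste0(recs$contig, ":", recs$pos)
  if (anyDuplicated(site_key))
    warning(sum(duplicated(site_key)),
            " multi-allelic site(s) split into biallelic records")
  rec_key <- paste0(site_key, ":", recs$alt)
  rownames(recs) <- NULL

  status <- matrix("MISSING", nrow(recs), length(genos),
                   dimnames = list(rec_key, genos))
  for (g in genos) {
    x <- calls_list[[g]]
    covered <- site_key %in% x$covered
    status[covered, g] <- "REF"
    if (nrow(x$calls)) {
      ck <- paste0(x$calls$contig, ":", x$calls$pos)
      # any non-reference evidence at the site
      ev <- match(site_key, ck)
      has_ev <- !is.na(ev)
      same_alt <- has_ev & x$calls$alt[ev] == recs$alt &
        x$calls$status[ev] == "ALT"
      status[has_ev & !same_alt, g] <- "BELOW_THRESHOLD"
      status[same_alt, g] <- "ALT"
    }
  }

  snps <- data.frame(
    snp_id = sprintf("%s_p%d_%s", recs$contig, recs$pos, recs$alt),
    contig = recs$contig, pos = recs$pos, ref = recs$ref, alt = recs$alt,
    class = classify_ts_tv(recs$ref, recs$alt), stringsAsFactors = FALSE)
  structure(list(snps = snps, status = status), class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs on %d contigs, %d genotypes\n",
              nrow(x$snps), length(unique(x$snps$contig)),
              ncol(x$status)))
  invisible(x)
}

#' Classify substitutions as transitions or transversions
#'
#' A&harr;G and C&harr;T are transitions; every other base pair is a
#' transversion.
#'
#' @param ref,alt Single-base character vectors (A/C/G/T).
#' @return Character vector `"transition"`/`"transversion"`.
#' @export
classify_ts_tv <- function(ref, alt) {
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES
  if (!all(ok)) stop_input("ambiguity codes are not classifiable")
  if (any(ref == alt)) stop_input("ref and alt alleles must differ")
  unname(ifelse(TS_PARTNER[ref] == alt, "transition", "transversion"))
}

#' Summarize a SNP table
#'
#' @param snp_table A `snp_table` from [merge_nonredundant()].
#' @return List with `n_snps`, `n_transitions`, `n_transversions`,
#'   `n_polymorphic_contigs`.
#' @export
snp_summary <- function(snp_table) {
  cls <- snp_table$snps$class
  list(n_snps = nrow(snp_table$snps),
       n_transitions = sum(cls == "transition"),
       n_transversions = sum(cls == "transversion"),
       n_polymorphic_contigs = length(unique(snp_table$snps$contig)))
}

#' Mean alternate-allele frequency over a genotype subset
#'
#' Per SNP, frequency = (number of confident ALT genotypes among the
#' subset) / (number of informative genotypes: those with status REF or
#' ALT, the reference genotype counting as an additional REF when
#' `include_reference`). The summary is the unweighted mean over SNPs with
#' at least one informative genotype; excluded SNPs are counted in the
#' `n_excluded` attribute.
#'
#' @param snp_table A `snp_table`.
#' @param subset Genotype names to include (default: all genotypes in the
#'   table).
#' @param include_reference Count the reference genotype as REF in the
#'   denominator (default TRUE).
#' @return Mean frequency (numeric scalar) with attributes `per_snp` and
#'   `n_excluded`.
#' @export
allele_frequency_summary <- function(snp_table, subset = NULL,
                                     include_reference = TRUE) {
  st <- snp_table$status
  subset <- subset %||% colnames(st)
  unknown <- setdiff(subset, colnames(st))
  if (length(unknown))
    stop_input("unknown genotype(s): ", paste(unknown, collapse = ", "))
  if (!length(subset)) stop_input("subset must be non-empty")
  sub <- st[, subset, drop = FALSE]
  n_alt <- rowSums(sub == "ALT")
  n_inf <- rowSums(sub == "ALT" | sub == "REF") + as.integer(include_reference)
  ok <- n_inf > 0
  freq <- ifelse(ok, n_alt / n_inf, NA_real_)
  structure(mean(freq[ok]), per_snp = freq, n_excluded = sum(!ok))
}

#' Find perfect microsatellite (SSR) tracts in contigs
#'
#' Scans for maximal perfect tandem repeats of motif length 1-6 and reports
#' those meeting both a per-motif-length minimum copy number (defaults:
#' mono >= 10, di >= 6, tri >= 5, tetra-hexa >= 4) and a minimum tract
#' length (`min_total_len`, default 12 bp). Motifs are required to be
#' primitive (a dinucleotide run is not also reported as a tetranucleotide)
#' and tracts nested inside an already-reported tract are suppressed.
#'
#' @param contigs Named character vector of sequences.
#' @param min_total_len Minimum tract length in bp.
#' @param min_copies Integer vector of length 6: minimum copy number per
#'   motif length.
#' @return Data frame `contig`, `motif`, `start`, `end`, `copies`.
#' @export
find_ssrs <- function(contigs, min_total_len = 12,
                      min_copies = SSR_MIN_COPIES) {
  stopifnot(length(min_copies) == 6L)
  out <- list()
  for (ct in names(contigs)) {
    s <- contigs[[ct]]
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(ch)
    found <- list()
    for (m in 1:6) {
      if (L < 2L * m) next
      eq <- ch[seq_len(L - m)] == ch[seq_len(L - m) + m]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths >= m)  # tract >= 2 copies
      for (h in hit) {
        tract_start <- starts[h]
        tract_len0 <- r$lengths[h] + m       # full matched stretch
        copies <- tract_len0 %/% m
        tract_len <- copies * m              # whole copies only
        if (copies < min_copies[m] || tract_len < min_total_len) next
        motif <- paste(ch[tract_start:(tract_start + m - 1L)], collapse = "")
        if (!is_primitive_motif(motif)) next
        found[[length(found) + 1L]] <- data.frame(
          contig = ct, motif = motif, start = tract_start,
          end = tract_start + tract_len - 1L, copies = copies,
          stringsAsFactors = FALSE)
      }
    }
    if (length(found)) {
      f <- do.call(rbind, found)
      f <- f[order(nchar(f$motif), f$start), ]
      keep <- rep(TRUE, nrow(f))
      for (i in seq_len(nrow(f))) {
        if (!keep[i]) next
        nested <- f$start >= f$start[i] & f$end <= f$end[i] &
          seq_len(nrow(f)) != i
        keep[nested] <- FALSE
      }
      out[[ct]] <- f[keep, ]
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), motif = character(),
                      start = integer(), end = integer(),
                      copies = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig, res$start), ]
}
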