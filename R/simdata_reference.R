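#' Specification for a synthetic 3'-cDNA reference contig set
#'
#' Describes the contig universe the generator emits: contig count and mean
#' length, the fraction of each contig that is 3'-UTR (3'-anchored cDNA data
#' over-represents untranslated 3' ends), the rate at which contigs carry a
#' planted microsatellite (SSR), the rate at which a contig is emitted twice
#' with slight divergence (a tandem/assembly duplicate), and the number of
#' collinearity-breaking rearrangements planted into the model-genome
#' anchoring of the contigs.
#'
#' @param n_contigs Number of (original) contigs to generate.
#' @param length_mean Mean contig length in bp (>= 200).
#' @param utr3_fraction Fraction of each contig annotated as 3'-UTR.
#' @param ssr_rate Probability a contig carries a planted SSR in its 3'-UTR.
#' @param dup_rate Probability a contig is emitted twice (second copy with
#'   ~0.5% substitution divergence).
#' @param antisense_rate Fraction of contigs stored in antisense orientation
#'   (coding strand is the reverse complement), exercising strand handling.
#' @param n_model_chrom Number of model-genome chromosomes anchors map to.
#' @param n_inversions,n_translocations Number of planted rearrangements in
#'   the model-genome anchor positions (contiguous windows of
#'   `rearrangement_len` contigs).
#' @param rearrangement_len Contigs per planted rearrangement window.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return An object of class `contig_spec`.
#' @export
contig_spec <- function(n_contigs, length_mean = 600, utr3_fraction = 0.3,
                        ssr_rate = 0.05, dup_rate = 0.01, antisense_rate = 0.2,
                        n_model_chrom = 8, n_inversions = 0,
                        n_translocations = 0, rearrangement_len = 6,
                        seed = NULL) {
  check_count(n_contigs, "n_contigs")
  if (!is.numeric(length_mean) || length_mean < 200)
    stop_input("'length_mean' must be >= 200 bp")
  check_fraction(utr3_fraction, "utr3_fraction")
  check_fraction(ssr_rate, "ssr_rate")
  check_fraction(dup_rate, "dup_rate")
  check_fraction(antisense_rate, "antisense_rate")
  check_count(n_model_chrom, "n_model_chrom")
  spec <- list(n_contigs = as.integer(n_contigs), length_mean = length_mean,
               utr3_fraction = utr3_fraction, ssr_rate = ssr_rate,
               dup_rate = dup_rate, antisense_rate = antisense_rate,
               n_model_chrom = as.integer(n_model_chrom),
               n_inversions = as.integer(n_inversions),
               n_translocations = as.integer(n_translocations),
               rearrangement_len = as.integer(rearrangement_len), seed = seed)
  structure(spec, class = "contig_spec")
}

# sense (non-stop) codons and stop codons from the standard genetic code
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

# minimum copy number per motif length for an SSR to count (mono..hexa)
SSR_MIN_COPIES <- c(10L, 6L, 5L, 4L, 4L, 4L)

# a motif is primitive if it is not a whole-number repetition of a shorter one
is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (strrep(unit, m %/% d) == motif) return(FALSE)
  }
  TRUE
}

random_primitive_motif <- function(m) {
  repeat {
    motif <- paste(sample(DNA_BASES, m, replace = TRUE), collapse = "")
    if (is_primitive_motif(motif)) return(motif)
  }
}

# flip a [start,end] interval to the opposite strand of a length-L sequence
flip_interval <- function(start, end, L) c(L - end + 1L, L - start + 1L)

#' Generate a synthetic reference contig set with full ground truth
#'
#' Emits 3'-cDNA-style contigs, each a coding region (sense codons closed by
#' a stop) followed by a 3'-UTR, with optional planted SSRs, antisense
#' orientation, near-identical duplicates, exon-junction annotation, and a
#' collinear model-genome anchor per contig into which a configurable number
#' of inversions and translocations are planted.
#'
#' @param spec A [contig_spec()].
#' @return A `reference_set` list with elements:
#'   \describe{
#'   \item{contigs}{named character vector of contig sequences (as stored).}
#'   \item{contig_table}{per-contig truth: length, strand, CDS/UTR intervals
#'     (stored coordinates), duplicate parent, SSR flag.}
#'   \item{anchors}{`gene_anchor_set` of truth anchors (see
#'     [anchor_contigs()]), including model-genome chromosome/position.}
#'   \item{ssr_truth}{planted SSR table (contig, motif, start, end, copies).}
#'   \item{duplicate_pairs}{data frame of (contig, duplicate) ids.}
#'   \item{rearrangements}{data frame naming contigs inside planted
#'     inversion/translocation windows.}
#'   \item{gene_db}{named character vector of model-gene mRNA (sense)
#'     sequences used by the built-in anchorer.}
#'   }
#' @export
generate_reference <- function(spec) {
  if (!inherits(spec, "contig_spec")) stop_input("'spec' must be a contig_spec")
  with_seed(spec$seed, {
    n <- spec$n_contigs
    ids <- sprintf("ctg%04d", seq_len(n))
    lens <- pmax(210L, as.integer(round(
      stats::rgamma(n, shape = 6, scale = spec$length_mean / 6))))
    sense <- sense_codons()
    stops <- stop_codons()

    contigs <- character(n)
    strand <- character(n)
    rows <- vector("list", n)
    ssr_rows <- list()
    anchors <- vector("list", n)

    for (i in seq_len(n)) {
      len <- lens[i]
      utr_len <- as.integer(round(len * spec$utr3_fraction))
      cds_len <- len - utr_len
      cds_len <- cds_len - cds_len %% 3L
      if (cds_len < 60L) { cds_len <- 60L; utr_len <- len - 60L }
      utr_len <- len - cds_len

      n_codon <- cds_len %/% 3L
      cds_seq <- paste0(
        paste(sample(sense, n_codon - 1L, replace = TRUE), collapse = ""),
        sample(stops, 1L))
      utr_seq <- paste(sample(DNA_BASES, utr_len, replace = TRUE),
                       collapse = "")

      ssr <- NULL
      if (stats::runif(1) < spec$ssr_rate && utr_len >= 30L) {
        m <- sample(1:6, 1L, prob = c(.10, .35, .30, .10, .10, .05))
        copies <- SSR_MIN_COPIES[m] + sample(0:3, 1L)
        tract_len <- m * copies
        if (tract_len < 12L) copies <- ceiling(12 / m)
        tract_len <- m * copies
        if (tract_len + 2L <= utr_len) {
          motif <- random_primitive_motif(m)
          off <- sample.int(utr_len - tract_len - 1L, 1L) + 1L  # >= 2
          tract <- strrep(motif, copies)
          # guard bases so the planted tract is maximal
          lg <- sample(setdiff(DNA_BASES, substr(motif, m, m)), 1L)
          rg <- sample(setdiff(DNA_BASES, substr(motif, 1L, 1L)), 1L)
          substr(utr_seq, off - 1L, off - 1L) <- lg
          substr(utr_seq, off, off + tract_len - 1L) <- tract
          substr(utr_seq, off + tract_len, off + tract_len) <- rg
          ssr <- list(motif = motif, start = cds_len + off,
                      end = cds_len + off + tract_len - 1L, copies = copies)
        }
      }

      mrna <- paste0(cds_seq, utr_seq)
      # exon junctions (annotation only; cDNA is contiguous): 0-2 per contig
      n_jx <- sample(0:2, 1L, prob = c(.5, .35, .15))
      jx <- if (n_jx > 0 && cds_len > 80L)
        sort(sample(seq(30L, cds_len - 30L), n_jx)) else integer(0)

      st <- if (stats::runif(1) < spec$antisense_rate) "-" else "+"
      stored <- if (st == "+") mrna else revcomp(mrna)
      cds_iv <- c(1L, cds_len); utr_iv <- c(cds_len + 1L, len)
      jx_stored <- jx
      if (st == "-") {
        cds_iv <- flip_interval(cds_iv[1], cds_iv[2], len)
        utr_iv <- flip_interval(utr_iv[1], utr_iv[2], len)
        jx_stored <- sort(len - jx + 1L)
        if (!is.null(ssr)) {
          se <- flip_interval(ssr$start, ssr$end, len)
          ssr$start <- se[1]; ssr$end <- se[2]
          ssr$motif <- substr(stored, se[1], se[1] + nchar(ssr$motif) - 1L)
        }
      }

      contigs[i] <- stored
      strand[i] <- st
      rows[[i]] <- data.frame(
        contig = ids[i], length = len, strand = st,
        cds_start = cds_iv[1], cds_end = cds_iv[2],
        utr3_start = utr_iv[1], utr3_end = utr_iv[2],
        has_ssr = !is.null(ssr), duplicate_of = NA_character_,
        stringsAsFactors = FALSE)
      if (!is.null(ssr))
        ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
          contig = ids[i], motif = ssr$motif, start = ssr$start,
          end = ssr$end, copies = ssr$copies, stringsAsFactors = FALSE)
      anchors[[i]] <- list(contig = ids[i], gene_id = paste0("g_", ids[i]),
                           strand = st, junctions = jx_stored)
    }
    names(contigs) <- ids
    contig_table <- do.call(rbind, rows)

    # model-genome anchor coordinates: collinear blocks with planted
    # rearrangement windows
    chrom_of <- cut(seq_len(n), breaks = spec$n_model_chrom, labels = FALSE)
    model_chrom <- sprintf("chr%d", chrom_of)
    model_pos <- integer(n)
    for (k in seq_len(spec$n_model_chrom)) {
      idx <- which(chrom_of == k)
      model_pos[idx] <- seq_along(idx) * 50000L
    }
    rearr <- list()
    win <- spec$rearrangement_len
    taken <- rep(FALSE, n)
    pick_window <- function() {
      for (try in 1:50) {
        s <- sample.int(n - win + 1L, 1L)
        idx <- s:(s + win - 1L)
        if (length(unique(chrom_of[idx])) == 1L && !any(taken[idx]))
          return(idx)
      }
      NULL
    }
    for (e in seq_len(spec$n_inversions)) {
      idx <- pick_window()
      if (is.null(idx)) break
      taken[idx] <- TRUE
      model_pos[idx] <- rev(model_pos[idx])
      rearr[[length(rearr) + 1L]] <- data.frame(
        contig = ids[idx], event = "inversion", event_id = paste0("inv", e),
        stringsAsFactors = FALSE)
    }
    for (e in seq_len(spec$n_translocations)) {
      idx <- pick_window()
      if (is.null(idx)) break
      taken[idx] <- TRUE
      src <- chrom_of[idx[1]]
      dst <- sample(setdiff(seq_len(spec$n_model_chrom), src), 1L)
      model_chrom[idx] <- sprintf("chr%d", dst)
      base <- max(model_pos[which(chrom_of == dst & !taken)], 0L)
      model_pos[idx] <- base + seq_along(idx) * 50000L
      rearr[[length(rearr) + 1L]] <- data.frame(
        contig = ids[idx], event = "translocation",
        event_id = paste0("tra", e), stringsAsFactors = FALSE)
    }

    identity <- stats::runif(n, 0.90, 0.995)
    align_len <- pmax(100L, as.integer(round(lens * stats::runif(n, 0.8, 1))))

    # duplicates: second copy with ~0.5% substitution divergence
    dup_idx <- which(stats::runif(n) < spec$dup_rate)
    dup_rows <- list(); dup_anchors <- list()
    dup_contigs <- character(0)
    for (i in dup_idx) {
      did <- paste0(ids[i], "d")
      s <- contigs[[i]]
      nmut <- stats::rbinom(1L, nchar(s), 0.005)
      if (nmut > 0) {
        at <- sample.int(nchar(s), nmut)
        for (p in at) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
        }
      }
      dup_contigs[did] <- s
      r <- contig_table[i, ]; r$contig <- did; r$duplicate_of <- ids[i]
      r$has_ssr <- FALSE
      dup_rows[[length(dup_rows) + 1L]] <- r
      dup_anchors[[did]] <- list(contig = did, gene_id = paste0("g_", ids[i]),
                                 strand = strand[i],
                                 junctions = anchors[[i]]$junctions)
    }

    all_contigs <- c(contigs, dup_contigs)
    contig_table <- rbind(contig_table, do.call(rbind, dup_rows))
    rownames(contig_table) <- contig_table$contig

    anc_df <- data.frame(
      contig = ids, gene_id = paste0("g_", ids), strand = strand,
      model_chrom = model_chrom, model_pos = model_pos,
      align_len = align_len, identity = identity, stringsAsFactors = FALSE)
    if (length(dup_idx)) {
      dd <- anc_df[dup_idx, ]
      dd$contig <- paste0(ids[dup_idx], "d")
      dd$model_pos <- dd$model_pos + 2000L
      anc_df <- rbind(anc_df, dd)
    }

    anchor_set <- build_gene_anchor_set(anc_df, contig_table,
                                        c(anchors, dup_anchors))

    # model-gene mRNA (sense) sequences for the built-in anchorer
    gene_db <- contigs
    flip <- strand == "-"
    gene_db[flip] <- revcomp(gene_db[flip])
    names(gene_db) <- paste0("g_", ids)

    structure(list(
      contigs = all_contigs,
      contig_table = contig_table,
      anchors = anchor_set,
      ssr_truth = if (length(ssr_rows)) do.call(rbind, ssr_rows) else
        data.frame(contig = character(), motif = character(),
                   start = integer(), end = integer(), copies = integer()),
      duplicate_pairs = if (length(dup_idx)) data.frame(
        contig = ids[dup_idx], duplicate = paste0(ids[dup_idx], "d"),
        stringsAsFactors = FALSE) else
        data.frame(contig = character(), duplicate = character()),
      rearrangements = if (length(rearr)) do.call(rbind, rearr) else
        data.frame(contig = character(), event = character(),
                   event_id = character()),
      gene_db = gene_db,
      spec = spec), class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "reference_set: %d contigs (%d duplicates), mean length %.0f bp\n",
    length(x$contigs), nrow(x$duplicate_pairs),
    mean(x$contig_table$length)))
  cat(sprintf("  planted SSR contigs: %d; rearrangement windows: %d\n",
              nrow(x$ssr_truth),
              length(unique(x$rearrangements$event_id))))
  invisible(x)
}
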