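# shared fixture builders: everything is generated in code at test time

# a snp_table built directly from a status matrix (genotypes in columns)
make_snp_table <- function(contig, pos, ref, alt, status) {
  snps <- data.frame(
    snp_id = sprintf("%s_p%d_%s", contig, pos, alt),
    contig = contig, pos = pos, ref = ref, alt = alt,
    class = lenspipe::classify_ts_tv(ref, alt), stringsAsFactors = FALSE)
  rownames(status) <- snps$snp_id
  structure(list(snps = snps, status = status), class = "snp_table")
}

# a single-row pileup data frame
pileup_row <- function(contig, pos, counts) {
  data.frame(contig = contig, pos = pos, depth = sum(counts),
             A = counts[1], C = counts[2], G = counts[3], T = counts[4],
             stringsAsFactors = FALSE)
}

# small end-to-end panel: reference + panel + error-free pileups + calls
small_panel_run <- function(n_contigs = 30, seed = 42, depth_mean = 15,
                            error_rate = 0, dup_rate = 0) {
  ref <- lenspipe::generate_reference(
    lenspipe::contig_spec(n_contigs = n_contigs, dup_rate = dup_rate,
                          seed = seed))
  pan <- lenspipe::mutate_panel(ref, lenspipe::panel_spec(seed = seed + 1))
  pu <- lenspipe::simulate_pileups(pan, depth_mean = depth_mean,
                                   error_rate = error_rate, seed = seed + 2)
  calls <- lapply(names(pu), function(g)
    lenspipe::call_snps_per_genotype(pu[[g]], ref$contigs, g))
  tab <- suppressWarnings(lenspipe::merge_nonredundant(calls, ref$contigs))
  list(ref = ref, pan = pan, pileups = pu, calls = calls, tab = tab)
}

# brute-force evaluation of the "<80% or <3 reads" confidence rule,
# written independently of the caller: per site, loop over bases
brute_force_call <- function(pileup, reference, min_reads = 3,
                             min_fraction = 0.8) {
  out <- character(nrow(pileup))
  for (i in seq_len(nrow(pileup))) {
    ref_base <- substr(reference[[pileup$contig[i]]], pileup$pos[i],
                       pileup$pos[i])
    cnt <- c(A = pileup$A[i], C = pileup$C[i], G = pileup$G[i],
             T = pileup$T[i])
    alt_cnt <- cnt[setdiff(names(cnt), ref_base)]
    best <- max(alt_cnt)
    if (pileup$depth[i] == 0) out[i] <- "MISSING"
    else if (best == 0) out[i] <- "REF"
    else if (best < min_reads || best / pileup$depth[i] < min_fraction)
      out[i] <- "BELOW"
    else out[i] <- "ALT"
  }
  out
}

# exhaustive maximum-weight increasing-subset search over all 2^n subsets
.subset_cache <- new.env()
all_subsets <- function(n) {
  key <- as.character(n)
  if (is.null(.subset_cache[[key]])) {
    .subset_cache[[key]] <- lapply(seq_len(2^n - 1), function(mask)
      which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L))
  }
  .subset_cache[[key]]
}
brute_force_lis_weight <- function(pos, w, decreasing = FALSE) {
  if (decreasing) pos <- -pos
  best <- 0
  for (idx in all_subsets(length(pos))) {
    if (length(idx) > 1L && any(diff(pos[idx]) <= 0)) next
    s <- sum(w[idx])
    if (s > best) best <- s
  }
  best
}
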