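.codon_cache <- new.env(parent = emptyenv())

# synonymous/non-synonymous site counts per sense codon (NG86):
# at each codon position, the synonymous fraction of the three possible
# single-base changes; changes creating a stop codon count as
# non-synonymous
ng86_site_counts <- function() {
  if (!is.null(.codon_cache$sites)) return(.codon_cache$sites)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  S <- vapply(sense, function(cd) {
    s <- 0
    for (p in 1:3) {
      cur <- substr(cd, p, p)
      for (b in setdiff(DNA_BASES, cur)) {
        alt <- cd
        substr(alt, p, p) <- b
        if (gc[alt] != "*" && gc[alt] == gc[cd]) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  m <- cbind(S = S, N = 3 - S)
  rownames(m) <- sense
  .codon_cache$sites <- m
  m
}

# single-base sense-codon neighbours, split synonymous / non-synonymous
codon_neighbours <- function() {
  if (!is.null(.codon_cache$nb)) return(.codon_cache$nb)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  nb <- lapply(sense, function(cd) {
    syn <- character(0); non <- character(0)
    for (p in 1:3) {
      cur <- substr(cd, p, p)
      for (b in setdiff(DNA_BASES, cur)) {
        alt <- cd
        substr(alt, p, p) <- b
        if (gc[alt] == "*") next
        if (gc[alt] == gc[cd]) syn <- c(syn, alt) else non <- c(non, alt)
      }
    }
    list(syn = syn, non = non)
  })
  names(nb) <- sense
  .codon_cache$nb <- nb
  nb
}

# average synonymous/non-synonymous difference counts between two codons
# over all mutational pathways; pathways through stop codons are excluded
# unless every pathway is blocked
codon_path_diffs <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  diff_pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(diff_pos) else {
    pm <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { pm[[length(pm) + 1L]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(0), diff_pos)
    pm
  }
  walk <- function(order) {
    cur <- ca; sd <- 0; ndd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[nxt] == "*") blocked <- TRUE
      if (gc[nxt] == gc[cur] && gc[nxt] != "*") sd <- sd + 1
      else ndd <- ndd + 1
      cur <- nxt
    }
    c(sd = sd, nd = ndd, blocked = as.numeric(blocked))
  }
  res <- t(vapply(perms, walk, numeric(3)))
  ok <- res[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(sd = mean(res[ok, "sd"]), nd = mean(res[ok, "nd"]))
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori (1986) synonymous substitution estimate
#'
#' Counts synonymous (S) and non-synonymous (N) sites per codon (averaged
#' over the two sequences), counts synonymous/non-synonymous differences
#' with multi-position codon differences averaged over all mutational
#' pathways (pathways through stop codons excluded when avoidable), and
#' applies the Jukes-Cantor correction
#' `Ks = -(3/4) * ln(1 - (4/3) * pS)` with `pS = Sd / S`.
#'
#' Sequences must be equal-length, gap- and N-free, a multiple of 3 long,
#' and contain no stop codons: only indel-free coding alignments are
#' accepted. When `pS >= 0.75` the Jukes-Cantor correction is saturated;
#' the estimate is returned with `Ks = NA` and `saturated = TRUE` (with a
#' warning), or an error is raised with `on_saturation = "error"`.
#'
#' @param seq_a,seq_b Coding sequences (character strings).
#' @param on_saturation `"na"` (default) or `"error"`.
#' @return An object of class `ks_estimate`: list `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `saturated`.
#' @export
ks_ng86 <- function(seq_a, seq_b, on_saturation = c("na", "error")) {
  on_saturation <- match.arg(on_saturation)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop_input("sequences must be of equal length (indel-free alignment)")
  if (nchar(seq_a) %% 3L != 0L) stop_input("length must be a multiple of 3")
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b))
    stop_input("sequences must contain only A/C/G/T (no gaps or Ns)")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  gc <- Biostrings::GENETIC_CODE
  if (any(gc[ca] == "*") || any(gc[cb] == "*"))
    stop_input("stop codons are not allowed in coding alignments")

  sites <- ng86_site_counts()
  S <- (sum(sites[ca, "S"]) + sum(sites[cb, "S"])) / 2
  N <- (sum(sites[ca, "N"]) + sum(sites[cb, "N"])) / 2
  diffs <- which(ca != cb)
  sd <- 0; nd <- 0
  for (i in diffs) {
    d <- codon_path_diffs(ca[i], cb[i])
    sd <- sd + d["sd"]; nd <- nd + d["nd"]
  }
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  saturated <- pS >= 0.75
  if (saturated && on_saturation == "error")
    stop_input("pS >= 0.75: Jukes-Cantor correction saturated")
  Ks <- if (saturated) {
    warning("pS >= 0.75: Ks saturated, returning NA")
    NA_real_
  } else -0.75 * log(1 - (4 / 3) * pS)
  structure(list(S = unname(S), N = unname(N), Sd = unname(sd),
                 Nd = unname(nd), pS = unname(pS), pN = unname(pN),
                 Ks = unname(Ks), saturated = saturated),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("ks_estimate: S=%.2f N=%.2f Sd=%.2f Nd=%.2f pS=%.4f Ks=%s\n",
              x$S, x$N, x$Sd, x$Nd, x$pS,
              if (is.na(x$Ks)) "saturated" else sprintf("%.4f", x$Ks)))
  invisible(x)
}

#' Ks for a table of sequence pairs
#'
#' @param pairs Data frame with columns `seq_a`, `seq_b`.
#' @param ... Passed to [ks_ng86()].
#' @return Data frame with one row per pair: `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `Ks`, `saturated`.
#' @export
ks_table <- function(pairs, ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    k <- ks_ng86(pairs$seq_a[i], pairs$seq_b[i], ...)
    data.frame(S = k$S, N = k$N, Sd = k$Sd, Nd = k$Nd, pS = k$pS,
               Ks = k$Ks, saturated = k$saturated)
  })
  do.call(rbind, rows)
}

#' Mode of binned Ks values
#'
#' Histograms finite Ks values into fixed-width bins anchored at 0 and
#' returns the midpoint of the most populated bin (ties: the lowest bin).
#'
#' @param ks_values Numeric vector; non-finite values are dropped.
#' @param bin_width Bin width in Ks units (default 0.01).
#' @return List `mode_ks` (bin midpoint), `bin_left`, `bin_width`, `n_bin`
#'   (count in the modal bin), `n` (finite values used).
#' @export
mode_binned <- function(ks_values, bin_width = 0.01) {
  ks <- ks_values[is.finite(ks_values)]
  if (!length(ks)) stop_input("no finite Ks values")
  if (!(bin_width > 0)) stop_input("'bin_width' must be > 0")
  idx <- floor(ks / bin_width)
  tab <- table(idx)
  best <- as.integer(names(tab)[tab == max(tab)])
  b <- min(best)
  list(mode_ks = (b + 0.5) * bin_width, bin_left = b * bin_width,
       bin_width = bin_width, n_bin = as.integer(max(tab)),
       n = length(ks))
}

#' Convert a synonymous divergence to a divergence time
#'
#' Uses the standard identity `Ks = 2 r T`, i.e. `T = Ks / (2 * rate)`,
#' with the synonymous substitution rate in substitutions per synonymous
#' site per Myr (default 5.17e-3, the legume-lineage rate).
#'
#' @param ks_mode Synonymous divergence (e.g. the binned mode), `>= 0`.
#' @param rate Substitutions per synonymous site per Myr, `> 0`.
#' @return Divergence time in Myr.
#' @export
divergence_time <- function(ks_mode, rate = 5.17e-3) {
  if (!is.finite(ks_mode) || ks_mode < 0)
    stop_input("'ks_mode' must be finite and >= 0")
  if (!(rate > 0)) stop_input("'rate' must be > 0")
  ks_mode / (2 * rate)
}

#' Impact-class tallies restricted to a genotype subset
#'
#' Counts annotated impact classes over the SNPs that segregate within the
#' named genotype subset (at least one confident alternate call among the
#' subset). With the full panel as subset this equals the full tallies;
#' subset counts can never exceed them.
#'
#' @param snp_table An annotated `snp_table` (see [annotate_snps()]).
#' @param subset Genotype names; default all.
#' @return Named integer vector of counts per impact class, with attribute
#'   `n_snps` (SNPs segregating in the subset).
#' @export
species_partition <- function(snp_table, subset = NULL) {
  st <- snp_table$status
  subset <- subset %||% colnames(st)
  unknown <- setdiff(subset, colnames(st))
  if (length(unknown))
    stop_input("unknown genotype(s): ", paste(unknown, collapse = ", "))
  seg <- rowSums(st[, subset, drop = FALSE] == "ALT") > 0
  impacts <- snp_table$snps$impact[seg]
  classes <- c("SYNONYMOUS", "NONSYN_SAME_PROP", "NONSYN_DIFF_PROP",
               "STOP_GAIN")
  counts <- vapply(classes, function(cl)
    sum(impacts == cl, na.rm = TRUE), integer(1))
  structure(counts, n_snps = sum(seg))
}
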