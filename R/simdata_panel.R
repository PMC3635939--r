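#' Specification for a genotype panel mutated from the reference
#'
#' The panel mirrors a crop SNP-discovery design: one reference genotype,
#' `n_cultivated` cultivated lines with low divergence from the reference,
#' and `n_wild` wild accessions with higher divergence, most of it on a
#' shared species branch (so wild-specific variants tend to be carried by
#' both wild accessions). Substitutions are transition-biased.
#'
#' @param n_cultivated,n_wild Panel sizes (defaults 8 cultivated + 2 wild).
#' @param theta_cultivated,theta_wild Expected per-site divergence from the
#'   reference for cultivated and wild genotypes (`theta_wild >
#'   theta_cultivated > 0`).
#' @param ts_tv_ratio Ratio of transition to transversion mutation
#'   probability; the expected transition fraction of planted variants is
#'   `ts_tv_ratio / (1 + ts_tv_ratio)`.
#' @param wild_shared Fraction of wild divergence placed on the species
#'   branch shared by all wild accessions (the remainder is private).
#' @param seed Integer seed.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_cultivated = 8, n_wild = 2,
                       theta_cultivated = 0.002, theta_wild = 0.01,
                       ts_tv_ratio = 1.5, wild_shared = 0.7, seed = NULL) {
  check_count(n_cultivated, "n_cultivated", min = 0L)
  check_count(n_wild, "n_wild", min = 0L)
  if (!(theta_wild > theta_cultivated && theta_cultivated >= 0))
    stop_input("need theta_wild > theta_cultivated >= 0")
  if (!(ts_tv_ratio >= 0)) stop_input("'ts_tv_ratio' must be >= 0")
  check_fraction(wild_shared, "wild_shared")
  structure(list(n_cultivated = as.integer(n_cultivated),
                 n_wild = as.integer(n_wild),
                 theta_cultivated = theta_cultivated,
                 theta_wild = theta_wild, ts_tv_ratio = ts_tv_ratio,
                 wild_shared = wild_shared, seed = seed),
            class = "panel_spec")
}

# draw alternate bases under a transition-biased substitution model
draw_alt_bases <- function(ref_bases, ts_tv_ratio) {
  n <- length(ref_bases)
  if (n == 0L) return(character(0))
  p_ts <- ts_tv_ratio / (1 + ts_tv_ratio)
  is_ts <- stats::runif(n) < p_ts
  alt <- character(n)
  alt[is_ts] <- TS_PARTNER[ref_bases[is_ts]]
  if (any(!is_ts)) {
    tv <- which(!is_ts)
    for (i in tv) {
      choices <- setdiff(DNA_BASES, c(ref_bases[i], TS_PARTNER[ref_bases[i]]))
      alt[i] <- choices[sample.int(2L, 1L)]
    }
  }
  alt
}

# sample variant sites across the concatenated contig space
sample_variant_sites <- function(contig_len, theta) {
  total <- sum(contig_len)
  n_var <- stats::rbinom(1L, total, theta)
  if (n_var == 0L)
    return(data.frame(contig = character(), pos = integer()))
  flat <- sort(sample.int(total, n_var))
  ends <- cumsum(contig_len)
  idx <- findInterval(flat - 1L, c(0L, ends), rightmost.closed = FALSE)
  pos <- flat - c(0L, ends)[idx]
  data.frame(contig = names(contig_len)[idx], pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Mutate a reference contig set into a genotype panel
#'
#' Plants substitution variants (no indels) into each panel genotype.
#' Cultivated genotypes draw from a shared pool of standing variation in
#' which each variant is carried by `k` genotypes under the neutral
#' site-frequency spectrum (`P(k)` proportional to `1/k`), scaled so the
#' expected per-genotype divergence from the reference is
#' `theta_cultivated`. Wild genotypes share a species-branch variant set
#' at rate `theta_wild * wild_shared` plus private variants making up the
#' remainder. Alternate bases are transition-biased by `ts_tv_ratio`.
#'
#' @param reference A `reference_set` from [generate_reference()].
#' @param panel A [panel_spec()].
#' @return A `panel` list: `haplotypes` (named list of per-genotype named
#'   sequence vectors), `truth` (data frame genotype/contig/pos/ref/alt),
#'   `genotypes`, `cultivated`, `wild`, and `reference_name` (`"REF"`).
#' @export
mutate_panel <- function(reference, panel) {
  if (!inherits(reference, "reference_set"))
    stop_input("'reference' must be a reference_set")
  if (!inherits(panel, "panel_spec")) stop_input("'panel' must be a panel_spec")
  with_seed(panel$seed, {
    seqs <- reference$contigs
    lens <- nchar(seqs)
    cult <- sprintf("LC%02d", seq_len(panel$n_cultivated))
    wild <- sprintf("LE%02d", seq_len(panel$n_wild))

    truth <- list()
    haplotypes <- list()

    shared <- sample_variant_sites(lens, panel$theta_wild * panel$wild_shared)
    if (nrow(shared)) {
      shared$ref <- base_at(seqs, shared$contig, shared$pos)
      shared$alt <- draw_alt_bases(shared$ref, panel$ts_tv_ratio)
    }

    # cultivated variants are standing variation: a shared pool in which
    # each variant is carried by k of the n cultivated genotypes with the
    # neutral site-frequency spectrum P(k) proportional to 1/k; the pool
    # density is scaled so each genotype's expected divergence from the
    # reference is theta_cultivated
    n_c <- panel$n_cultivated
    carriers <- vector("list", 0L)
    pool <- NULL
    if (n_c > 0 && panel$theta_cultivated > 0) {
      h_n <- sum(1 / seq_len(n_c))
      pool <- sample_variant_sites(lens, min(1, panel$theta_cultivated * h_n))
      if (nrow(pool)) {
        pool$ref <- base_at(seqs, pool$contig, pool$pos)
        pool$alt <- draw_alt_bases(pool$ref, panel$ts_tv_ratio)
        k <- sample(seq_len(n_c), nrow(pool), replace = TRUE,
                    prob = 1 / seq_len(n_c))
        carriers <- lapply(k, function(ki) sample(cult, ki))
      }
    }

    for (g in c(cult, wild)) {
      if (g %in% cult) {
        vars <- if (!is.null(pool) && nrow(pool)) {
          mine <- vapply(carriers, function(cs) g %in% cs, logical(1))
          pool[mine, , drop = FALSE]
        } else data.frame(contig = character(), pos = integer(),
                          ref = character(), alt = character())
      } else {
        priv <- sample_variant_sites(lens,
                                     panel$theta_wild * (1 - panel$wild_shared))
        if (nrow(priv)) {
          priv$ref <- base_at(seqs, priv$contig, priv$pos)
          priv$alt <- draw_alt_bases(priv$ref, panel$ts_tv_ratio)
        }
        vars <- if (nrow(shared)) rbind(shared, priv) else priv
      }
      if (nrow(vars)) {
        # drop double hits at one site within a genotype
        vars <- vars[!duplicated(vars[c("contig", "pos")]), ]
        vars <- vars[order(vars$contig, vars$pos), ]
      }
      haplotypes[[g]] <- apply_substitutions(seqs, vars$contig, vars$pos,
                                             vars$alt)
      if (nrow(vars)) {
        vars$genotype <- g
        truth[[g]] <- vars[c("genotype", "contig", "pos", "ref", "alt")]
      }
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(genotype = character(), contig = character(),
                 pos = integer(), ref = character(), alt = character())
    rownames(truth) <- NULL
    structure(list(haplotypes = haplotypes, truth = truth,
                   genotypes = c(cult, wild), cultivated = cult, wild = wild,
                   reference_name = "REF"),
              class = "panel")
  })
}

#' Simulate per-genotype base-count pileups against the reference
#'
#' Draws a per-site read depth from a Poisson with mean `depth_mean` and
#' distributes reads over A/C/G/T: reads carry the genotype's haplotype base
#' except that each read is independently miscalled to one of the other
#' three bases with probability `error_rate`.
#'
#' @param panel A `panel` from [mutate_panel()] (or a named list of
#'   haplotype sequence vectors).
#' @param depth_mean Mean read depth (the study's genotypes averaged 8-31x).
#' @param error_rate Per-base miscall probability in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return Named list (per genotype) of pileup data frames with columns
#'   `contig`, `pos` (1-based), `depth`, `A`, `C`, `G`, `T`; counts sum to
#'   depth.
#' @export
simulate_pileups <- function(panel, depth_mean, error_rate = 0, seed = NULL) {
  if (!(is.numeric(depth_mean) && depth_mean > 0))
    stop_input("'depth_mean' must be > 0")
  if (!(is.numeric(error_rate) && error_rate >= 0 && error_rate <= 0.1))
    stop_input("'error_rate' must lie in [0, 0.1]")
  haps <- if (inherits(panel, "panel")) panel$haplotypes else panel
  with_seed(seed, lapply(haps, function(seqs) {
    lens <- nchar(seqs)
    contig <- rep(names(seqs), lens)
    pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
    bases <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE),
                    use.names = FALSE)
    nsite <- length(bases)
    depth <- stats::rpois(nsite, depth_mean)
    counts <- matrix(0L, nsite, 4L, dimnames = list(NULL, DNA_BASES))
    bidx <- match(bases, DNA_BASES)
    nerr <- if (error_rate > 0) stats::rbinom(nsite, depth, error_rate)
    else integer(nsite)
    counts[cbind(seq_len(nsite), bidx)] <- depth - nerr
    esites <- which(nerr > 0L)
    for (i in esites) {
      others <- setdiff(1:4, bidx[i])
      counts[i, others] <- counts[i, others] +
        as.integer(stats::rmultinom(1L, nerr[i], rep(1 / 3, 3)))
    }
    data.frame(contig = contig, pos = pos, depth = depth,
               A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
               T = counts[, "T"], stringsAsFactors = FALSE)
  }))
}
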