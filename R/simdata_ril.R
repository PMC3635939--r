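#' Specification for a simulated recombinant inbred line population
#'
#' An F1 between two fully homozygous parents is selfed
#' `selfing_generations` times (7 selfings = F8, matching lines bulked at
#' F8), with crossovers simulated as a Markov chain along each linkage
#' group using adjacent-interval recombination fractions from the inverse
#' Kosambi function and no interference. A handful of individuals can be
#' given elevated missing-data rates to emulate poor DNA samples that are
#' removed by the pre-mapping QC step.
#'
#' @param n_lg Number of linkage groups (chromosomes).
#' @param markers_per_lg Markers per linkage group.
#' @param lg_length_cM Map length of each group, in centimorgans.
#' @param n_ril Number of RILs (default 147, the bulked population size).
#' @param selfing_generations Rounds of selfing after the F1 (default 7,
#'   i.e. F8); residual heterozygosity decays as `0.5^g`.
#' @param missing_rate Per-call missing probability for typical samples.
#' @param n_poor_dna Individuals with elevated missing rate
#'   (`poor_missing_rate`), emulating samples dropped before mapping.
#' @param poor_missing_rate Missing probability for poor-DNA individuals.
#' @param seed Integer seed.
#' @return An object of class `ril_spec`.
#' @export
ril_spec <- function(n_lg = 7, markers_per_lg = 70, lg_length_cM = 120,
                     n_ril = 147, selfing_generations = 7,
                     missing_rate = 0.02, n_poor_dna = 5,
                     poor_missing_rate = 0.35, seed = NULL) {
  check_count(n_lg, "n_lg")
  check_count(markers_per_lg, "markers_per_lg", min = 2L)
  if (!(lg_length_cM > 0)) stop_input("'lg_length_cM' must be > 0")
  check_count(n_ril, "n_ril")
  check_count(selfing_generations, "selfing_generations", min = 0L)
  check_fraction(missing_rate, "missing_rate", open_right = TRUE)
  check_count(n_poor_dna, "n_poor_dna", min = 0L)
  check_fraction(poor_missing_rate, "poor_missing_rate", open_right = TRUE)
  structure(list(n_lg = as.integer(n_lg),
                 markers_per_lg = as.integer(markers_per_lg),
                 lg_length_cM = lg_length_cM, n_ril = as.integer(n_ril),
                 selfing_generations = as.integer(selfing_generations),
                 missing_rate = missing_rate,
                 n_poor_dna = as.integer(n_poor_dna),
                 poor_missing_rate = poor_missing_rate, seed = seed),
            class = "ril_spec")
}

#' Build a true marker map for a RIL specification
#'
#' Markers are spread over each group approximately evenly with random
#' jitter; the first marker sits at 0 cM.
#'
#' @param spec A [ril_spec()].
#' @return Data frame `marker`, `lg`, `cM`, sorted by group and position.
#' @export
make_marker_map <- function(spec) {
  if (!inherits(spec, "ril_spec")) stop_input("'spec' must be a ril_spec")
  with_seed(spec$seed, {
    maps <- lapply(seq_len(spec$n_lg), function(g) {
      m <- spec$markers_per_lg
      base <- seq(0, spec$lg_length_cM, length.out = m)
      jit <- stats::rnorm(m, 0, spec$lg_length_cM / (4 * m))
      cm <- sort(base + jit)
      cm <- cm - cm[1]
      data.frame(marker = sprintf("LG%d_M%03d", g, seq_len(m)),
                 lg = paste0("LG", g), cM = cm, stringsAsFactors = FALSE)
    })
    do.call(rbind, maps)
  })
}

# one meiosis for all individuals at once on one linkage group
# h1, h2: markers x individuals 0/1 haplotype matrices; r: adjacent
# recombination fractions (length m-1). Returns gamete matrix.
meiosis_gametes <- function(h1, h2, r) {
  m <- nrow(h1); n <- ncol(h1)
  pick <- matrix(0L, m, n)
  pick[1, ] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1L) {
    sw <- matrix(stats::rbinom((m - 1L) * n, 1L, rep(r, n)), m - 1L, n)
    pick[-1, ] <- sw
    pick <- apply(pick, 2L, cumsum) %% 2L
  }
  ifelse(pick == 1L, h2, h1)
}

#' Simulate a RIL marker genotype matrix with known truth
#'
#' Parents are opposite homozygotes at every marker (P1 = A, P2 = B). The F1
#' is selfed `selfing_generations` times; each gamete is generated by a
#' no-interference crossover Markov chain with adjacent recombination
#' fractions `kosambi_r(diff(cM))`. Calls are coded `A`/`B`/`H`/`U`
#' (U = missing).
#'
#' @param map Data frame `marker`, `lg`, `cM` (e.g. [make_marker_map()]).
#' @param spec A [ril_spec()].
#' @return A list of class `ril_population`: `calls` (markers x individuals
#'   character matrix including `P1`, `P2` columns), `map`, `poor_dna`
#'   (ids of elevated-missing individuals), `spec`.
#' @export
simulate_ril_population <- function(map, spec) {
  if (!inherits(spec, "ril_spec")) stop_input("'spec' must be a ril_spec")
  need <- c("marker", "lg", "cM")
  if (!all(need %in% names(map)))
    stop_input("'map' needs columns marker, lg, cM")
  if (any(is.na(map$cM))) stop_input("every marker needs a map position")
  with_seed(spec$seed, {
    map <- map[order(map$lg, map$cM), ]
    n <- spec$n_ril
    inds <- sprintf("RIL%03d", seq_len(n))
    geno <- matrix(NA_integer_, nrow(map), n)  # 0,1,2 = #B alleles
    rownames(geno) <- map$marker

    for (g in unique(map$lg)) {
      rows <- which(map$lg == g)
      m <- length(rows)
      r <- kosambi_r(diff(map$cM[rows]))
      # F1: one A haplotype, one B haplotype
      h1 <- matrix(0L, m, n); h2 <- matrix(1L, m, n)
      for (gen in seq_len(spec$selfing_generations)) {
        g1 <- meiosis_gametes(h1, h2, r)
        g2 <- meiosis_gametes(h1, h2, r)
        h1 <- g1; h2 <- g2
      }
      geno[rows, ] <- h1 + h2
    }

    calls <- matrix(c("A", "H", "B")[geno + 1L], nrow(map), n,
                    dimnames = list(map$marker, inds))
    poor <- if (spec$n_poor_dna > 0)
      sample(inds, min(spec$n_poor_dna, n)) else character(0)
    miss_rate <- ifelse(inds %in% poor, spec$poor_missing_rate,
                        spec$missing_rate)
    miss <- matrix(stats::runif(length(calls)) <
                     rep(miss_rate, each = nrow(calls)),
                   nrow(calls), ncol(calls))
    calls[miss] <- "U"
    calls <- cbind(calls, P1 = "A", P2 = "B")

    structure(list(calls = calls, map = map, poor_dna = sort(poor),
                   spec = spec), class = "ril_population")
  })
}

#' Simulate indel-free orthologous CDS pairs at a known divergence time
#'
#' Starting from a random ancestral coding sequence, synonymous
#' substitutions are planted at an expected density of `2 * rate * t_myr`
#' per synonymous site (the standard `Ks = 2rT` identity), and
#' non-synonymous substitutions at `ka_ks` times that density per
#' non-synonymous site. Codons mutate through single-base synonymous /
#' non-synonymous neighbours (never through stops), so the planted Ks is
#' recoverable by Nei-Gojobori counting.
#'
#' @param n_pairs Number of sequence pairs.
#' @param t_myr True divergence time in Myr.
#' @param rate Synonymous substitution rate per site per Myr
#'   (default 5.17e-3, the legume-lineage rate used for dating).
#' @param n_codons Codons per sequence.
#' @param ka_ks Ratio of non-synonymous to synonymous per-site rates.
#' @param seed Integer seed.
#' @return List with `pairs` (data frame `seq_a`, `seq_b`) and `ks_true`
#'   (the planted per-synonymous-site substitution density).
#' @export
simulate_cds_pairs <- function(n_pairs, t_myr, rate = 5.17e-3,
                               n_codons = 200, ka_ks = 0.1, seed = NULL) {
  check_count(n_pairs, "n_pairs")
  if (!(t_myr >= 0)) stop_input("'t_myr' must be >= 0")
  ks_true <- 2 * rate * t_myr
  nb <- codon_neighbours()
  sense <- sense_codons()
  s_sites <- ng86_site_counts()[sense, "S"]
  with_seed(seed, {
    seq_a <- seq_b <- character(n_pairs)
    for (p in seq_len(n_pairs)) {
      anc <- sample(sense, n_codons, replace = TRUE)
      der <- anc
      n_syn <- stats::rpois(n_codons, ks_true * s_sites[anc])
      n_non <- stats::rpois(n_codons, ka_ks * ks_true * (3 - s_sites[anc]))
      for (i in which(n_syn + n_non > 0L)) {
        moves <- c(rep("syn", n_syn[i]), rep("non", n_non[i]))
        moves <- sample(moves)
        cd <- der[i]
        for (mv in moves) {
          opts <- nb[[cd]][[mv]]
          if (length(opts) == 0L) next
          cd <- opts[sample.int(length(opts), 1L)]
        }
        der[i] <- cd
      }
      seq_a[p] <- paste(anc, collapse = "")
      seq_b[p] <- paste(der, collapse = "")
    }
    list(pairs = data.frame(seq_a = seq_a, seq_b = seq_b,
                            stringsAsFactors = FALSE),
         ks_true = ks_true)
  })
}

#' Simulate linkage-group-to-model-genome synteny anchors
#'
#' Generates, per linkage group, anchors whose model-genome positions are
#' collinear with the cM positions, then plants a configurable number of
#' inversions (a window's model positions reversed) and translocations (a
#' window moved to another model chromosome).
#'
#' @param n_lg Number of linkage groups.
#' @param anchors_per_lg Anchors per group.
#' @param lg_length_cM Group length in cM.
#' @param n_inversions,n_translocations Planted rearrangement counts.
#' @param event_len Anchors per planted rearrangement window (default 6).
#' @param seed Integer seed.
#' @return List with `anchors` (data frame `marker`, `lg`, `cM`,
#'   `model_chrom`, `model_pos`, `align_len`, `identity`) and `truth`
#'   (marker/event/event_id for planted windows).
#' @export
simulate_synteny_anchors <- function(n_lg = 7, anchors_per_lg = 30,
                                     lg_length_cM = 120, n_inversions = 0,
                                     n_translocations = 0, event_len = 6,
                                     seed = NULL) {
  check_count(n_lg, "n_lg")
  check_count(anchors_per_lg, "anchors_per_lg", min = 2L)
  with_seed(seed, {
    res <- list(); truth <- list()
    ev_inv <- 0L; ev_tra <- 0L
    for (g in seq_len(n_lg)) {
      m <- anchors_per_lg
      cm <- sort(stats::runif(m, 0, lg_length_cM))
      pos <- cumsum(stats::rpois(m, 4) + 1L) * 100000L
      df <- data.frame(
        marker = sprintf("LG%d_A%03d", g, seq_len(m)),
        lg = paste0("LG", g), cM = cm,
        model_chrom = paste0("chr", g),
        model_pos = pos,
        align_len = sample(150:600, m, replace = TRUE),
        identity = round(stats::runif(m, 0.85, 0.99), 3),
        stringsAsFactors = FALSE)
      res[[g]] <- df
    }
    anchors <- do.call(rbind, res)
    used <- character(0)
    pick_window <- function() {
      for (try in 1:100) {
        g <- sample(n_lg, 1L)
        rows <- which(anchors$lg == paste0("LG", g))
        if (length(rows) < event_len + 4L) next
        s <- sample(3:(length(rows) - event_len - 1L), 1L)
        w <- rows[s:(s + event_len - 1L)]
        if (!any(anchors$marker[w] %in% used)) return(w)
      }
      NULL
    }
    for (e in seq_len(n_inversions)) {
      w <- pick_window()
      if (is.null(w)) break
      ev_inv <- ev_inv + 1L
      anchors$model_pos[w] <- rev(anchors$model_pos[w])
      used <- c(used, anchors$marker[w])
      truth[[length(truth) + 1L]] <- data.frame(
        marker = anchors$marker[w], event = "inversion",
        event_id = paste0("inv", ev_inv), stringsAsFactors = FALSE)
    }
    for (e in seq_len(n_translocations)) {
      w <- pick_window()
      if (is.null(w)) break
      ev_tra <- ev_tra + 1L
      src <- anchors$model_chrom[w[1]]
      dst <- sample(setdiff(paste0("chr", seq_len(n_lg)), src), 1L)
      anchors$model_chrom[w] <- dst
      base <- max(anchors$model_pos[anchors$model_chrom == dst]) + 100000L
      anchors$model_pos[w] <- base + seq_along(w) * 100000L
      used <- c(used, anchors$marker[w])
      truth[[length(truth) + 1L]] <- data.frame(
        marker = anchors$marker[w], event = "translocation",
        event_id = paste0("tra", ev_tra), stringsAsFactors = FALSE)
    }
    list(anchors = anchors,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(marker = character(), event = character(),
                      event_id = character()))
  })
}
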