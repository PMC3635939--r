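#' Consensus haplotype call per contig
#'
#' Collapses the rows of a marker genotype matrix that belong to the same
#' contig into one consensus row per contig: for each individual, if all
#' non-missing calls agree that call is used (so missing data is filled in
#' from other SNPs in the contig); any disagreement, or all-missing, gives
#' `U`.
#'
#' @param calls Character matrix (markers x individuals) with calls in
#'   `A`/`B`/`H`/`U`.
#' @param marker_contig Named character vector mapping marker -> contig id.
#' @return Character matrix with one row per contig.
#' @export
consensus_haplotype <- function(calls, marker_contig) {
  miss <- setdiff(rownames(calls), names(marker_contig))
  if (length(miss))
    stop_input("markers without a contig assignment: ",
               paste(utils::head(miss, 5), collapse = ", "))
  contigs <- marker_contig[rownames(calls)]
  groups <- split(seq_len(nrow(calls)), contigs)
  out <- t(vapply(groups, function(rows) {
    block <- calls[rows, , drop = FALSE]
    apply(block, 2L, function(col) {
      obs <- unique(col[col != "U"])
      if (length(obs) == 1L) obs else "U"
    })
  }, character(ncol(calls))))
  colnames(out) <- colnames(calls)
  out
}

#' Recode dominant (present/null) markers to codominant calls
#'
#' For assays where one allele gives no signal, the null allele is
#' assigned to whichever parent is null and the present allele to the
#' other. Markers whose parents are indistinguishable are dropped (and
#' listed in the `dropped` attribute).
#'
#' @param calls Character matrix (markers x individuals, including parent
#'   columns) with calls in `PRESENT`/`NULL`/`U`.
#' @param p1,p2 Parent column names (default `"P1"`, `"P2"`; P1 carries
#'   the `A` allele).
#' @return Character matrix of `A`/`B`/`U` calls (parents recoded too),
#'   with attribute `dropped`.
#' @export
recode_dominant <- function(calls, p1 = "P1", p2 = "P2") {
  if (!all(c(p1, p2) %in% colnames(calls)))
    stop_input("parent columns not found")
  ok <- calls[, p1] != calls[, p2] &
    calls[, p1] != "U" & calls[, p2] != "U"
  dropped <- rownames(calls)[!ok]
  kept <- calls[ok, , drop = FALSE]
  out <- kept
  for (i in seq_len(nrow(kept))) {
    null_parent_is_p1 <- kept[i, p1] == "NULL"
    # allele of the null-carrying parent
    null_allele <- if (null_parent_is_p1) "A" else "B"
    pres_allele <- if (null_parent_is_p1) "B" else "A"
    out[i, ] <- ifelse(kept[i, ] == "NULL", null_allele,
                       ifelse(kept[i, ] == "PRESENT", pres_allele, "U"))
  }
  structure(out, dropped = dropped)
}

#' Remove individuals with excessive missing data
#'
#' @param calls Character matrix (markers x individuals).
#' @param max_missing Maximum tolerated missing-call fraction in `(0, 1]`;
#'   individuals above it are removed.
#' @param parents Columns exempt from QC (default `c("P1","P2")` when
#'   present).
#' @return Filtered matrix with attribute `removed` (data frame
#'   `individual`, `missing_fraction`).
#' @export
qc_individuals <- function(calls, max_missing,
                           parents = intersect(c("P1", "P2"),
                                               colnames(calls))) {
  if (!(max_missing > 0 && max_missing <= 1))
    stop_input("'max_missing' must lie in (0, 1]")
  frac <- colMeans(calls == "U")
  drop <- frac > max_missing & !(colnames(calls) %in% parents)
  if (all(drop)) stop_input("all individuals removed by QC")
  removed <- data.frame(individual = colnames(calls)[drop],
                        missing_fraction = unname(frac[drop]),
                        stringsAsFactors = FALSE)
  structure(calls[, !drop, drop = FALSE], removed = removed)
}

#' Pairwise recombination estimates and LOD scores
#'
#' For each marker pair, individuals with an `A` or `B` call at both
#' markers are informative (`H` and `U` are excluded); `R = k/n` is the
#' observed recombinant fraction, corrected to a per-meiosis recombination
#' fraction for selfing-derived RILs by `r = R / (2(1 - R))` (capped at
#' 0.5, from the Haldane-Waddington identity `R = 2r/(1+2r)`), and
#' `LOD = k log10(R/0.5) + (n-k) log10((1-R)/0.5)`.
#'
#' @param calls Character matrix (markers x individuals; parent columns are
#'   ignored if named `P1`/`P2`).
#' @return List of class `pair_linkage`: matrices `n`, `k`, `R`, `r`,
#'   `lod` (markers x markers, symmetric).
#' @export
pairwise_linkage <- function(calls) {
  if (!is.null(colnames(calls)))
    calls <- calls[, !colnames(calls) %in% c("P1", "P2"), drop = FALSE]
  m <- nrow(calls)
  A <- (calls == "A") * 1
  B <- (calls == "B") * 1
  n <- (A + B) %*% t(A + B)
  k <- A %*% t(B) + B %*% t(A)
  R <- ifelse(n > 0, k / n, NA_real_)
  r <- ifelse(is.na(R), NA_real_, pmin(R / (2 * (1 - R)), 0.5))
  r[is.nan(r)] <- 0.5  # R = 1
  t1 <- ifelse(k > 0, k * log10(R / 0.5), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log10((1 - R) / 0.5), 0)
  lod <- ifelse(n > 0, t1 + t2, NA_real_)
  dimnames(n) <- dimnames(k) <- dimnames(R) <- dimnames(r) <-
    dimnames(lod) <- list(rownames(calls), rownames(calls))
  structure(list(n = n, k = k, R = R, r = r, lod = lod),
            class = "pair_linkage")
}

#' Group markers into linkage groups at a LOD threshold
#'
#' Linkage groups are the connected components of the marker graph with an
#' edge wherever the pairwise LOD is at or above the threshold. Raising
#' the threshold can only refine (never merge) the grouping.
#'
#' @param pairs A `pair_linkage` from [pairwise_linkage()].
#' @param lod_threshold Grouping threshold (default 6).
#' @return Named list of character vectors (marker ids), largest first.
#' @export
group_markers <- function(pairs, lod_threshold = 6) {
  lod <- pairs$lod
  markers <- rownames(lod)
  adj <- !is.na(lod) & lod >= lod_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(markers, comp$membership)
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  names(groups) <- paste0("LG", seq_along(groups))
  groups
}

# greedy nearest-neighbour path + 2-opt on the sum of adjacent distances
order_path <- function(D) {
  m <- nrow(D)
  if (m <= 2L) return(seq_len(m))
  start <- which.max(rowSums(D, na.rm = TRUE))  # likely a terminus
  path <- start
  left <- setdiff(seq_len(m), start)
  while (length(left)) {
    nxt <- left[which.min(D[path[length(path)], left])]
    path <- c(path, nxt)
    left <- setdiff(left, nxt)
  }
  # 2-opt: reversing path[i..j] changes only the two boundary edges
  improved <- TRUE; guard <- 0L
  while (improved && guard < 100L) {
    improved <- FALSE; guard <- guard + 1L
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      delta <- 0
      if (i > 1L) delta <- delta + D[path[i - 1L], path[j]] -
          D[path[i - 1L], path[i]]
      if (j < m) delta <- delta + D[path[i], path[j + 1L]] -
          D[path[j], path[j + 1L]]
      if (delta < -1e-12) {
        path[i:j] <- rev(path[i:j])
        improved <- TRUE
      }
    }
  }
  path
}

#' Order one linkage group and assign Kosambi cM positions
#'
#' Marker order comes from a greedy nearest-neighbour walk through the
#' RIL-corrected recombination-fraction matrix refined by 2-opt
#' (minimising the sum of adjacent `r`); this is a documented heuristic
#' stand-in for full ML/regression map ordering, validated by simulation
#' recovery. Adjacent distances are `kosambi_cM(r)` and positions
#' accumulate from 0. Orientation is canonicalised so the first marker id
#' sorts before the last (map length is invariant under reversal).
#'
#' @param group Character vector of marker ids (one linkage group).
#' @param pairs A `pair_linkage`.
#' @return Data frame `marker`, `cM` in map order.
#' @export
order_and_space <- function(group, pairs) {
  if (length(group) < 2L)
    return(data.frame(marker = group, cM = 0, stringsAsFactors = FALSE))
  r <- pairs$r[group, group]
  if (any(is.na(r)))
    stop_input("missing pairwise estimates within a linkage group")
  path <- order_path(r)
  ord <- group[path]
  if (ord[1] > ord[length(ord)]) ord <- rev(ord)
  radj <- pairs$r[cbind(ord[-length(ord)], ord[-1])]
  radj <- pmin(radj, 0.5 - 1e-9)
  d <- kosambi_cM(radj)
  data.frame(marker = ord, cM = cumsum(c(0, d)), stringsAsFactors = FALSE)
}

#' Build a full linkage map from a genotype matrix
#'
#' Convenience wrapper: pairwise linkage, LOD grouping, then per-group
#' ordering and Kosambi spacing.
#'
#' @param calls Character matrix (markers x individuals).
#' @param lod_threshold Grouping LOD (default 6).
#' @param min_group_size Groups smaller than this are reported unplaced
#'   (default 2).
#' @return List of class `linkage_map`: `map` (data frame `group`,
#'   `marker`, `cM`), `groups`, `pairs`, `unplaced`.
#' @export
build_linkage_map <- function(calls, lod_threshold = 6, min_group_size = 2) {
  pairs <- pairwise_linkage(calls)
  groups <- group_markers(pairs, lod_threshold)
  big <- groups[vapply(groups, length, integer(1)) >= min_group_size]
  unplaced <- unlist(groups[vapply(groups, length, integer(1)) <
                              min_group_size], use.names = FALSE)
  maps <- lapply(names(big), function(g) {
    df <- order_and_space(big[[g]], pairs)
    cbind(group = g, df, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  structure(list(map = map, groups = big, pairs = pairs,
                 unplaced = unplaced %||% character(0)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  lens <- tapply(x$map$cM, x$map$group, max)
  cat(sprintf("linkage_map: %d groups, %d markers, total length %.1f cM\n",
              length(x$groups), nrow(x$map), sum(lens)))
  invisible(x)
}
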