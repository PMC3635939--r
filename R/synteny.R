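#' Weighted longest increasing subset of synteny anchors
#'
#' Dynamic-programming maximum-total-weight subset of anchors (weight =
#' aligned length x identity) whose model-genome positions are strictly
#' increasing (`orientation = "forward"`) or strictly decreasing
#' (`"inverted"`) when the anchors are walked in cM order. Deterministic:
#' among equal-weight solutions the earliest-cM chain is returned.
#'
#' @param anchors Data frame with columns `cM`, `model_pos`, `align_len`,
#'   `identity` (one linkage group x model chromosome pair), sorted by cM
#'   (re-sorted if not).
#' @param orientation `"forward"` or `"inverted"`.
#' @return The retained rows of `anchors` (possibly empty), with attribute
#'   `weight` (total retained weight).
#' @export
weighted_lis <- function(anchors, orientation = c("forward", "inverted")) {
  orientation <- match.arg(orientation)
  if (nrow(anchors) == 0L)
    return(structure(anchors, weight = 0))
  ord <- order(anchors$cM)
  anchors <- anchors[ord, , drop = FALSE]
  pos <- anchors$model_pos
  if (orientation == "inverted") pos <- -pos
  w <- anchors$align_len * anchors$identity
  n <- length(pos)
  best <- w
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    cands <- which(pos[seq_len(i - 1L)] < pos[i])
    if (length(cands)) {
      b <- best[cands]
      j <- cands[which.max(b)]  # which.max: earliest index on ties
      best[i] <- w[i] + best[j]
      prev[i] <- j
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  while (!is.na(end)) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  structure(anchors[chain, , drop = FALSE], weight = max(best))
}

# segment a cM-sorted anchor set into maximal constant-direction runs of
# model_pos; an anchor at a direction change belongs to both flanking runs
direction_runs <- function(df) {
  n <- nrow(df)
  if (n < 2L) return(list(list(rows = seq_len(n), dir = 1L)))
  step <- sign(diff(df$model_pos))
  step[step == 0L] <- NA_integer_  # ties continue the current direction
  for (i in seq_along(step)) if (is.na(step[i]))
    step[i] <- if (i > 1L) step[i - 1L] else 1L
  runs <- list()
  start <- 1L
  for (i in seq_along(step)) {
    if (i == length(step) || step[i + 1L] != step[i]) {
      runs[[length(runs) + 1L]] <- list(rows = start:(i + 1L),
                                        dir = step[i])
      start <- i + 1L
    }
  }
  runs
}

#' Chain anchors into synteny blocks and flag rearrangements
#'
#' Per linkage group x model chromosome pair, anchors are filtered by
#' [weighted_lis()] in the heavier orientation; leftovers are re-chained in
#' the opposite orientation; the union, walked in cM order, is segmented
#' into maximal same-orientation runs, and runs of at least `min_block`
#' anchors become blocks. A block whose orientation is the minority (by
#' anchor weight) within its linkage group is flagged as an inversion; a
#' linkage group with `min_block`-or-more anchors in blocks on two or more
#' model chromosomes is flagged as a translocation.
#'
#' @param anchors Data frame with columns `marker`, `lg`, `cM`,
#'   `model_chrom`, `model_pos`, `align_len`, `identity`.
#' @param min_block Minimum anchors per block (default 3).
#' @return List of class `synteny_blocks`: `blocks` (data frame `block_id`,
#'   `lg`, `model_chrom`, `orientation`, `n_anchors`, `cM_start`, `cM_end`,
#'   `pos_start`, `pos_end`, `inversion`), `translocations` (data frame
#'   `lg`, `chroms`), `dotplot` (anchor table with `block_id` and
#'   `orientation` for plotting).
#' @export
call_blocks <- function(anchors, min_block = 3) {
  need <- c("marker", "lg", "cM", "model_chrom", "model_pos",
            "align_len", "identity")
  if (!all(need %in% names(anchors)))
    stop_input("anchors need columns: ", paste(need, collapse = ", "))
  blocks <- list()
  dot <- list()
  bid <- 0L
  for (g in unique(anchors$lg)) {
    ag <- anchors[anchors$lg == g, , drop = FALSE]
    for (ch in unique(ag$model_chrom)) {
      ac <- ag[ag$model_chrom == ch, , drop = FALSE]
      ac <- ac[order(ac$cM), , drop = FALSE]
      fwd <- weighted_lis(ac, "forward")
      inv <- weighted_lis(ac, "inverted")
      main <- if (attr(fwd, "weight") >= attr(inv, "weight")) fwd else inv
      rest <- ac[!ac$marker %in% main$marker, , drop = FALSE]
      other <- if (nrow(rest) >= 2L) {
        of <- weighted_lis(rest, "forward")
        oi <- weighted_lis(rest, "inverted")
        if (attr(of, "weight") >= attr(oi, "weight")) of else oi
      } else rest
      used <- rbind(main, other)
      used <- used[order(used$cM), , drop = FALSE]
      if (nrow(used) == 0L) next
      for (run in direction_runs(used)) {
        if (length(run$rows) < min_block) next
        bid <- bid + 1L
        seg <- used[run$rows, , drop = FALSE]
        seg$block_id <- paste0("blk", bid)
        seg$orientation <- if (run$dir >= 0L) "forward" else "inverted"
        dot[[length(dot) + 1L]] <- seg
        blocks[[length(blocks) + 1L]] <- data.frame(
          block_id = paste0("blk", bid), lg = g, model_chrom = ch,
          orientation = seg$orientation[1], n_anchors = nrow(seg),
          cM_start = min(seg$cM), cM_end = max(seg$cM),
          pos_start = seg$model_pos[1],
          pos_end = seg$model_pos[nrow(seg)],
          weight = sum(seg$align_len * seg$identity),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(blocks))
    return(structure(list(blocks = data.frame(), translocations =
                            data.frame(lg = character(),
                                       chroms = character()),
                          dotplot = data.frame()),
                     class = "synteny_blocks"))
  bdf <- do.call(rbind, blocks)

  # inversions: minority orientation by weight within a linkage group
  bdf$inversion <- FALSE
  for (g in unique(bdf$lg)) {
    rows <- which(bdf$lg == g)
    if (length(unique(bdf$orientation[rows])) < 2L) next
    wgt <- tapply(bdf$weight[rows], bdf$orientation[rows], sum)
    minority <- names(wgt)[which.min(wgt)]
    bdf$inversion[rows][bdf$orientation[rows] == minority] <- TRUE
  }

  # translocations: a linkage group with blocks on >= 2 model chromosomes
  tr <- list()
  for (g in unique(bdf$lg)) {
    rows <- which(bdf$lg == g)
    per_chrom <- tapply(bdf$n_anchors[rows], bdf$model_chrom[rows], sum)
    hit <- names(per_chrom)[per_chrom >= min_block]
    if (length(hit) >= 2L)
      tr[[length(tr) + 1L]] <- data.frame(
        lg = g, chroms = paste(sort(hit), collapse = ","),
        stringsAsFactors = FALSE)
  }
  structure(list(blocks = bdf,
                 translocations = if (length(tr)) do.call(rbind, tr) else
                   data.frame(lg = character(), chroms = character()),
                 dotplot = do.call(rbind, dot)),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf(
    "synteny_blocks: %d blocks (%d inverted), %d translocated group(s)\n",
    nrow(x$blocks), sum(x$blocks$inversion), nrow(x$translocations)))
  invisible(x)
}
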