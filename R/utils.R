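#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T)
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a locally-set RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators are reproducible
#' without clobbering the caller's RNG stream. A `NULL` seed runs the code
#' on the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# vectorised single-base lookup: base of seqs[[contig]] at pos
base_at <- function(seqs, contig, pos) {
  substring(seqs[contig], pos, pos)
}

# replace single bases at (contig, pos) with alt in a named character vector
apply_substitutions <- function(seqs, contig, pos, alt) {
  if (length(pos) == 0L) return(seqs)
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    s <- seqs[[ct]]
    for (i in idx) substr(s, pos[i], pos[i]) <- alt[i]
    seqs[[ct]] <- s
  }
  seqs
}

stop_input <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop_input(sprintf("'%s' must be a fraction in [0,%s]", name,
                              if (open_right) "1)" else "1"))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && x >= min && x == floor(x)
  if (!ok) stop_input(sprintf("'%s' must be an integer >= %d", name, min))
  invisible(as.integer(x))
}
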