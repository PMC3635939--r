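test_that("reference filter applies the length and repeat rules", {
  ctgs <- c(a = strrep("A", 199), b = strrep("C", 200),
            c = strrep("G", 500), d = strrep("T", 300))
  kept <- filter_reference(ctgs, repeat_class = "d")
  expect_identical(sort(names(kept)), c("b", "c"))  # 199 bp out, 200 bp in
  removed <- attr(kept, "removed")
  expect_setequal(removed$reason[removed$contig == "a"], "too_short")
  expect_setequal(removed$reason[removed$contig == "d"], "repeat_class")
  # 10 contigs, 3 flagged repeat -> 7 retained
  many <- setNames(rep(strrep("A", 250), 10), paste0("c", 1:10))
  expect_length(filter_reference(many, repeat_class = c("c1", "c2", "c3")), 7)
  expect_warning(filter_reference(setNames(character(0), character(0))),
                 "empty")
})

test_that("confidence thresholds partition calls as specified", {
  ref <- c(ctg = strrep("A", 100))
  # depth 2, alt 2 (100% but <3 reads) -> below threshold
  pu <- rbind(pileup_row("ctg", 1, c(0, 0, 2, 0)),
              # depth 10, alt 0 -> REF (no call)
              pileup_row("ctg", 2, c(10, 0, 0, 0)),
              # depth 10, alt 9 (90%, >=3) -> confident ALT
              pileup_row("ctg", 3, c(1, 0, 9, 0)),
              # depth 10, alt 7 (70%) -> below threshold
              pileup_row("ctg", 4, c(3, 0, 7, 0)),
              # boundary: alt 8 of 10 = exactly 80% -> confident
              pileup_row("ctg", 5, c(2, 0, 8, 0)),
              # boundary: alt 3 of 3 -> confident
              pileup_row("ctg", 6, c(0, 0, 3, 0)))
  out <- call_snps_per_genotype(pu, ref, "g1")
  st <- setNames(out$calls$status, out$calls$pos)
  expect_identical(unname(st[c("1", "3", "4", "5", "6")]),
                   c("BELOW", "ALT", "BELOW", "ALT", "ALT"))
  expect_false("2" %in% names(st))
  expect_error(call_snps_per_genotype(
    pileup_row("nope", 1, c(1, 0, 0, 0)), ref), "nope")
})

test_that("calling matches an independent brute-force rule evaluation", {
  set.seed(101)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                      collapse = ""))
  n <- 800
  pos <- sample(500, n, replace = TRUE)
  pos <- pos[!duplicated(pos)]
  counts <- t(vapply(seq_along(pos), function(i) {
    d <- rpois(1, 6)
    as.integer(rmultinom(1, d, c(0.55, 0.15, 0.15, 0.15)))
  }, integer(4)))
  pu <- data.frame(contig = "c1", pos = pos, depth = rowSums(counts),
                   A = counts[, 1], C = counts[, 2], G = counts[, 3],
                   T = counts[, 4])
  out <- call_snps_per_genotype(pu, ref, "g")
  expected <- brute_force_call(pu, ref)
  got <- rep("REF", nrow(pu))
  got[pu$depth == 0] <- "MISSING"
  got[match(out$calls$pos, pu$pos)] <- out$calls$status
  expect_identical(got, expected)
  # calling is invariant to pileup row order
  shuf <- pu[sample(nrow(pu)), ]
  out2 <- call_snps_per_genotype(shuf, ref, "g")
  o1 <- out$calls[order(out$calls$pos), ]
  o2 <- out2$calls[order(out2$calls$pos), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("relaxing thresholds never shrinks the confident-call set", {
  set.seed(102)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                      collapse = ""))
  counts <- t(vapply(1:400, function(i) {
    as.integer(rmultinom(1, rpois(1, 8), c(0.5, 0.2, 0.2, 0.1)))
  }, integer(4)))
  pu <- data.frame(contig = "c1", pos = 1:400, depth = rowSums(counts),
                   A = counts[, 1], C = counts[, 2], G = counts[, 3],
                   T = counts[, 4])
  alt_set <- function(min_reads, min_fraction) {
    cc <- call_snps_per_genotype(pu, ref, "g", min_reads, min_fraction)
    cc$calls$pos[cc$calls$status == "ALT"]
  }
  base <- alt_set(3, 0.8)
  expect_true(all(base %in% alt_set(2, 0.8)))
  expect_true(all(base %in% alt_set(3, 0.6)))
  expect_true(all(base %in% alt_set(1, 0.3)))
})

test_that("non-redundant merge deduplicates and assigns statuses", {
  ref <- c(ctg = strrep("A", 100), ctg2 = strrep("C", 100))
  mk_calls <- function(g, rows, covered) {
    structure(list(genotype = g, calls = rows, covered = covered,
                   params = list()), class = "genotype_calls")
  }
  row <- function(contig, pos, alt, status, ref_base = "A")
    data.frame(contig = contig, pos = pos, ref = ref_base, alt = alt,
               depth = 10L, alt_reads = 9L, status = status,
               stringsAsFactors = FALSE)
  cov_all <- c(paste0("ctg:", 1:100), paste0("ctg2:", 1:100))
  # same SNP confident in three genotypes -> one record, 3 ALT statuses
  g1 <- mk_calls("g1", row("ctg", 5, "G", "ALT"), cov_all)
  g2 <- mk_calls("g2", row("ctg", 5, "G", "ALT"), cov_all)
  g3 <- mk_calls("g3", row("ctg", 5, "G", "ALT"), cov_all)
  # below-threshold only, confident nowhere -> absent from the table
  g4 <- mk_calls("g4", row("ctg", 50, "T", "BELOW"), cov_all)
  # no data at position 5 in g5
  g5 <- mk_calls("g5", row("ctg", 60, "G", "ALT"),
                 setdiff(cov_all, "ctg:5"))
  tab <- merge_nonredundant(list(g1, g2, g3, g4, g5), ref)
  expect_identical(nrow(tab$snps), 2L)
  expect_false(50 %in% tab$snps$pos)
  r5 <- tab$status[tab$snps$pos == 5, ]
  expect_identical(unname(r5[c("g1", "g2", "g3", "g4", "g5")]),
                   c("ALT", "ALT", "ALT", "REF", "MISSING"))
  # 2 genotypes x disjoint SNP sets of 5 -> 10 records
  d1 <- mk_calls("d1", do.call(rbind, lapply(1:5, function(p)
    row("ctg", p, "G", "ALT"))), cov_all)
  d2 <- mk_calls("d2", do.call(rbind, lapply(6:10, function(p)
    row("ctg", p, "T", "ALT"))), cov_all)
  expect_identical(nrow(merge_nonredundant(list(d1, d2), ref)$snps), 10L)
  # two different confident ALT bases at one site -> two biallelic records
  m1 <- mk_calls("m1", row("ctg", 7, "G", "ALT"), cov_all)
  m2 <- mk_calls("m2", row("ctg", 7, "T", "ALT"), cov_all)
  expect_warning(tab2 <- merge_nonredundant(list(m1, m2), ref),
                 "multi-allelic")
  expect_identical(nrow(tab2$snps), 2L)
  # below-threshold at a position confident elsewhere is reported as such
  b1 <- mk_calls("b1", row("ctg", 9, "G", "ALT"), cov_all)
  b2 <- mk_calls("b2", row("ctg", 9, "G", "BELOW"), cov_all)
  tab3 <- merge_nonredundant(list(b1, b2), ref)
  expect_identical(unname(tab3$status[1, "b2"]), "BELOW_THRESHOLD")
})

test_that("transition/transversion classification enumerates correctly", {
  expect_identical(classify_ts_tv("A", "G"), "transition")
  expect_identical(classify_ts_tv("C", "A"), "transversion")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_ts_tv(pairs$ref, pairs$alt)
  expect_identical(sum(cls == "transition"), 4L)
  expect_identical(sum(cls == "transversion"), 8L)
  expect_error(classify_ts_tv("N", "A"), "ambiguity")
  expect_error(classify_ts_tv("A", "A"), "differ")
})

test_that("allele frequencies average correctly and match a truth oracle", {
  status <- rbind(c("ALT", rep("REF", 9), "MISSING"),
                  c("ALT", "ALT", rep("REF", 7), "BELOW_THRESHOLD",
                    "MISSING"))
  colnames(status) <- paste0("g", 1:11)
  tab <- make_snp_table(c("c1", "c1"), c(10L, 20L), c("A", "A"),
                        c("G", "G"), status)
  # SNP1: 1 ALT / (10 informative + ref) = 1/11; SNP2: 2/(9+1) = 0.2
  af <- allele_frequency_summary(tab)
  expect_equal(as.numeric(af), mean(c(1 / 11, 2 / 10)))
  af2 <- allele_frequency_summary(tab, include_reference = FALSE)
  expect_equal(as.numeric(af2), mean(c(1 / 10, 2 / 9)))
  expect_error(allele_frequency_summary(tab, subset = "nope"), "unknown")

  # panel oracle: recompute per record from the generator truth list
  run <- small_panel_run(n_contigs = 25, seed = 7)
  got <- allele_frequency_summary(run$tab)
  tr <- run$pan$truth
  n_geno <- length(run$pan$genotypes)
  expected <- mean(vapply(seq_len(nrow(run$tab$snps)), function(i) {
    rec <- run$tab$snps[i, ]
    here <- tr[tr$contig == rec$contig & tr$pos == rec$pos, ]
    n_alt <- sum(here$alt == rec$alt)
    # carriers of a different alternate at the site are uninformative
    n_other <- sum(here$alt != rec$alt)
    n_alt / (n_geno - n_other + 1)
  }, numeric(1)))
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)
})

test_that("SSR finder reports maximal perfect repeats above thresholds", {
  got <- find_ssrs(c(x = "ACACACACACAC"))  # (AC)6
  expect_identical(nrow(got), 1L)
  expect_identical(got$motif, "AC")
  expect_identical(got$copies, 6L)
  expect_identical(c(got$start, got$end), c(1L, 12L))
  # (AT)5 below the di threshold of 6 -> not reported
  expect_identical(nrow(find_ssrs(c(x = "GGATATATATATGG"))), 0L)
  # mononucleotide run of 12 (a run of 10 fails the 12 bp tract minimum)
  expect_identical(nrow(find_ssrs(c(x = paste0("GC", strrep("T", 10), "GA")))),
                   0L)
  got2 <- find_ssrs(c(x = paste0("GC", strrep("T", 12), "GA")))
  expect_identical(got2$motif, "T")
  expect_identical(got2$copies, 12L)
  # planted SSRs are recovered exactly on error-free contigs
  ref <- generate_reference(contig_spec(n_contigs = 120, ssr_rate = 0.5,
                                        seed = 31))
  found <- find_ssrs(ref$contigs[!grepl("d$", names(ref$contigs))])
  truth <- ref$ssr_truth
  key_t <- paste0(truth$contig, ":", truth$start, "-", truth$end)
  key_f <- paste0(found$contig, ":", found$start, "-", found$end)
  expect_true(all(key_t %in% key_f))
})

test_that("error-free calling recovers all planted variants exactly", {
  run <- small_panel_run(n_contigs = 40, seed = 55, depth_mean = 15)
  truth_key <- unique(paste0(run$pan$truth$contig, ":", run$pan$truth$pos,
                             ":", run$pan$truth$alt))
  called_key <- paste0(run$tab$snps$contig, ":", run$tab$snps$pos, ":",
                       run$tab$snps$alt)
  # depth >= 3 everywhere at mean 15 is near-certain; require full recall
  expect_true(all(truth_key %in% called_key))
  # and no false calls
  expect_true(all(called_key %in% truth_key))
  # per-genotype status agrees with the truth carriers
  tr <- run$pan$truth
  for (i in sample(nrow(run$tab$snps), 20)) {
    rec <- run$tab$snps[i, ]
    carriers <- tr$genotype[tr$contig == rec$contig & tr$pos == rec$pos &
                              tr$alt == rec$alt]
    expect_setequal(names(which(run$tab$status[i, ] == "ALT")), carriers)
  }
})
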