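test_that("seeded reference generation is bit-reproducible", {
  s <- contig_spec(n_contigs = 25, seed = 1)
  a <- generate_reference(s)
  b <- generate_reference(s)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$anchors, b$anchors)
  expect_identical(a$ssr_truth, b$ssr_truth)
})

test_that("reference structure honours its declared invariants", {
  ref <- generate_reference(contig_spec(n_contigs = 50, seed = 3))
  tab <- ref$contig_table
  expect_true(all(tab$length >= 200))
  expect_true(all(nchar(ref$contigs[tab$contig]) == tab$length))
  cds_len <- tab$cds_end - tab$cds_start + 1
  expect_true(all(cds_len %% 3 == 0))
  # CDS read in transcription order starts with sense codons, ends in stop
  gc <- Biostrings::GENETIC_CODE
  for (i in sample(nrow(tab), 10)) {
    s <- ref$contigs[[tab$contig[i]]]
    cds <- substr(s, tab$cds_start[i], tab$cds_end[i])
    if (tab$strand[i] == "-")
      cds <- paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]),
                   collapse = "")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_true(all(gc[codons[-length(codons)]] != "*"))
    expect_identical(unname(gc[codons[length(codons)]]), "*")
  }
})

test_that("ssr_rate = 0 plants no SSRs and dup_rate follows binomial bounds", {
  ref0 <- generate_reference(contig_spec(n_contigs = 40, ssr_rate = 0,
                                         seed = 5))
  expect_identical(nrow(ref0$ssr_truth), 0L)
  refd <- generate_reference(contig_spec(n_contigs = 1000, length_mean = 210,
                                         dup_rate = 0.5, ssr_rate = 0,
                                         seed = 6))
  n_dup <- nrow(refd$duplicate_pairs)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_dup, bounds[1])
  expect_lte(n_dup, bounds[2])
})

test_that("zero cultivated divergence leaves cultivated lines identical", {
  ref <- generate_reference(contig_spec(n_contigs = 10, seed = 7))
  pan <- mutate_panel(ref, panel_spec(theta_cultivated = 0, seed = 8))
  for (g in pan$cultivated)
    expect_identical(pan$haplotypes[[g]], ref$contigs)
  expect_false(identical(pan$haplotypes[[pan$wild[1]]], ref$contigs))
})

test_that("transition fraction of planted variants follows ts_tv_ratio", {
  ref <- generate_reference(contig_spec(n_contigs = 150, seed = 9))
  is_ts <- function(truth) {
    # unique variants: shared variants appear once per carrier in truth
    u <- unique(truth[c("contig", "pos", "ref", "alt")])
    lenspipe::classify_ts_tv(u$ref, u$alt) == "transition"
  }
  # ts_tv_ratio = 0.5 -> expected transition fraction 1/3
  pan <- mutate_panel(ref, panel_spec(ts_tv_ratio = 0.5, seed = 10))
  ts <- is_ts(pan$truth)
  expect_gt(length(ts), 500)
  expect_lt(abs(mean(ts) - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / length(ts)))
  # default 1.5 -> 0.6
  pan2 <- mutate_panel(ref, panel_spec(seed = 11))
  ts2 <- is_ts(pan2$truth)
  expect_lt(abs(mean(ts2) - 0.6), 3 * sqrt(0.6 * 0.4 / length(ts2)))
})

test_that("wild variant counts land in the Poisson interval at 1 Mbp", {
  ref <- generate_reference(contig_spec(n_contigs = 1667, length_mean = 600,
                                        ssr_rate = 0, seed = 12))
  total <- sum(nchar(ref$contigs))
  expect_gt(total, 9e5)
  pan <- mutate_panel(ref, panel_spec(theta_wild = 0.01, seed = 13))
  lambda <- total * 0.01
  for (g in pan$wild) {
    n_g <- sum(pan$truth$genotype == g)
    expect_gte(n_g, qpois(0.005, lambda))
    expect_lte(n_g, qpois(0.995, lambda))
  }
  # wild genotypes carry more variants than cultivated in expectation
  n_wild <- mean(table(pan$truth$genotype)[pan$wild])
  n_cult <- mean(table(pan$truth$genotype)[pan$cultivated])
  expect_gt(n_wild, 2 * n_cult)
})

test_that("pileups are seeded-deterministic with exact counts", {
  ref <- generate_reference(contig_spec(n_contigs = 8, seed = 14))
  pan <- mutate_panel(ref, panel_spec(seed = 15))
  a <- simulate_pileups(pan, depth_mean = 20, error_rate = 0, seed = 16)
  b <- simulate_pileups(pan, depth_mean = 20, error_rate = 0, seed = 16)
  expect_identical(a, b)
  pu <- a[[pan$wild[1]]]
  expect_true(all(rowSums(pu[c("A", "C", "G", "T")]) == pu$depth))
  # error-free: all reads carry the haplotype base, incl. at variant sites
  v <- pan$truth[pan$truth$genotype == pan$wild[1], ][1, ]
  row <- pu[pu$contig == v$contig & pu$pos == v$pos, ]
  expect_identical(row$depth, row[[v$alt]])
})

test_that("mean simulated depth converges to depth_mean", {
  ref <- generate_reference(contig_spec(n_contigs = 120, seed = 17))
  pan <- mutate_panel(ref, panel_spec(n_cultivated = 1, n_wild = 1,
                                      seed = 18))
  pu <- simulate_pileups(pan, depth_mean = 12, seed = 19)
  m <- mean(pu[[1]]$depth)
  expect_lt(abs(m - 12) / 12, 0.01)
})

test_that("RIL markers 0 cM apart never recombine", {
  map <- data.frame(marker = c("m1", "m2"), lg = "LG1", cM = c(10, 10))
  spec <- ril_spec(n_lg = 1, markers_per_lg = 2, n_ril = 200,
                   missing_rate = 0, n_poor_dna = 0, seed = 20)
  pop <- simulate_ril_population(map, spec)
  calls <- pop$calls[, !colnames(pop$calls) %in% c("P1", "P2")]
  expect_true(all(calls["m1", ] == calls["m2", ]))
})

test_that("RIL recombinant fraction matches the Haldane-Waddington limit", {
  # adjacent markers at r = 0.2: RIL R = 2r/(1+2r) = 1/3
  d <- kosambi_cM(0.2)
  map <- data.frame(marker = c("m1", "m2"), lg = "LG1", cM = c(0, d))
  spec <- ril_spec(n_lg = 1, markers_per_lg = 2, n_ril = 1000,
                   missing_rate = 0, n_poor_dna = 0, seed = 21)
  pop <- simulate_ril_population(map, spec)
  calls <- pop$calls[, !colnames(pop$calls) %in% c("P1", "P2")]
  hom <- calls["m1", ] %in% c("A", "B") & calls["m2", ] %in% c("A", "B")
  R <- mean(calls["m1", hom] != calls["m2", hom])
  expect_lt(abs(R - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / sum(hom)))
})

test_that("residual heterozygosity decays as 0.5^generations", {
  map <- data.frame(marker = sprintf("m%d", 1:20), lg = "LG1",
                    cM = seq(0, 95, by = 5))
  spec <- ril_spec(n_lg = 1, markers_per_lg = 20, n_ril = 800,
                   selfing_generations = 7, missing_rate = 0,
                   n_poor_dna = 0, seed = 22)
  pop <- simulate_ril_population(map, spec)
  calls <- pop$calls[, !colnames(pop$calls) %in% c("P1", "P2")]
  h <- mean(calls == "H")
  n <- length(calls)
  expect_lt(abs(h - 0.5^7), 4 * sqrt(0.5^7 * (1 - 0.5^7) / n))
})

test_that("invalid specifications are rejected", {
  expect_error(contig_spec(10, length_mean = 150), "length_mean")
  expect_error(panel_spec(theta_cultivated = 0.02, theta_wild = 0.01),
               "theta")
  expect_error(ril_spec(missing_rate = 1), "missing_rate")
  map <- data.frame(marker = "m1", lg = "LG1", cM = NA_real_)
  expect_error(simulate_ril_population(map, ril_spec(seed = 1)),
               "map position")
})
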