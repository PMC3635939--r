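test_that("Kosambi function behaves and round-trips", {
  expect_equal(kosambi_cM(0), 0)
  expect_equal(kosambi_cM(0.2), 21.18, tolerance = 2e-4)
  r <- seq(0, 0.49, by = 0.01)
  d <- kosambi_cM(r)
  expect_true(all(diff(d) > 0))
  expect_gt(kosambi_cM(0.4999), 100)
  expect_equal(kosambi_r(d), r, tolerance = 1e-10)
  expect_error(kosambi_cM(0.5), "0.5")
  expect_error(kosambi_r(-1), ">= 0")
})

test_that("consensus haplotypes fill missing data and flag conflicts", {
  calls <- rbind(m1 = c("A", "U", "A", "B"),
                 m2 = c("U", "B", "A", "B"),
                 m3 = c("A", "U", "B", "U"),
                 m4 = c("B", "B", "B", "A"))
  colnames(calls) <- paste0("i", 1:4)
  mc <- c(m1 = "ctg1", m2 = "ctg1", m3 = "ctg1", m4 = "ctg2")
  cons <- consensus_haplotype(calls, mc)
  # {A, U} -> A (filled in); {A, B} disagreement -> U; all U -> handled
  expect_identical(unname(cons["ctg1", ]), c("A", "B", "U", "B"))
  # single-marker contig: unchanged
  expect_identical(unname(cons["ctg2", ]), unname(calls["m4", ]))
  expect_error(consensus_haplotype(calls, mc[-1]), "without a contig")
})

test_that("dominant markers are recoded by the null parent", {
  calls <- rbind(d1 = c("NULL", "PRESENT", "NULL", "PRESENT", "U"),
                 d2 = c("PRESENT", "PRESENT", "NULL", "NULL", "NULL"))
  colnames(calls) <- c("P1", "P2", "i1", "i2", "i3")
  out <- recode_dominant(calls)
  # P1 null -> null allele is A
  expect_identical(unname(out["d1", ]), c("A", "B", "A", "B", "U"))
  expect_identical(attr(out, "dropped"), "d2")  # parents indistinguishable
})

test_that("recoded dominant markers match truth genotypes in simulation", {
  spec <- ril_spec(n_lg = 1, markers_per_lg = 12, lg_length_cM = 60,
                   n_ril = 150, missing_rate = 0, n_poor_dna = 0, seed = 81)
  pop <- simulate_ril_population(make_marker_map(spec), spec)
  truth <- pop$calls
  # simulate a dominant assay: allele B gives no signal
  dom <- ifelse(truth == "B", "NULL",
                ifelse(truth %in% c("A", "H"), "PRESENT", "U"))
  out <- recode_dominant(dom)
  inds <- setdiff(colnames(truth), c("P1", "P2"))
  hom <- truth[, inds] %in% c("A", "B")
  agree <- mean(out[, inds][hom] == truth[, inds][hom])
  expect_gte(agree, 0.99)  # H scored PRESENT collapses onto A only
})

test_that("individual QC removes exactly the high-missing samples", {
  spec <- ril_spec(n_lg = 2, markers_per_lg = 25, n_ril = 144,
                   n_poor_dna = 5, seed = 82)
  pop <- simulate_ril_population(make_marker_map(spec), spec)
  out <- qc_individuals(pop$calls, max_missing = 0.2)
  removed <- attr(out, "removed")
  expect_identical(sort(removed$individual), pop$poor_dna)
  expect_identical(ncol(out), 144L + 2L - 5L)
  # brute-force recount
  frac <- colMeans(pop$calls == "U")
  expect_identical(nrow(removed), sum(frac > 0.2) )
  # threshold 1.0 removes nobody
  expect_identical(ncol(qc_individuals(pop$calls, 1.0)), ncol(pop$calls))
  all_u <- matrix("U", 3, 4, dimnames = list(paste0("m", 1:3),
                                             paste0("i", 1:4)))
  expect_error(qc_individuals(all_u, 0.5), "all individuals")
})

test_that("pairwise linkage statistics follow their closed forms", {
  # identical rows over 20 informative individuals: LOD = 20 log10(2)
  calls <- rbind(m1 = rep(c("A", "B"), 10), m2 = rep(c("A", "B"), 10))
  colnames(calls) <- paste0("i", 1:20)
  pl <- pairwise_linkage(calls)
  expect_identical(pl$n["m1", "m2"], 20)
  expect_equal(pl$lod["m1", "m2"], 20 * log10(2))
  expect_equal(pl$lod["m1", "m2"], 6.02, tolerance = 1e-3)
  # R = 0.4 -> r = 0.3333; R = 0.5 -> LOD = 0
  g1 <- c(rep("A", 10), rep("B", 10))
  g2 <- c(rep("A", 6), rep("B", 4), rep("B", 6), rep("A", 4))
  pl2 <- pairwise_linkage(rbind(m1 = g1, m2 = g2))
  expect_equal(pl2$R["m1", "m2"], 0.4)
  expect_equal(pl2$r["m1", "m2"], 1 / 3, tolerance = 1e-9)
  g3 <- c(rep(c("A", "B"), 5), rep(c("B", "A"), 5))
  pl3 <- pairwise_linkage(rbind(m1 = g1, m2 = g3))
  expect_equal(pl3$R["m1", "m2"], 0.5)
  expect_equal(pl3$lod["m1", "m2"], 0)
  # H calls are excluded from the informative count
  g4 <- c(rep("H", 5), rep("A", 5), rep("B", 10))
  pl4 <- pairwise_linkage(rbind(m1 = g1, m2 = g4))
  expect_identical(pl4$n["m1", "m2"], 15)
})

test_that("LOD grouping is a refinement-monotone component partition", {
  spec <- ril_spec(n_lg = 3, markers_per_lg = 15, lg_length_cM = 80,
                   n_ril = 120, n_poor_dna = 0, seed = 83)
  map <- make_marker_map(spec)
  pop <- simulate_ril_population(map, spec)
  pairs <- pairwise_linkage(pop$calls)
  groups <- group_markers(pairs, 6)
  expect_length(groups, 3L)
  for (g in groups) {
    lgs <- unique(map$lg[match(g, map$marker)])
    expect_length(lgs, 1L)
  }
  # threshold high enough -> every marker its own group
  singletons <- group_markers(pairs, Inf)
  expect_length(singletons, nrow(map))
  # raising the threshold never merges groups
  g10 <- group_markers(pairs, 10)
  for (g in g10) {
    in6 <- vapply(groups, function(x) all(g %in% x), logical(1))
    expect_identical(sum(in6), 1L)
  }
})

test_that("ordering recovers simulated maps and is reversal-invariant", {
  spec <- ril_spec(n_lg = 2, markers_per_lg = 30, lg_length_cM = 100,
                   n_ril = 139, n_poor_dna = 0, seed = 84)
  map <- make_marker_map(spec)
  pop <- simulate_ril_population(map, spec)
  lmap <- build_linkage_map(pop$calls)
  expect_length(lmap$groups, 2L)
  for (g in unique(lmap$map$group)) {
    sub <- lmap$map[lmap$map$group == g, ]
    truth <- map$cM[match(sub$marker, map$marker)]
    expect_gte(abs(cor(sub$cM, truth, method = "spearman")), 0.95)
    expect_true(all(diff(sub$cM) >= 0))
    expect_identical(sub$cM[1], 0)
  }
  # r = 0 adjacent pair -> 0 cM apart; r = 0.2 -> 21.18 cM
  pr <- structure(list(r = matrix(c(0, 0, 0, 0), 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("a", "b")))),
                  class = "pair_linkage")
  os <- order_and_space(c("a", "b"), pr)
  expect_equal(os$cM, c(0, 0))
  pr2 <- structure(list(r = matrix(c(0, 0.2, 0.2, 0), 2, 2,
                                   dimnames = list(c("a", "b"),
                                                   c("a", "b")))),
                   class = "pair_linkage")
  expect_equal(order_and_space(c("a", "b"), pr2)$cM[2], 21.18,
               tolerance = 2e-4)
})

test_that("map length is invariant under group reversal", {
  spec <- ril_spec(n_lg = 1, markers_per_lg = 20, lg_length_cM = 90,
                   n_ril = 120, n_poor_dna = 0, seed = 85)
  map <- make_marker_map(spec)
  pop <- simulate_ril_population(map, spec)
  pairs <- pairwise_linkage(pop$calls)
  groups <- group_markers(pairs, 6)
  g <- groups[[1]]
  fwd <- order_and_space(g, pairs)
  rev_ <- order_and_space(rev(g), pairs)
  expect_equal(max(fwd$cM), max(rev_$cM), tolerance = 1e-9)
  expect_identical(fwd$marker, rev_$marker)  # canonical orientation
})
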