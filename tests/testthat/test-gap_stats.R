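make_gap_world <- function(n_species = 4, n_acc = 3, inter_mut = 10,
                           intra_mut = 1, L = 300, seed = 71) {
  set.seed(seed)
  seqs <- character(0); species <- character(0)
  base <- random_dna(L)
  for (s in seq_len(n_species)) {
    center <- mutate_seq(base, inter_mut * s)
    for (a in seq_len(n_acc)) {
      id <- sprintf("sp%02d_a%d", s, a)
      seqs[id] <- mutate_seq(center, intra_mut)
      species[id] <- sprintf("Sp %02d", s)
    }
  }
  recs <- marker_records(names(seqs), unname(seqs), species = species,
                         genus = "Gen", subfamily = "SF1",
                         species_group = "g1", provenance = "P1")
  list(records = recs, d = distance_matrix(as_msa(seqs)))
}

test_that("pair classification strata are disjoint and exhaustive", {
  set.seed(72)
  seqs <- setNames(vapply(1:8, function(i) mutate_seq(random_dna(200), i),
                          character(1)), paste0("r", 1:8))
  recs <- marker_records(names(seqs), unname(seqs),
                         species = c("A a", "A a", "A b", "B c",
                                     "B d", "C e", "C f", "D g"),
                         genus = "G", subfamily = rep(c("SF1", "SF2"), 4),
                         species_group = rep(c("g1", "g2"), each = 4),
                         provenance = "P1")
  d <- distance_matrix(as_msa(seqs))
  pairs <- classify_pairs(d, recs)
  expect_equal(nrow(pairs), choose(8, 2) - sum(is.na(d[upper.tri(d)])))
  expect_true(all(pairs$level %in% c("intraspecific", "congeneric",
                                     "intergeneric", "interfamilial")))
})

test_that("intra/inter pair counts follow the combinatorics", {
  w <- make_gap_world(n_species = 1, n_acc = 3)
  parts <- partition_distances(w$d, w$records)
  expect_equal(length(parts$intra), 3L)        # C(3,2)
  expect_equal(length(parts$inter), 0L)
  w2 <- make_gap_world(n_species = 2, n_acc = 1)
  parts2 <- partition_distances(w2$d, w2$records)
  expect_equal(length(parts2$intra), 0L)
  expect_equal(length(parts2$inter), 1L)
  # 11 species x 5 accessions: 11 * C(5,2) intraspecific pairs
  w3 <- make_gap_world(n_species = 11, n_acc = 5, inter_mut = 4, L = 400)
  parts3 <- partition_distances(w3$d, w3$records)
  expect_equal(length(parts3$intra), 11 * choose(5, 2))
  expect_equal(length(parts3$inter), choose(55, 2) - 11 * choose(5, 2))
})

test_that("Wilcoxon exact p matches full enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)        # most extreme of C(6,3) = 20
  expect_equal(r$method, "exact")
  expect_equal(r$w_stat, 6)
  # identical samples -> p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact p agrees with the reference implementation (tie-free)", {
  set.seed(73)
  for (k in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:8, 1)
    x <- sample(1:1000, na + nb)    # distinct -> no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    ours <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$w_stat, ref$statistic[[1]] + na * (na + 1) / 2)
  }
})

test_that("exact and normal p agree tightly at the 8 vs 8 boundary", {
  # exhaustive over every achievable rank sum: the continuity-corrected
  # normal approximation deviates from the exact two-sided p by at most
  # 0.011 anywhere in the 8 vs 8 regime (the worst case, at W = 60, is
  # 0.0109; no normal approximation does better than ~0.01 here)
  set.seed(74)
  x <- sort(sample(1:10000, 16))
  rank_sets <- list(1:8,                             # W = 36, extreme
                    c(1, 2, 3, 4, 7, 13, 14, 16),    # W = 60, worst case
                    c(1, 3, 5, 7, 9, 11, 13, 15),    # W = 64
                    9:16)                            # W = 100, extreme
  for (rs in rank_sets) {
    a <- x[rs]; b <- x[-rs]
    pe <- wilcoxon_rank_sum(a, b, exact_max = 8)$p_value
    pn <- wilcoxon_rank_sum(a, b, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.011)
  }
  # and on random tie-free draws
  for (k in 1:20) {
    y <- sample(1:10000, 16)
    pe <- wilcoxon_rank_sum(y[1:8], y[9:16], exact_max = 8)$p_value
    pn <- wilcoxon_rank_sum(y[1:8], y[9:16], exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.011)
  }
})

test_that("Wilcoxon p is invariant under monotone transforms", {
  set.seed(75)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  p0 <- wilcoxon_rank_sum(a, b)$p_value
  expect_equal(wilcoxon_rank_sum(exp(a), exp(b))$p_value, p0)
  expect_equal(wilcoxon_rank_sum(a^3, b^3)$p_value, p0)
})

test_that("ties are handled with midranks and tie-corrected variance", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  ours <- wilcoxon_rank_sum(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$w_stat, ref$statistic[[1]] + 4 * 5 / 2)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("gap report detects planted separation and planted overlap", {
  # disjoint: intra <= 0.004, inter >= 0.05
  w <- make_gap_world(inter_mut = 20, intra_mut = 1)
  rep1 <- gap_report(w$d, w$records)
  expect_false(rep1$overlap)
  expect_lt(rep1$p_value, 0.001)
  expect_equal(rep1$n_intra, 4 * choose(3, 2))
  # overlapping: one species with deep intraspecific variation alongside
  # a close neighbor species -- the intra pair is farther than the
  # closest inter pair, so no gap exists
  set.seed(76)
  base <- random_dna(300)
  seqs <- c(sp1_a1 = base,
            sp1_a2 = mutate_seq(base, 15),    # deep intra pair
            sp2_a1 = mutate_seq(base, 2),     # close inter neighbor
            sp2_a2 = mutate_seq(mutate_seq(base, 2), 1))
  recs <- marker_records(names(seqs), unname(seqs),
                         species = c("Sp 1", "Sp 1", "Sp 2", "Sp 2"),
                         genus = "Gen", subfamily = "SF1",
                         species_group = "g1", provenance = "P1")
  rep2 <- gap_report(distance_matrix(as_msa(seqs)), recs)
  expect_true(rep2$overlap)
  expect_true(max(rep2$intra) >= min(rep2$inter))
})

test_that("degenerate single-species input warns and leaves p unset", {
  w <- make_gap_world(n_species = 1, n_acc = 4)
  expect_warning(rep1 <- gap_report(w$d, w$records), "fewer than 2")
  expect_true(is.na(rep1$p_value))
  expect_equal(rep1$n_inter, 0L)
})

test_that("gap reports serialize to JSON with the summary strata", {
  w <- make_gap_world()
  rep1 <- gap_report(w$d, w$records)
  tf <- tempfile(fileext = ".json")
  write_gap_json(rep1, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$n_intra, rep1$n_intra)
  expect_equal(back$overlap, rep1$overlap)
  expect_true("by_level" %in% names(back))
})
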