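test_that("NJ recovers a hand-built additive 4-taxon matrix exactly", {
  # tree: ((a:2,b:3):1,(c:4,d:5))  -> additive distances
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"),
                              c("a", "b", "c", "d")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c", "d"))
  # additive matrices are reconstructed exactly: path lengths match
  coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(coph, d, tolerance = 1e-9)
})

test_that("three taxa resolve by the closed three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                  tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(len[["a"]], (3 + 4 - 5) / 2)
  expect_equal(len[["b"]], (3 + 5 - 4) / 2)
  expect_equal(len[["c"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers random additive topologies (RF = 0) and matches ape", {
  skip_if_not_installed("phangorn")
  set.seed(81)
  for (k in 1:15) {
    n <- sample(4:10, 1)
    tr0 <- ape::rtree(n, br = function(x) runif(x, 0.1, 1))
    d <- ape::cophenetic.phylo(tr0)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    tr <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr0)), 0)
    expect_equal(phangorn::RF.dist(ape::unroot(tr),
                                   ape::unroot(ape::nj(as.dist(d)))), 0)
  }
})

test_that("NJ refuses masked matrices and degenerate sizes", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d[1, 2] <- d[2, 1] <- NA
  expect_error(neighbor_joining(d), "masked")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("ultrametric matrices mirror the single-linkage dendrogram", {
  # clear two-clade ultrametric structure
  labs <- c("a", "b", "c", "d", "e")
  d <- matrix(1, 5, 5, dimnames = list(labs, labs))
  d[1:2, 1:2] <- 0.1; d[3:5, 3:5] <- 0.2; diag(d) <- 0
  tr <- neighbor_joining(d)
  parts <- lcnbarcode:::.bipartitions(tr)
  expect_true(paste(sort(c("c", "d", "e")), collapse = "\r") %in% parts ||
                paste(sort(c("a", "b")), collapse = "\r") %in% parts)
  hc <- hclust(as.dist(d), method = "single")
  expect_setequal(cutree(hc, 2)[1:2], 1)   # same first clade
})

test_that("bootstrap supports planted clades and quantizes correctly", {
  set.seed(82)
  base <- random_dna(200)
  diag1 <- random_dna(30); diag2 <- random_dna(30)
  mk <- function(core, tag) paste0(core, tag)
  seqs <- c(a1 = mk(mutate_seq(base, 1), diag1),
            a2 = mk(mutate_seq(base, 1), diag1),
            a3 = mk(mutate_seq(base, 1), diag1),
            b1 = mk(mutate_seq(base, 25), diag2),
            b2 = mk(mutate_seq(base, 25), diag2),
            b3 = mk(mutate_seq(base, 25), diag2))
  tr <- bootstrap_support(as_msa(seqs), n_replicates = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup >= 95, na.rm = TRUE))
  # one replicate -> supports in {0, 100}
  tr1 <- bootstrap_support(as_msa(seqs), n_replicates = 1, seed = 5)
  sup1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup1 %in% c(0, 100) | is.na(sup1)))
})

test_that("bootstrap is invariant to leaf input order at a fixed seed", {
  set.seed(83)
  base <- random_dna(150)
  seqs <- setNames(vapply(c(1, 1, 8, 8, 15), function(m)
    mutate_seq(base, m), character(1)), c("a", "b", "c", "d", "e"))
  t1 <- bootstrap_support(as_msa(seqs), 50, seed = 9)
  t2 <- bootstrap_support(as_msa(seqs[c(3, 1, 5, 2, 4)]), 50, seed = 9)
  s1 <- setNames(t1$node.label, vapply(lcnbarcode:::.tips_under(t1),
                                       function(x) paste(sort(x), collapse = ","),
                                       character(1)))
  s2 <- setNames(t2$node.label, vapply(lcnbarcode:::.tips_under(t2),
                                       function(x) paste(sort(x), collapse = ","),
                                       character(1)))
  shared <- intersect(names(s1), names(s2))
  expect_true(length(shared) >= 2)
  expect_equal(s1[shared], s2[shared])
})

test_that("degenerate identical-sequence alignments do not crash bootstrap", {
  seqs <- setNames(rep(strrep("ACGT", 40), 4), paste0("s", 1:4))
  expect_no_error(tr <- bootstrap_support(as_msa(seqs), 5, seed = 1))
  expect_equal(length(tr$tip.label), 4L)
})

test_that("alleles assign to their genepools with sane margins and ties", {
  set.seed(84)
  poolA_ref <- random_dna(400)
  poolB_ref <- mutate_seq(poolA_ref, 40)
  pools <- list(A = c(rA1 = poolA_ref, rA2 = mutate_seq(poolA_ref, 2)),
                B = c(rB1 = poolB_ref, rB2 = mutate_seq(poolB_ref, 2)))
  alleles <- data.frame(
    allele_id = c("x_a", "x_b", "y_a"),
    individual_id = c("x", "x", "y"),
    sequence = c(poolA_ref,                 # identical to a pool-A reference
                 mutate_seq(poolB_ref, 1),  # near pool B
                 mutate_seq(poolA_ref, 3)), # near pool A only
    stringsAsFactors = FALSE)
  asn <- assign_alleles(alleles, pools)
  expect_equal(asn$genepool, c("A", "B", "A"))
  expect_true(asn$identical[1])
  expect_true(all(asn$margin >= 0))
  expect_equal(unique(asn$putative_hybrid[asn$individual_id == "x"]), TRUE)
  expect_equal(unique(asn$putative_hybrid[asn$individual_id == "y"]), FALSE)
  # exact tie: same sequence in both pools
  tie_pools <- list(P1 = c(r1 = poolA_ref), P2 = c(r2 = poolA_ref))
  tie <- assign_alleles(data.frame(allele_id = "t_a", individual_id = "t",
                                   sequence = poolA_ref), tie_pools)
  expect_equal(tie$genepool, "P1")
  expect_equal(tie$margin, 0)
  expect_true(tie$tie)
})

test_that("non-hybrids are never flagged when all alleles fall in one pool", {
  set.seed(85)
  a <- random_dna(300); b <- mutate_seq(a, 30)
  pools <- list(A = c(r1 = a), B = c(r2 = b))
  alleles <- data.frame(allele_id = paste0("i", 1:4, "_a"),
                        individual_id = paste0("i", 1:4),
                        sequence = vapply(1:4, function(k) mutate_seq(a, 2),
                                          character(1)))
  asn <- assign_alleles(alleles, pools)
  expect_true(all(!asn$putative_hybrid))
})
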