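# A small hand-built world: three species with boundaries set, one of
# them duplicated byte-identically under a second species name to force
# ambiguity.
make_world <- function(seed = 61) {
  set.seed(seed)
  exon <- random_dna(264)
  base_intron <- random_dna(150)
  a_exon <- exon
  b_exon <- mutate_seq(exon, 12)
  c_exon <- mutate_seq(exon, 25)
  seq_of <- function(e) paste0(e, base_intron)
  seqs <- c(A1 = seq_of(a_exon),                 # species A, 2 provenances
            A2 = seq_of(mutate_seq(a_exon, 1)),
            B1 = seq_of(b_exon),                 # species B, 2 provenances
            B2 = seq_of(mutate_seq(b_exon, 1)),
            C1 = seq_of(c_exon))                 # species C, 1 provenance
  marker_records(names(seqs), unname(seqs),
                 species = c("Aa x", "Aa x", "Bb y", "Bb y", "Cc z"),
                 genus = c("Aa", "Aa", "Bb", "Bb", "Cc"),
                 subfamily = "SF1",
                 species_group = c("g1", "g1", "g1", "g1", "g2"),
                 provenance = c("HD", "GOE", "HD", "GOE", "HD"),
                 exon_end = 264L, intron_end = 414L)
}

test_that("queries are one record per multi-provenance species", {
  recs <- make_world()
  q <- select_queries(recs)
  expect_equal(q$id, c("A1", "B1"))          # smallest id per species
  # single-provenance species are excluded
  expect_false("Cc z" %in% q$species)
  # planted: 7 of 20 species multi-provenance -> exactly 7 queries
  set.seed(62)
  ids <- sprintf("sp%02d_%d", rep(1:20, each = 2), rep(1:2, 20))
  recs2 <- marker_records(ids, replicate(40, random_dna(80)),
                          species = sprintf("Sp %02d", rep(1:20, each = 2)),
                          provenance = ifelse(rep(1:20, each = 2) <= 7,
                                              rep(c("P1", "P2"), 20), "P1"))
  expect_equal(nrow(select_queries(recs2)), 7L)
})

test_that("unique top hit is correct; tied species are ambiguous", {
  recs <- make_world()
  db <- build_reference_db(recs, "exon_intron")
  r <- identify(recs[recs$id == "A1", ], db)
  expect_equal(r$outcome, "correct")
  expect_equal(r$top_species, "Aa x")
  # plant a byte-identical sequence under another species
  dup <- recs[recs$id == "A2", ]
  dup$id <- "D1"; dup$species <- "Dd w"; dup$genus <- "Dd"
  recs2 <- rbind(recs, dup)
  db2 <- build_reference_db(recs2, "exon_intron")
  r2 <- identify(recs2[recs2$id == "A1", ], db2)
  expect_equal(r2$outcome, "ambiguous")
  expect_setequal(r2$top_species, c("Aa x", "Dd w"))
})

test_that("self-hits are excluded and missing conspecifics are flagged", {
  recs <- make_world()
  db <- build_reference_db(recs, "exon_intron")
  # C has no conspecific: can only be incorrect or no_hit, and is flagged
  r <- identify(recs[recs$id == "C1", ], db)
  expect_false(r$conspecific_in_db)
  expect_true(r$outcome %in% c("incorrect", "no_hit"))
  expect_false("C1" %in% r$hits$subject_id)
})

test_that("group-level correctness follows the single best hit", {
  recs <- make_world()
  db <- build_reference_db(recs, "exon_intron")
  res <- identify_all(select_queries(recs), db)
  expect_true(all(res$group_correct[res$outcome == "correct"]))
})

test_that("success tables count outcomes like a barcoding trial", {
  res <- data.frame(query_id = paste0("q", 1:10),
                    species = paste0("s", 1:10),
                    outcome = c(rep("correct", 6), rep("ambiguous", 3),
                                "incorrect"),
                    top_bit_score = 1, top_species = "x",
                    group_correct = rep(c(TRUE, FALSE), c(8, 2)),
                    conspecific_in_db = TRUE)
  tab <- success_table(res, "exon_intron")
  expect_equal(tab$correct, c(6L, 8L))
  expect_equal(tab$ambiguous[1], 3L)
  expect_equal(tab$n_tested, c(10L, 10L))
  expect_error(success_table(res[0, ]), "no identification results")
})

test_that("identification is deterministic and robust to non-top pruning", {
  recs <- make_world()
  db <- build_reference_db(recs, "exon_intron")
  q <- recs[recs$id == "A1", ]
  r1 <- identify(q, db)
  r2 <- identify(q, db)
  expect_identical(r1$outcome, r2$outcome)
  expect_identical(r1$hits, r2$hits)
  # dropping subjects below the top tie set cannot flip correct -> incorrect
  keep <- c("A2", "B1")
  db_small <- build_reference_db(recs[recs$id %in% keep, ], "exon_intron")
  expect_equal(identify(q, db_small)$outcome, "correct")
})

test_that("planted well-separated simulations identify nearly all species", {
  # interspecific >= 3%, intraspecific <= 0.5%: identification should be
  # essentially perfect in exon+intron mode
  p <- sim_params(n_subfamilies = 1, n_groups_per_subfamily = 2,
                  n_species_per_group = 5, accessions_per_species = 2,
                  exon_divergence_target = 0.03,
                  intraspecific_divergence = 0.004,
                  het_fraction = 0, seed = 63)
  sim <- simulate_dataset(p)
  db <- build_reference_db(sim$records, "exon_intron")
  res <- identify_all(select_queries(sim$records), db)
  expect_gte(mean(res$outcome == "correct"), 0.9)
})

test_that("exon+intron mode is at least as accurate as exon-only", {
  accs <- vapply(c(64, 65), function(seed) {
    p <- sim_params(n_subfamilies = 1, n_groups_per_subfamily = 2,
                    n_species_per_group = 5, accessions_per_species = 2,
                    exon_divergence_target = 0.015,
                    intraspecific_divergence = 0.004,
                    het_fraction = 0, seed = seed)
    sim <- simulate_dataset(p)
    q <- select_queries(sim$records)
    both <- vapply(c("exon", "exon_intron"), function(m) {
      db <- build_reference_db(sim$records, m)
      mean(identify_all(q, db)$outcome == "correct")
    }, numeric(1))
    both["exon_intron"] - both["exon"]
  }, numeric(1))
  expect_true(all(accs >= 0))
})

test_that("identification results serialize with the fixed column set", {
  recs <- make_world()
  db <- build_reference_db(recs, "exon_intron")
  res <- identify_all(select_queries(recs), db)
  tf <- tempfile(fileext = ".tsv")
  write_identification_tsv(res, tf)
  back <- read.delim(tf)
  expect_equal(names(back), c("query_id", "species", "outcome",
                              "top_bit_score", "top_species",
                              "group_correct"))
  expect_equal(back$outcome, res$outcome)
})
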