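# Independent oracles and tiny fixture builders used across the suite.

# Unbanded full-matrix Needleman-Wunsch score with linear gap costs,
# written naively in R: the reference for the banded C++ kernel.
nw_score_full <- function(a, b, match = 1, mismatch = -2, gap = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  S <- matrix(0, la + 1, lb + 1)
  S[1, ] <- -gap * (0:lb)
  S[, 1] <- -gap * (0:la)
  for (i in seq_len(la))
    for (j in seq_len(lb))
      S[i + 1, j + 1] <- max(S[i, j] + if (A[i] == B[j]) match else mismatch,
                             S[i, j + 1] - gap, S[i + 1, j] - gap)
  S[la + 1, lb + 1]
}

# Connected components of the >= threshold identity graph (exhaustive,
# for small n): greedy clusters must each sit inside one component.
identity_components <- function(seqs, threshold) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <-
        global_identity(seqs[[i]], seqs[[j]])$identity >= threshold
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(seqs), comp)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Mutate a sequence at k positions, guaranteeing the base changes.
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# A minimal record table with controllable metadata.
toy_records <- function(seqs, species = names(seqs),
                        group = NA_character_, subfamily = "SF1",
                        provenance = "P1") {
  marker_records(id = names(seqs), sequence = unname(seqs),
                 species = species, genus = sub(" .*", "", species),
                 subfamily = subfamily, species_group = group,
                 provenance = provenance)
}
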