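#' Megablast-style scoring scheme
#'
#' Defaults follow the common megablast configuration for short, highly
#' similar barcode sequences: match +1, mismatch -2, linear gap cost, word
#' size 28, maximum E-value 10. The linear per-position gap cost is not
#' published for this mode; 2 keeps a gap exactly as costly as a mismatch
#' and is configurable.
#'
#' @param match positive integer match reward.
#' @param mismatch negative integer mismatch penalty.
#' @param gap_per_position positive integer linear gap cost.
#' @param word_size exact-word seed length (>= 4).
#' @param max_evalue hits above this E-value are discarded.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_per_position = 2L,
                           word_size = 28L, max_evalue = 10) {
  stopifnot(match > 0, mismatch < 0, gap_per_position > 0, word_size >= 4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_per_position = as.integer(gap_per_position),
                 word_size = as.integer(word_size),
                 max_evalue = as.numeric(max_evalue)),
            class = "scoring_scheme")
}

#' Karlin-Altschul parameters for bit scores and E-values
#'
#' lambda is always computed from the scoring scheme by [solve_lambda()];
#' K defaults to 0.62. Bit-score and E-value *rankings* do not depend on
#' K, only their absolute magnitudes do.
#'
#' @param scoring a [scoring_scheme()].
#' @param k_const Karlin-Altschul K.
#' @param background per-base background probabilities (must sum to 1).
#' @return a `bit_score_params` list with elements `lambda`, `k_const`,
#'   `background`.
#' @export
bit_score_params <- function(scoring = scoring_scheme(), k_const = 0.62,
                             background = rep(0.25, 4)) {
  stopifnot(k_const > 0, abs(sum(background) - 1) < 1e-12, all(background > 0))
  structure(list(lambda = solve_lambda(scoring, background),
                 k_const = k_const, background = background),
            class = "bit_score_params")
}

#' Solve for the Karlin-Altschul lambda of an ungapped scoring scheme
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s(i,j)) = 1` by bisection to 1e-9. With a
#' match/mismatch scheme this reduces to
#' `pm * exp(lambda*match) + (1-pm) * exp(lambda*mismatch) = 1` where
#' `pm = sum(p^2)` is the background probability of an identical pair.
#' A positive root exists iff the expected score per aligned pair is
#' negative.
#'
#' @param scoring a [scoring_scheme()].
#' @param background per-base background probabilities.
#' @param tol bisection tolerance.
#' @return lambda (nats per score unit).
#' @export
solve_lambda <- function(scoring, background = rep(0.25, 4), tol = 1e-9) {
  pm <- sum(background^2)
  es <- pm * scoring$match + (1 - pm) * scoring$mismatch
  if (es >= 0)
    stop("expected score per aligned pair is non-negative (", es,
         "): no positive lambda exists")
  f <- function(l) pm * exp(l * scoring$match) +
    (1 - pm) * exp(l * scoring$mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- tol
  while (f(lo) > 0) lo <- lo / 2   # guard: f < 0 just right of 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Bit score from a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`; strictly monotone in the raw score.
#'
#' @param raw_score integer raw alignment score(s).
#' @param bitparams a [bit_score_params()].
#' @return bit score(s).
#' @export
bit_score <- function(raw_score, bitparams) {
  (bitparams$lambda * raw_score - log(bitparams$k_const)) / log(2)
}

#' E-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`, the expected number of chance hits
#' of score >= S between a query of length m and a database of total
#' length n. No effective-length edge correction is applied.
#'
#' @param raw_score integer raw alignment score(s).
#' @param query_len query length m.
#' @param subject_total_len summed database length n.
#' @param bitparams a [bit_score_params()].
#' @return E-value(s).
#' @export
evalue <- function(raw_score, query_len, subject_total_len, bitparams) {
  stopifnot(query_len > 0, subject_total_len > 0)
  bitparams$k_const * query_len * subject_total_len *
    exp(-bitparams$lambda * raw_score)
}

#' Global identity between two sequences
#'
#' Banded global alignment (linear gaps); identity is the number of
#' identical aligned positions divided by the length of the *shorter*
#' sequence — the CD-HIT-EST convention, under which a clean terminal
#' indel does not count against identity.
#'
#' @param seq_a,seq_b DNA strings.
#' @param scoring a [scoring_scheme()].
#' @param band band half-width; default `abs(len_a - len_b) + 32`, wide
#'   enough for intron length differences plus scattered indels.
#' @param denominator `"shorter"` (default) or `"alignment"` (identical
#'   positions over aligned columns).
#' @return list with `identity`, `matches`, `aligned_length`, `score`.
#' @export
global_identity <- function(seq_a, seq_b, scoring = scoring_scheme(),
                            band = NULL,
                            denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (is.null(band)) band <- abs(nchar(seq_a) - nchar(seq_b)) + 32L
  r <- .align_global_banded_cpp(seq_a, seq_b, scoring$match, scoring$mismatch,
                                scoring$gap_per_position, as.integer(band),
                                FALSE)
  den <- if (denominator == "shorter") min(nchar(seq_a), nchar(seq_b))
         else r$aligned_length
  list(identity = r$matches / den, matches = r$matches,
       aligned_length = r$aligned_length, score = r$score)
}

#' Global alignment returning the gapped sequence pair
#'
#' Used where downstream statistics (e.g. K2P with pairwise deletion)
#' need the aligned columns, not just the score.
#'
#' @inheritParams global_identity
#' @return list with `score`, `matches`, `aligned_length`, `alignment_a`,
#'   `alignment_b`.
#' @export
global_align <- function(seq_a, seq_b, scoring = scoring_scheme(),
                         band = NULL) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (is.null(band)) band <- abs(nchar(seq_a) - nchar(seq_b)) + 32L
  .align_global_banded_cpp(seq_a, seq_b, scoring$match, scoring$mismatch,
                           scoring$gap_per_position, as.integer(band), TRUE)
}

.seq_words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  unique(substring(s, 1:(n - w + 1L), w:n))
}

#' Word-seeded local database search
#'
#' Megablast-style search: only subjects sharing at least one exact word
#' of `word_size` letters with the query are aligned (full local DP with
#' linear gaps); hits with E-value above `max_evalue` are dropped; the
#' rest are sorted by descending bit score, ties broken by subject id.
#' Queries shorter than the word size fall back to aligning every
#' subject.
#'
#' @param query a single DNA string.
#' @param database named character vector of subject sequences.
#' @param scoring a [scoring_scheme()].
#' @param bitparams a [bit_score_params()].
#' @param query_id id recorded in the hit table.
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `raw_score`, `bit_score`, `evalue`, `identity`, `aligned_length`.
#'   Here `identity` is matches over aligned columns, so
#'   `identity * aligned_length` is the integer match count.
#' @export
seeded_local_search <- function(query, database, scoring = scoring_scheme(),
                                bitparams = bit_score_params(scoring),
                                query_id = "query") {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      raw_score = integer(), bit_score = numeric(),
                      evalue = numeric(), identity = numeric(),
                      aligned_length = integer(), stringsAsFactors = FALSE)
  if (!length(database)) return(empty)
  if (is.null(names(database)) || anyDuplicated(names(database)))
    stop("database must be a uniquely named character vector")
  if (!nzchar(query)) stop("empty query")
  w <- scoring$word_size
  if (nchar(query) >= w) {
    qwords <- .seq_words(query, w)
    keep <- vapply(database,
                   function(s) nchar(s) >= w &&
                     any(.seq_words(s, w) %in% qwords),
                   logical(1))
  } else {
    keep <- rep(TRUE, length(database))
  }
  cand <- database[keep]
  if (!length(cand)) return(empty)
  ntot <- sum(nchar(database))
  rows <- lapply(names(cand), function(sid) {
    r <- .align_local_cpp(query, cand[[sid]], scoring$match,
                          scoring$mismatch, scoring$gap_per_position, FALSE)
    data.frame(query_id = query_id, subject_id = sid, raw_score = r$score,
               bit_score = bit_score(r$score, bitparams),
               evalue = evalue(r$score, nchar(query), ntot, bitparams),
               identity = if (r$aligned_length) r$matches / r$aligned_length
                          else 0,
               aligned_length = r$aligned_length, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= scoring$max_evalue, , drop = FALSE]
  hits <- hits[order(-hits$bit_score, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a hit table as TSV
#'
#' Fixed column order: query_id, subject_id, raw_score, bit_score,
#' evalue, identity, aligned_length.
#'
#' @param hits hit `data.frame` from [seeded_local_search()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  cols <- c("query_id", "subject_id", "raw_score", "bit_score", "evalue",
            "identity", "aligned_length")
  utils::write.table(hits[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
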