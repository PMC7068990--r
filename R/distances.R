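.BASE_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# Map a character vector of aligned residues to integer codes;
# gaps and IUPAC ambiguity codes become NA (treated as missing).
.encode_residues <- function(x) {
  codes <- .BASE_CODES[x]
  unname(codes)
}

.encode_seq <- function(s) .encode_residues(strsplit(toupper(s), "")[[1]])

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites with a gap or ambiguity code in either sequence are excluded
#' (pairwise deletion). With transition proportion P and transversion
#' proportion Q over the remaining sites,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param seq_a,seq_b aligned sequences (equal length, `-` for gaps).
#' @return list with `d`, `P`, `Q`, `n_sites`.
#' @export
k2p <- function(seq_a, seq_b) {
  a <- .encode_seq(seq_a)
  b <- .encode_seq(seq_b)
  if (length(a) != length(b))
    stop("aligned sequences differ in length: ", length(a), " vs ", length(b))
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  if (n == 0L) stop("no comparable sites (all gapped or ambiguous)")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  s <- a + b
  ts <- sum(diff & (s == 2L | s == 4L))   # A<->G or C<->T
  tv <- sum(diff) - ts
  .k2p_from_counts(ts / n, tv / n, n)
}

.k2p_from_counts <- function(P, Q, n) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturated): P=", signif(P, 4),
         " Q=", signif(Q, 4))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d + 0 * (d == 0), P = P, Q = Q, n_sites = n)
}

#' Alignment column statistics: variable and parsimony-informative sites
#'
#' A column is *variable* when at least two distinct unambiguous bases
#' occur; *parsimony-informative* when at least two bases each occur in
#' at least two rows. Under the default gap policy, gaps and ambiguity
#' codes are excluded from the state counts; under `"fifth_state"` the
#' gap character is counted as an additional state (ambiguities are
#' always excluded).
#'
#' @param msa alignment from [as_msa()] (or aligned character vector).
#' @param gap_policy `"exclude"` (default) or `"fifth_state"`.
#' @return list with `aln_length`, `variable`, `informative`.
#' @export
site_stats <- function(msa, gap_policy = c("exclude", "fifth_state")) {
  gap_policy <- match.arg(gap_policy)
  m <- as_msa(msa)
  states <- names(.BASE_CODES)
  if (gap_policy == "fifth_state") states <- c(states, "-")
  variable <- 0L
  informative <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(factor(m[, j], levels = states))
    tab <- tab[tab > 0L]
    if (length(tab) >= 2L) {
      variable <- variable + 1L
      if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  list(aln_length = ncol(m), variable = variable, informative = informative)
}

#' Pairwise K2P distance matrix over an alignment
#'
#' Saturated pairs (where the K2P logs are undefined) and pairs with no
#' comparable sites are masked as `NA` rather than raising an error, so
#' the matrix stays usable with explicit masking.
#'
#' @param msa alignment from [as_msa()] (or aligned character vector).
#' @return symmetric numeric matrix with zero diagonal, `NA` for masked
#'   pairs, and row/column names from the alignment.
#' @export
distance_matrix <- function(msa) {
  m <- as_msa(msa)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  codes <- matrix(.encode_residues(m), nrow(m), ncol(m))
  codes[is.na(codes)] <- -1L
  cnt <- .k2p_counts_cpp(codes)
  n <- nrow(m)
  P <- cnt$transitions / cnt$n_sites
  Q <- cnt$transversions / cnt$n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  bad <- cnt$n_sites == 0L | w1 <= 0 | w2 <= 0    # saturated or empty
  w1[bad] <- NA_real_
  w2[bad] <- NA_real_
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  d[d == 0] <- 0                      # avoid IEEE negative zero
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d distance matrix (masked entries are written as -1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    vals <- ifelse(is.na(d[i, ]), -1, d[i, ])
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", vals), collapse = " ")), con)
  }
  invisible(path)
}

#' Write a distance matrix as long-format TSV
#'
#' One row per unordered pair: `id_a`, `id_b`, `distance` (`NA` when
#' masked).
#'
#' @param d distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(d, path) {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(id_a = rownames(d)[idx[, 1]],
                    id_b = colnames(d)[idx[, 2]],
                    distance = d[idx], stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
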