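#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined. Ties
#' are broken by the lexicographically smallest pair of node ids (an
#' internal node is identified by the smallest leaf label under it), so
#' the result is deterministic and independent of input order. Additive
#' matrices are reconstructed exactly; negative branch lengths are
#' clamped to zero and flagged via the `"clamped"` attribute.
#'
#' @param d complete symmetric distance matrix, n >= 3, no `NA`.
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (anyNA(d))
    stop("distance matrix has masked entries; impute or drop those taxa")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nwk <- labels          # growing newick fragment per active node
  key <- labels          # smallest leaf label under each active node
  D <- unname(d)
  clamped <- 0L
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  while (nrow(D) > 2L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- paste(pmin(key[cand[, 1]], key[cand[, 2]]),
                pmax(key[cand[, 1]], key[cand[, 2]]), sep = "\r")
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; lj <- lj + li; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; li <- li + lj; lj <- 0 }
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newnwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    newkey <- min(key[i], key[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], newnwk)
    key <- c(key[keep], newkey)
  }
  # final edge between the last two nodes; emit the standard unrooted
  # (trifurcating) form by splicing one internal node open
  dfin <- max(D[1, 2], 0)
  if (D[1, 2] < 0) clamped <- clamped + 1L
  int <- which(startsWith(nwk, "("))
  if (length(int)) {
    a <- int[1]; b <- setdiff(1:2, a)
    inner <- substr(nwk[a], 2L, nchar(nwk[a]) - 1L)
    text <- sprintf("(%s,%s:%s);", inner, nwk[b], fmt(dfin))
  } else {
    text <- sprintf("(%s:%s,%s:0);", nwk[1], fmt(dfin), nwk[2])
  }
  tree <- ape::read.tree(text = text)
  attr(tree, "clamped") <- clamped
  tree
}

# Bipartitions of an unrooted tree as canonical strings: for each
# internal edge, the side not containing the reference (first) leaf,
# sorted and joined.
.bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  desc <- .tips_under(tree)
  parts <- character(0)
  for (node in seq_along(desc)) {
    tips <- desc[[node]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    parts <- c(parts, paste(sort(side), collapse = "\r"))
  }
  unique(parts)
}

# tip labels under each internal node (indexed n+1 .. n+Nnode); relies on
# ape's cladewise edge order (parents precede children), so a single
# reverse pass accumulates children before their parents are consumed.
.tips_under <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  n <- length(tree$tip.label)
  out <- vector("list", tree$Nnode)
  for (k in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[k, 1] - n
    child <- tree$edge[k, 2]
    add <- if (child <= n) tree$tip.label[child] else out[[child - n]]
    out[[parent]] <- c(out[[parent]], add)
  }
  out
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the K2P
#' distance matrix and NJ tree per replicate, and reports for each
#' internal edge of the original tree the percentage of successful
#' replicates containing the same bipartition. Replicates whose
#' resampled matrix has masked (saturated or empty) pairs are skipped
#' and counted.
#'
#' @param msa alignment from [as_msa()] with >= 4 rows.
#' @param n_replicates bootstrap replicates (1000 in typical use;
#'   reduce for quick checks).
#' @param seed RNG seed for reproducibility.
#' @return the original NJ [ape::phylo] with `node.label` carrying
#'   bootstrap percentages; attributes `n_effective` (replicates used)
#'   and `n_skipped`.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L) {
  m <- as_msa(msa)
  if (nrow(m) < 4L) stop("need >= 4 sequences for bootstrap")
  stopifnot(n_replicates >= 1L)
  d0 <- distance_matrix(m)
  if (anyNA(d0)) stop("original matrix has masked entries")
  tree <- neighbor_joining(d0)
  target <- .bipartitions(tree)
  counts <- stats::setNames(numeric(length(target)), target)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  used <- 0L; skipped <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    db <- tryCatch(distance_matrix(m[, cols, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(db) || anyNA(db)) { skipped <- skipped + 1L; next }
    tb <- neighbor_joining(db)
    used <- used + 1L
    hit <- target %in% .bipartitions(tb)
    counts[hit] <- counts[hit] + 1
  }
  if (skipped) warning(skipped, " bootstrap replicate(s) skipped (saturation)")
  support <- if (used) round(100 * counts / used, 1) else counts * NA
  # map supports onto internal nodes
  n <- length(tree$tip.label)
  desc <- .tips_under(tree)
  ref <- sort(tree$tip.label)[1]
  labs <- vapply(seq_len(tree$Nnode), function(k) {
    tips <- desc[[k]]
    if (length(tips) <= 1L || length(tips) >= n - 1L) return("")
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "\r")
    if (key %in% names(support)) as.character(support[[key]]) else ""
  }, character(1))
  tree$node.label <- labs
  attr(tree, "n_effective") <- used
  attr(tree, "n_skipped") <- skipped
  tree
}

#' Assign alleles to parental genepools
#'
#' Each allele is globally aligned (exon+intron, gaps excluded pairwise)
#' against every reference in every declared genepool and assigned to
#' the pool containing its minimum-K2P reference. The margin is the
#' distance to the nearest other pool minus the distance to the assigned
#' pool; exact ties go to the lexicographically first pool with margin 0
#' and a tie flag. An individual whose alleles land in two or more
#' distinct pools is flagged `putative_hybrid`.
#'
#' @param alleles `data.frame` with columns `allele_id`, `individual_id`,
#'   `sequence`.
#' @param genepools named list of named character vectors (pool ->
#'   reference sequences).
#' @param scoring a [scoring_scheme()] for the alignments.
#' @return `data.frame`: `allele_id`, `individual_id`, `genepool`,
#'   `margin`, `identical`, `tie`, `putative_hybrid` (`genepool` is `NA`
#'   when the allele is saturated against every reference).
#' @export
assign_alleles <- function(alleles, genepools, scoring = scoring_scheme()) {
  stopifnot(all(c("allele_id", "individual_id", "sequence") %in%
                  names(alleles)),
            length(genepools) >= 2L, !is.null(names(genepools)))
  pools <- sort(names(genepools))
  rows <- lapply(seq_len(nrow(alleles)), function(k) {
    dmin <- vapply(pools, function(p) {
      ds <- vapply(genepools[[p]], function(ref) {
        al <- global_align(alleles$sequence[k], ref, scoring)
        tryCatch(k2p(al$alignment_a, al$alignment_b)$d,
                 error = function(e) NA_real_)
      }, numeric(1))
      if (all(is.na(ds))) NA_real_ else min(ds, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(dmin)))
      return(data.frame(allele_id = alleles$allele_id[k],
                        individual_id = alleles$individual_id[k],
                        genepool = NA_character_, margin = NA_real_,
                        identical = FALSE, tie = FALSE,
                        stringsAsFactors = FALSE))
    best <- min(dmin, na.rm = TRUE)
    at_best <- pools[!is.na(dmin) & dmin <= best + 1e-12]
    others <- dmin[!pools %in% at_best]
    margin <- if (length(at_best) > 1L) 0
      else if (all(is.na(others))) NA_real_
      else min(others, na.rm = TRUE) - best
    data.frame(allele_id = alleles$allele_id[k],
               individual_id = alleles$individual_id[k],
               genepool = at_best[1], margin = margin,
               identical = best == 0, tie = length(at_best) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  hyb <- tapply(out$genepool, out$individual_id,
                function(g) length(unique(g[!is.na(g)])) >= 2L)
  out$putative_hybrid <- as.vector(hyb[out$individual_id])
  out
}

#' Write allele assignments as TSV
#'
#' @param assignments `data.frame` from [assign_alleles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
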