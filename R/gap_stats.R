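#' Classify every unordered pair of a distance matrix by taxonomic level
#'
#' Levels: `intraspecific` (same species), `congeneric` (same species
#' group, different species), `intergeneric` (same subfamily, different
#' species group), `interfamilial` (different subfamilies). Masked (`NA`)
#' distances are dropped. The classes are disjoint and cover all
#' unmasked off-diagonal pairs.
#'
#' @param d distance matrix with record ids as dimnames.
#' @param records marker record `data.frame` mapping ids to species,
#'   species_group and subfamily.
#' @return long `data.frame`: `id_a`, `id_b`, `distance`, `level`.
#' @export
classify_pairs <- function(d, records) {
  ids <- rownames(d)
  ri <- match(ids, records$id)
  if (anyNA(ri)) stop("matrix ids missing from records: ",
                      paste(ids[is.na(ri)], collapse = ", "))
  sp <- records$species[ri]
  grp <- records$species_group[ri]
  sf <- records$subfamily[ri]
  idx <- which(upper.tri(d), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same_grp <- !is.na(grp[i]) & !is.na(grp[j]) & grp[i] == grp[j]
  same_sf <- !is.na(sf[i]) & !is.na(sf[j]) & sf[i] == sf[j]
  level <- ifelse(sp[i] == sp[j], "intraspecific",
           ifelse(same_grp, "congeneric",
           ifelse(same_sf, "intergeneric", "interfamilial")))
  out <- data.frame(id_a = ids[i], id_b = ids[j], distance = d[idx],
                    level = level, stringsAsFactors = FALSE)
  out[!is.na(out$distance), , drop = FALSE]
}

#' Partition distances into intra- and interspecific sets
#'
#' `intra` is always the intraspecific distances; `inter` is the set at
#' the requested level (`"interspecific"` pools every different-species
#' pair; the other levels select one stratum).
#'
#' @param d distance matrix.
#' @param records marker record `data.frame`.
#' @param level one of `"interspecific"`, `"congeneric"`,
#'   `"intergeneric"`, `"interfamilial"`.
#' @return list with numeric vectors `intra` and `inter`.
#' @export
partition_distances <- function(d, records,
                                level = c("interspecific", "congeneric",
                                          "intergeneric", "interfamilial")) {
  level <- match.arg(level)
  pairs <- classify_pairs(d, records)
  intra <- pairs$distance[pairs$level == "intraspecific"]
  inter <- if (level == "interspecific")
    pairs$distance[pairs$level != "intraspecific"]
  else pairs$distance[pairs$level == level]
  list(intra = intra, inter = inter)
}

#' Wilcoxon rank-sum test (exact or tie-corrected normal approximation)
#'
#' W is the rank sum of `sample_a` in the pooled data, with midranks for
#' ties. When the smaller sample has at most `exact_max` observations and
#' there are no ties, the two-sided p-value is computed exactly by full
#' enumeration of the rank assignments; otherwise by normal approximation
#' with tie-corrected variance and continuity correction. When every
#' pooled value is identical, p = 1 by convention.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param exact_max largest min-sample size for which enumeration is used.
#' @return list with `w_stat`, `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b, exact_max = 8L) {
  na <- length(sample_a); nb <- length(sample_b)
  if (!na || !nb) stop("both samples must be non-empty")
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                       # midranks for ties
  w <- sum(r[seq_len(na)])
  n <- na + nb
  mu <- na * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L)
    return(list(w_stat = w, p_value = 1, method = "degenerate"))
  if (min(na, nb) <= exact_max && !ties && choose(n, na) <= 5e5) {
    combos <- utils::combn(n, na)
    wdist <- colSums(matrix(seq_len(n)[combos], nrow = na))
    p <- mean(abs(wdist - mu) >= abs(w - mu) - 1e-9)
    return(list(w_stat = w, p_value = p, method = "exact"))
  }
  tvals <- table(pooled)
  tie_term <- sum(tvals^3 - tvals) / (n * (n - 1))
  v <- na * nb / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(w_stat = w, p_value = 1, method = "degenerate"))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)   # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(w_stat = w, p_value = p, method = "normal")
}

#' Barcoding-gap report
#'
#' Assembles the intra- vs interspecific K2P distance distributions, an
#' overlap flag (`max(intra) >= min(inter)` — a true barcoding gap means
#' no overlap), the Wilcoxon rank-sum comparison, and per-level summary
#' quantiles.
#'
#' @param d distance matrix.
#' @param records marker record `data.frame`.
#' @return a `gap_report` list: `intra`, `inter`, `n_intra`, `n_inter`,
#'   `overlap`, `overlap_interval`, `w_stat`, `p_value`, `by_level`.
#' @export
gap_report <- function(d, records) {
  parts <- partition_distances(d, records, "interspecific")
  intra <- parts$intra; inter <- parts$inter
  overlap <- NA
  interval <- c(NA_real_, NA_real_)
  if (length(intra) && length(inter)) {
    overlap <- max(intra) >= min(inter)
    if (isTRUE(overlap)) interval <- c(min(inter), max(intra))
  }
  w_stat <- NA_real_; p_value <- NA_real_
  if (length(intra) >= 2L && length(inter) >= 2L) {
    wt <- wilcoxon_rank_sum(intra, inter)
    w_stat <- wt$w_stat; p_value <- wt$p_value
  } else {
    warning("fewer than 2 distances in a class; Wilcoxon p-value unset")
  }
  pairs <- classify_pairs(d, records)
  by_level <- do.call(rbind, lapply(split(pairs$distance, pairs$level),
    function(x) data.frame(n = length(x), median = stats::median(x),
                           q25 = unname(stats::quantile(x, 0.25)),
                           q75 = unname(stats::quantile(x, 0.75)))))
  by_level <- cbind(level = rownames(by_level), by_level)
  rownames(by_level) <- NULL
  structure(list(intra = intra, inter = inter, n_intra = length(intra),
                 n_inter = length(inter), overlap = overlap,
                 overlap_interval = interval, w_stat = w_stat,
                 p_value = p_value, by_level = by_level),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Barcoding-gap report\n")
  cat(sprintf("  intraspecific: n=%d median=%.4g\n", x$n_intra,
              stats::median(x$intra)))
  cat(sprintf("  interspecific: n=%d median=%.4g\n", x$n_inter,
              stats::median(x$inter)))
  cat("  overlap:", if (isTRUE(x$overlap)) "yes (no barcoding gap)"
      else if (isFALSE(x$overlap)) "no (gap present)" else "undetermined",
      "\n")
  if (!is.na(x$p_value))
    cat(sprintf("  Wilcoxon rank-sum: W=%g, two-sided p=%.3g\n",
                x$w_stat, x$p_value))
  invisible(x)
}

#' Write a gap report as JSON
#'
#' @param report a [gap_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gap_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "columns")
  invisible(path)
}
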