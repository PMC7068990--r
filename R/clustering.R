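#' Greedy incremental identity clustering
#'
#' CD-HIT-EST-style longest-first clustering: sequences are sorted by
#' decreasing length (ties by id), the first seeds cluster 1, and each
#' subsequent sequence joins the *first* existing representative with
#' [global_identity()] at or above `threshold`, otherwise it seeds a new
#' cluster. Deterministic and independent of input order.
#'
#' @param records marker record `data.frame`, or a named character vector
#'   of sequences.
#' @param threshold identity threshold in (0, 1]; default 0.98, the
#'   cut-off at which barcode clusters track accepted taxonomic groups.
#' @param scoring a [scoring_scheme()] for the identity alignments.
#' @return a `cluster_set`: list with `clusters` (`data.frame` of
#'   `cluster_id`, `id`, `is_representative`, `identity_to_rep`) and
#'   `threshold`.
#' @export
greedy_cluster <- function(records, threshold = 0.98,
                           scoring = scoring_scheme()) {
  seqs <- .as_named_seqs(records)
  if (!length(seqs)) stop("no sequences to cluster")
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  rep_ids <- character(0)
  assign_cluster <- integer(length(seqs))
  ident <- numeric(length(seqs))
  for (k in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(rep_ids)) {
      gi <- global_identity(seqs[[k]], seqs[[rep_ids[ci]]], scoring)
      if (gi$identity >= threshold) {
        assign_cluster[k] <- ci
        ident[k] <- gi$identity
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, names(seqs)[k])
      assign_cluster[k] <- length(rep_ids)
      ident[k] <- 1
    }
  }
  clusters <- data.frame(cluster_id = assign_cluster, id = names(seqs),
                         is_representative = names(seqs) %in% rep_ids &
                           !duplicated(assign_cluster),
                         identity_to_rep = ident, stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster_id, -clusters$is_representative,
                             clusters$id), ]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, threshold = threshold),
            class = "cluster_set")
}

.as_named_seqs <- function(records) {
  if (is.data.frame(records)) {
    validate_records(records)
    stats::setNames(records$sequence, records$id)
  } else {
    if (length(records) && is.null(names(records)))
      stop("sequences must be named")
    records
  }
}

#' @export
print.cluster_set <- function(x, ...) {
  n <- nrow(x$clusters)
  k <- max(x$clusters$cluster_id)
  cat("Greedy identity clustering: ", n, " sequences in ", k,
      " clusters (threshold ", x$threshold, ")\n", sep = "")
  sizes <- table(x$clusters$cluster_id)
  cat("cluster sizes: ", paste(sort(as.integer(sizes), decreasing = TRUE),
                               collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Label clusters by taxonomic concordance
#'
#' Each cluster is labeled `species_cluster` (all members one species),
#' `supported` (members span several species but all share a species
#' group, or failing that a genus), `unsupported` (mixed groups), or
#' `unknown` (a member species missing from the taxonomy). Counts are
#' aggregated per subfamily.
#'
#' @param cluster_set result of [greedy_cluster()].
#' @param records marker record `data.frame` mapping ids to species.
#' @param taxonomy taxonomy `data.frame` as from [read_taxonomy()].
#' @return list with `labels` (`data.frame`: cluster_id, subfamily,
#'   n_members, n_species, label) and `by_subfamily` (`data.frame`:
#'   subfamily, n_sequences, n_species, n_clusters, supported,
#'   unsupported, species_clusters).
#' @export
cluster_purity <- function(cluster_set, records, taxonomy) {
  cl <- cluster_set$clusters
  sp <- stats::setNames(records$species, records$id)
  labs <- lapply(split(cl$id, cl$cluster_id), function(ids) {
    species <- unique(sp[ids])
    tax <- taxonomy[match(species, taxonomy$species), , drop = FALSE]
    subfam <- unique(tax$subfamily[!is.na(tax$subfamily)])
    subfam <- if (length(subfam)) paste(sort(subfam), collapse = "+") else NA
    if (anyNA(tax$species)) {
      label <- "unknown"
    } else if (length(species) == 1L) {
      label <- "species_cluster"
    } else {
      grp <- tax$species_group
      gen <- tax$genus
      one_group <- !anyNA(grp) && length(unique(grp)) == 1L
      one_genus <- !anyNA(gen) && length(unique(gen)) == 1L
      label <- if (one_group || one_genus) "supported" else "unsupported"
    }
    data.frame(subfamily = subfam, n_members = length(ids),
               n_species = length(species), label = label,
               stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, labs)
  labels <- cbind(cluster_id = as.integer(names(labs)), labels)
  rownames(labels) <- NULL
  missing_sp <- setdiff(unique(sp[cl$id]), taxonomy$species)
  by_sf <- do.call(rbind, lapply(split(labels, labels$subfamily), function(g) {
    ids <- cl$id[cl$cluster_id %in% g$cluster_id]
    data.frame(subfamily = g$subfamily[1],
               n_sequences = length(ids),
               n_species = length(unique(sp[ids])),
               n_clusters = nrow(g),
               supported = sum(g$label %in% c("supported", "species_cluster")),
               unsupported = sum(g$label == "unsupported"),
               species_clusters = sum(g$label == "species_cluster"),
               stringsAsFactors = FALSE)
  }))
  rownames(by_sf) <- NULL
  list(labels = labels, by_subfamily = by_sf, missing_species = missing_sp)
}

#' Write clusters in CD-HIT ".clstr"-style text format
#'
#' @param cluster_set result of [greedy_cluster()].
#' @param records marker record `data.frame` (for sequence lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(cluster_set, records, path) {
  seqs <- .as_named_seqs(records)
  cl <- cluster_set$clusters
  con <- file(path, "w")
  on.exit(close(con))
  for (ci in unique(cl$cluster_id)) {
    writeLines(sprintf(">Cluster %d", ci - 1L), con)
    g <- cl[cl$cluster_id == ci, ]
    for (k in seq_len(nrow(g))) {
      tail <- if (g$is_representative[k]) "*"
              else sprintf("at +/%.2f%%", 100 * g$identity_to_rep[k])
      writeLines(sprintf("%d\t%dnt, >%s... %s", k - 1L,
                         nchar(seqs[[g$id[k]]]), g$id[k], tail), con)
    }
  }
  invisible(path)
}

#' Write clusters as TSV
#'
#' @param cluster_set result of [greedy_cluster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(cluster_set, path) {
  utils::write.table(cluster_set$clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
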