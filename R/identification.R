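#' Build a barcode reference database
#'
#' Applies [split_regions()] and assembles the searchable sequences:
#' mode `"exon"` keeps the slow exon only (at most 264 bp), mode
#' `"exon_intron"` concatenates exon and intron (the short terminal exon
#' remnant is always cut off).
#'
#' @param records marker record `data.frame` with boundaries set (or a
#'   `reference_exon` for the alignment fallback).
#' @param mode `"exon_intron"` (default) or `"exon"`.
#' @param reference_exon optional boundary-location fallback, see
#'   [split_regions()].
#' @return a `reference_db`: list with `sequences` (named character),
#'   `records`, `mode`.
#' @export
build_reference_db <- function(records, mode = c("exon_intron", "exon"),
                               reference_exon = NULL) {
  mode <- match.arg(mode)
  parts <- split_regions(records, reference_exon = reference_exon)
  seqs <- if (mode == "exon") parts$exon
          else paste0(parts$exon, parts$intron)
  if (any(!nzchar(seqs)))
    stop("empty database sequence(s): ",
         paste(parts$id[!nzchar(seqs)], collapse = ", "))
  structure(list(sequences = stats::setNames(seqs, parts$id),
                 records = records, mode = mode),
            class = "reference_db")
}

#' Select one query per multi-provenance species
#'
#' Identification trials hold out one accession per species, restricted
#' to species sampled from at least two distinct provenances (so a
#' conspecific from another source remains in the database). The
#' designated query is the record with the lexicographically smallest id.
#'
#' @param records marker record `data.frame` with `provenance` set.
#' @return the query rows of `records` (possibly zero rows).
#' @export
select_queries <- function(records) {
  validate_records(records)
  nprov <- tapply(records$provenance, records$species,
                  function(p) length(unique(p[!is.na(p)])))
  eligible <- names(nprov)[nprov >= 2L]
  pick <- vapply(eligible, function(s) {
    ids <- records$id[records$species == s]
    sort(ids)[1]
  }, character(1))
  out <- records[records$id %in% pick, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

#' Identify one query against a reference database
#'
#' Runs [seeded_local_search()] with the query's own record removed
#' (self-hit exclusion by id). Let B be the maximum bit score among the
#' hits; the *top species set* is the species of all hits whose raw
#' score ties the best (with fixed lambda and K, bit-score ties are
#' exactly raw-score ties). Outcome:
#' `correct` when the top set is exactly the query species; `ambiguous`
#' when the query species is in a top set of several species;
#' `no_hit` when no hit survives the seed and E-value filters;
#' `incorrect` otherwise. `group_correct` records whether the single
#' best-sorted hit shares the query's species group.
#'
#' @param query one marker record row (also used for its id and species).
#' @param db a [build_reference_db()] result.
#' @param scoring,bitparams alignment scoring and Karlin-Altschul
#'   parameters.
#' @return list with `query_id`, `query_species`, `outcome`,
#'   `top_species`, `top_bit_score`, `group_correct`, `conspecific_in_db`,
#'   `hits`.
#' @export
identify <- function(query, db, scoring = scoring_scheme(),
                     bitparams = bit_score_params(scoring)) {
  stopifnot(inherits(db, "reference_db"), nrow(query) == 1L)
  seqs <- db$sequences[setdiff(names(db$sequences), query$id)]
  qparts <- split_regions(query)
  qseq <- if (db$mode == "exon") qparts$exon
          else paste0(qparts$exon, qparts$intron)
  hits <- seeded_local_search(qseq, seqs, scoring, bitparams,
                              query_id = query$id)
  species_of <- stats::setNames(db$records$species, db$records$id)
  group_of <- stats::setNames(db$records$species_group, db$records$id)
  conspecific <- query$species %in% species_of[names(seqs)]
  if (!nrow(hits)) {
    return(list(query_id = query$id, query_species = query$species,
                outcome = "no_hit", top_species = character(0),
                top_bit_score = NA_real_, group_correct = FALSE,
                conspecific_in_db = conspecific, hits = hits))
  }
  hits$species <- unname(species_of[hits$subject_id])
  top <- hits[hits$raw_score == max(hits$raw_score), , drop = FALSE]
  top_species <- sort(unique(top$species))
  outcome <- if (identical(top_species, query$species)) "correct"
    else if (query$species %in% top_species) "ambiguous"
    else "incorrect"
  best_grp <- group_of[hits$subject_id[1]]
  group_correct <- !is.na(best_grp) && !is.na(query$species_group) &&
    best_grp == query$species_group
  list(query_id = query$id, query_species = query$species,
       outcome = outcome, top_species = top_species,
       top_bit_score = hits$bit_score[1], group_correct = group_correct,
       conspecific_in_db = conspecific, hits = hits)
}

#' Identify a set of queries
#'
#' @param queries marker record rows (e.g. from [select_queries()]).
#' @param db a [build_reference_db()] result.
#' @param scoring,bitparams see [identify()].
#' @return `data.frame` with one row per query: `query_id`, `species`,
#'   `outcome`, `top_bit_score`, `top_species` (semicolon-joined),
#'   `group_correct`, `conspecific_in_db`, plus attribute `"details"`
#'   holding the full per-query results.
#' @export
identify_all <- function(queries, db, scoring = scoring_scheme(),
                         bitparams = bit_score_params(scoring)) {
  res <- lapply(seq_len(nrow(queries)),
                function(k) identify(queries[k, , drop = FALSE], db,
                                     scoring, bitparams))
  out <- data.frame(
    query_id = vapply(res, `[[`, character(1), "query_id"),
    species = vapply(res, `[[`, character(1), "query_species"),
    outcome = vapply(res, `[[`, character(1), "outcome"),
    top_bit_score = vapply(res, `[[`, numeric(1), "top_bit_score"),
    top_species = vapply(res, function(r)
      paste(r$top_species, collapse = ";"), character(1)),
    group_correct = vapply(res, `[[`, logical(1), "group_correct"),
    conspecific_in_db = vapply(res, `[[`, logical(1), "conspecific_in_db"),
    stringsAsFactors = FALSE)
  attr(out, "details") <- res
  out
}

#' Identification success summary
#'
#' Aggregates outcome counts the way barcoding trials report them: number
#' of species tested, ambiguous, and correctly identified, at species
#' level and (when requested) at genus/clade level via `group_correct`.
#'
#' @param results `data.frame` from [identify_all()].
#' @param marker label for the marker/mode row.
#' @return `data.frame` with rows per taxon level.
#' @export
success_table <- function(results, marker = "marker") {
  if (!nrow(results)) stop("no identification results to summarize")
  data.frame(
    marker = marker,
    level = c("species", "genus_clade"),
    n_tested = nrow(results),
    ambiguous = c(sum(results$outcome == "ambiguous"), NA_integer_),
    correct = c(sum(results$outcome == "correct"),
                sum(results$group_correct)),
    stringsAsFactors = FALSE)
}

#' Write identification results as TSV
#'
#' @param results `data.frame` from [identify_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_identification_tsv <- function(results, path) {
  cols <- c("query_id", "species", "outcome", "top_bit_score",
            "top_species", "group_correct")
  utils::write.table(results[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
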