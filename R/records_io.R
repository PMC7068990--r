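#' Marker record tables
#'
#' A marker record set is a plain `data.frame` with one row per sequence
#' (or per cloned allele) and the columns `id`, `species`, `genus`,
#' `subfamily`, `species_group`, `provenance`, `allele_id`, `sequence`,
#' `exon_end`, `intron_end`. Coordinates are 0-based half-open:
#' `exon_end` marks the exon/intron boundary and `intron_end` the
#' intron/terminal-exon-remnant boundary, so the exon occupies
#' `[0, exon_end)`, the intron `[exon_end, intron_end)` and the short
#' terminal exon remnant `[intron_end, length)`.
#'
#' @param id character vector of unique record ids.
#' @param sequence DNA sequences (A, C, G, T, N and IUPAC ambiguity codes;
#'   lower case is folded to upper).
#' @param species,genus,subfamily,species_group,provenance,allele_id
#'   taxonomy and provenance metadata; `species_group` and `allele_id`
#'   may be `NA`.
#' @param exon_end,intron_end optional 0-based half-open region boundaries.
#' @return a validated marker record `data.frame`.
#' @export
marker_records <- function(id, sequence, species = NA_character_,
                           genus = NA_character_, subfamily = NA_character_,
                           species_group = NA_character_,
                           provenance = NA_character_,
                           allele_id = NA_character_,
                           exon_end = NA_integer_, intron_end = NA_integer_) {
  df <- data.frame(id = as.character(id),
                   species = as.character(species),
                   genus = as.character(genus),
                   subfamily = as.character(subfamily),
                   species_group = as.character(species_group),
                   provenance = as.character(provenance),
                   allele_id = as.character(allele_id),
                   sequence = toupper(as.character(sequence)),
                   exon_end = as.integer(exon_end),
                   intron_end = as.integer(intron_end),
                   stringsAsFactors = FALSE)
  validate_records(df)
}

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")

#' Validate a marker record table
#'
#' Checks id uniqueness, non-empty upper-case sequences over the IUPAC
#' alphabet, and boundary sanity (`0 <= exon_end <= intron_end <= length`
#' where set).
#'
#' @param records a marker record `data.frame`.
#' @return `records`, invisibly unchanged, or an error.
#' @export
validate_records <- function(records) {
  needed <- c("id", "species", "sequence")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("record table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$id))
    stop("duplicate record ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  if (any(!nzchar(records$sequence)))
    stop("empty sequence for record(s): ",
         paste(records$id[!nzchar(records$sequence)], collapse = ", "))
  bad <- grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"),
               records$sequence)
  if (any(bad))
    stop("non-IUPAC characters in sequence(s): ",
         paste(records$id[bad], collapse = ", "))
  if (!is.null(records$exon_end)) {
    len <- nchar(records$sequence)
    ee <- records$exon_end
    ie <- records$intron_end
    ok <- is.na(ee) | (ee >= 0 & (is.na(ie) | (ee <= ie & ie <= len)))
    if (any(!ok))
      stop("inconsistent region boundaries for record(s): ",
           paste(records$id[!ok], collapse = ", "))
  }
  records
}

#' Read marker sequences from FASTA with structured headers
#'
#' Header lines carry metadata fields separated by `sep` (default
#' `id|species|genus|subfamily|species_group|provenance`). Wrapped
#' sequence lines and CRLF line endings are handled; sequences are folded
#' to upper case. A header with the wrong number of fields is reported
#' with its line number; duplicate ids are an error.
#'
#' @param path path to a FASTA file.
#' @param fields header field names, in order. Must include `"id"`;
#'   any of the marker record metadata columns may appear.
#' @param sep single-character field delimiter.
#' @return a marker record `data.frame` (boundary columns `NA`).
#' @export
read_fasta <- function(path,
                       fields = c("id", "species", "genus", "subfamily",
                                  "species_group", "provenance"),
                       sep = "|") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!"id" %in% fields) stop("header schema must include an 'id' field")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  hdr_at <- which(startsWith(lines, ">"))
  if (!length(hdr_at)) stop("no FASTA entries in ", path)
  n <- length(hdr_at)
  ends <- c(hdr_at[-1] - 1L, length(lines))
  meta <- matrix(NA_character_, n, length(fields),
                 dimnames = list(NULL, fields))
  seqs <- character(n)
  for (k in seq_len(n)) {
    parts <- strsplit(sub("^>", "", lines[hdr_at[k]]), sep, fixed = TRUE)[[1]]
    if (length(parts) != length(fields))
      stop("malformed header at line ", hdr_at[k], ": expected ",
           length(fields), " '", sep, "'-separated fields, got ",
           length(parts))
    meta[k, ] <- parts
    if (ends[k] >= hdr_at[k] + 1L)
      seqs[k] <- paste(lines[(hdr_at[k] + 1L):ends[k]], collapse = "")
  }
  seqs <- toupper(gsub("[ \t]", "", seqs))
  args <- c(list(id = meta[, "id"], sequence = seqs),
            lapply(setdiff(fields, "id"), function(f) meta[, f]))
  names(args)[-(1:2)] <- setdiff(fields, "id")
  do.call(marker_records, args)
}

#' Write marker records to FASTA with structured headers
#'
#' @param records marker record `data.frame`.
#' @param path output path.
#' @param fields,sep header schema as in [read_fasta()].
#' @param width sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path,
                        fields = c("id", "species", "genus", "subfamily",
                                   "species_group", "provenance"),
                        sep = "|", width = 70L) {
  validate_records(records)
  hdr <- apply(as.matrix(records[fields]), 1L,
               function(r) paste(ifelse(is.na(r), "", r), collapse = sep))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    writeLines(paste0(">", hdr[k]), con)
    s <- records$sequence[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Split a barcode sequence into exon and intron parts
#'
#' Uses the stored 0-based half-open boundaries. The exon part is trimmed
#' to at most `exon_max` bases from the 5' end; the intron part runs from
#' the exon/intron boundary to the intron end, excluding the short
#' terminal exon remnant. When boundaries are unset, a reference exon
#' sequence can locate the exon/intron boundary by best local alignment.
#'
#' @param records marker record `data.frame`.
#' @param exon_max maximum exon length retained (barcode convention:
#'   264 bp of the slow exon).
#' @param reference_exon optional reference exon used to locate the
#'   boundary when `exon_end` is `NA`.
#' @param scoring [scoring_scheme()] used for the fallback alignment.
#' @return a `data.frame` with columns `id`, `exon`, `intron`.
#' @export
split_regions <- function(records, exon_max = 264L, reference_exon = NULL,
                          scoring = scoring_scheme()) {
  validate_records(records)
  out <- data.frame(id = records$id, exon = character(nrow(records)),
                    intron = character(nrow(records)),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(records))) {
    s <- records$sequence[k]
    ee <- records$exon_end[k]
    ie <- records$intron_end[k]
    if (is.na(ee)) {
      if (is.null(reference_exon))
        stop("record ", records$id[k],
             ": no exon boundary set and no reference exon given")
      hit <- .align_local_cpp(reference_exon, s, scoring$match,
                              scoring$mismatch, scoring$gap_per_position,
                              FALSE)
      ee <- hit$end_b        # 1-based inclusive end == 0-based half-open end
      ie <- NA_integer_
    }
    if (is.na(ie)) ie <- nchar(s)
    out$exon[k] <- substr(s, 1L, min(ee, exon_max))
    out$intron[k] <- if (ie > ee) substr(s, ee + 1L, ie) else ""
  }
  out
}

#' Read a reference taxonomy table
#'
#' Tab-separated, with required columns `species`, `genus`, `subfamily`,
#' `species_group`, `literature_support`. Species names must be unique.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` with one row per species.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  needed <- c("species", "genus", "subfamily", "species_group",
              "literature_support")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("taxonomy table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species))
    stop("duplicate species in taxonomy: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "))
  tab$literature_support <- as.logical(tab$literature_support)
  tab
}

#' Write a taxonomy table as TSV
#'
#' @param taxonomy taxonomy `data.frame` as from [read_taxonomy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Derive a taxonomy table from marker records
#'
#' @param records marker record `data.frame`.
#' @return taxonomy `data.frame` (one row per species,
#'   `literature_support = TRUE`).
#' @export
records_taxonomy <- function(records) {
  tab <- unique(records[c("species", "genus", "subfamily", "species_group")])
  tab <- tab[order(tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  tab$literature_support <- TRUE
  tab
}

#' Newick export / import
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so all tree
#' I/O in the package goes through one place.
#'
#' @param tree an [ape::phylo] tree.
#' @param path optional file; when `NULL` the newick string is returned.
#' @return newick string (write) or `phylo` (read).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}

#' @rdname write_newick
#' @param text optional newick string instead of a file.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(path)) ape::read.tree(text = text) else ape::read.tree(path)
}

#' Build an alignment block from aligned sequences
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (gap character `-`), or a character matrix of single characters.
#' @return character matrix (rows = sequences, columns = sites) with an
#'   attribute `gap_only_columns` flagging all-gap columns.
#' @export
as_msa <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
      stop("aligned sequences differ in length: ",
           paste(range(nchar(seqs)), collapse = " vs "))
    m <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
                byrow = TRUE, dimnames = list(names(seqs), NULL))
  }
  if (!ncol(m)) stop("empty alignment")
  attr(m, "gap_only_columns") <- which(colSums(m != "-") == 0L)
  m
}
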