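#' Pipeline run configuration
#'
#' @param out_dir output directory for report files.
#' @param sim [sim_params()] describing the dataset to simulate, or
#'   `NULL` when `records`/`msa` are supplied directly.
#' @param records,msa optional pre-loaded marker records and exon
#'   alignment (used instead of simulation).
#' @param threshold clustering identity threshold.
#' @param scoring a [scoring_scheme()].
#' @param n_bootstrap bootstrap replicates for the tree stage.
#' @param stages subset of
#'   `c("cluster", "distances", "gap", "identify", "tree", "assign")`.
#' @param seed seed for the stochastic stages (bootstrap); the simulated
#'   dataset itself is governed by `sim$seed`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, sim = sim_params(), records = NULL,
                       msa = NULL, threshold = 0.98,
                       scoring = scoring_scheme(), n_bootstrap = 100L,
                       stages = c("cluster", "distances", "gap",
                                  "identify", "tree", "assign"),
                       seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!length(stages)) stop("at least one stage must be enabled")
  structure(list(out_dir = out_dir, sim = sim, records = records,
                 msa = msa, threshold = threshold, scoring = scoring,
                 n_bootstrap = as.integer(n_bootstrap), stages = stages,
                 seed = as.integer(seed)),
            class = "run_config")
}

# hash of the scientific configuration only (output location excluded,
# so reruns into different directories compare byte-identical)
.config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

.provenance_header <- function(config) {
  ver <- tryCatch(as.character(utils::packageVersion("lcnbarcode")),
                  error = function(e) "dev")
  sprintf("# lcnbarcode %s; seed=%d; config=%s", ver, config$seed,
          .config_hash(config))
}

.write_tsv_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end marker evaluation pipeline
#'
#' Simulates (or accepts) a dataset, then runs the enabled stages and
#' writes `table1.tsv` (clusters per subfamily with concordance labels),
#' `table2.tsv` (alignment length, variable and parsimony-informative
#' sites), `table3.tsv` (identification success per marker mode and
#' taxon level), `gap_report.json`, `tree.nwk` (NJ with bootstrap) and
#' `assignments.tsv` (allele-to-genepool calls for hybrid candidates).
#' Every report carries a provenance header (version, seed, config
#' hash). A stage failure aborts the run, removes that stage's partial
#' outputs, and names the stage.
#'
#' @param config a [run_config()].
#' @return list with the in-memory results of each stage and `files`,
#'   the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", config$out_dir)
  if (is.null(config$records)) {
    sim <- simulate_dataset(config$sim)
    records <- sim$records
    msa <- sim$msa_exon
  } else {
    sim <- NULL
    records <- validate_records(config$records)
    msa <- if (is.null(config$msa)) NULL else as_msa(config$msa)
  }
  taxonomy <- records_taxonomy(records)
  hdr <- .provenance_header(config)
  out <- list(records = records, taxonomy = taxonomy, sim = sim,
              files = character(0))
  run_stage <- function(name, paths, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      unlink(paths)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    out$files <<- c(out$files, paths)
    res
  }
  f <- function(x) file.path(config$out_dir, x)

  out$clusters <- run_stage("cluster", f("table1.tsv"), function() {
    cs <- greedy_cluster(records, config$threshold, config$scoring)
    purity <- cluster_purity(cs, records, taxonomy)
    .write_tsv_report(purity$by_subfamily, f("table1.tsv"), hdr)
    list(cluster_set = cs, purity = purity)
  })

  out$distances <- run_stage("distances", f("table2.tsv"), function() {
    if (is.null(msa)) stop("no exon alignment available")
    ss <- site_stats(msa)
    tab2 <- data.frame(marker = "exon", aln_length = ss$aln_length,
                       variable = ss$variable,
                       informative = ss$informative,
                       substitution_model = "K80")
    .write_tsv_report(tab2, f("table2.tsv"), hdr)
    list(site_stats = ss, matrix = distance_matrix(msa))
  })

  out$gap <- run_stage("gap", f("gap_report.json"), function() {
    d <- if (!is.null(out$distances)) out$distances$matrix
         else distance_matrix(msa)
    rep <- gap_report(d, records)
    write_gap_json(rep, f("gap_report.json"))
    rep
  })

  out$identification <- run_stage("identify", f("table3.tsv"), function() {
    queries <- select_queries(records)
    if (!nrow(queries)) stop("no multi-provenance species to query")
    bp <- bit_score_params(config$scoring)
    tabs <- lapply(c("exon", "exon_intron"), function(mode) {
      db <- build_reference_db(records, mode)
      res <- identify_all(queries, db, config$scoring, bp)
      list(mode = mode, results = res,
           table = success_table(res, marker = mode))
    })
    tab3 <- do.call(rbind, lapply(tabs, `[[`, "table"))
    .write_tsv_report(tab3, f("table3.tsv"), hdr)
    tabs
  })

  out$tree <- run_stage("tree", f("tree.nwk"), function() {
    if (nrow(msa) < 4L) stop("need >= 4 sequences for the tree stage")
    tr <- bootstrap_support(msa, config$n_bootstrap, seed = config$seed)
    con <- file(f("tree.nwk"), "w")
    writeLines(hdr, con)
    close(con)
    cat(write_newick(tr), "\n", file = f("tree.nwk"), append = TRUE,
        sep = "")
    tr
  })

  out$assignments <- run_stage("assign", f("assignments.tsv"), function() {
    hyb <- !is.null(sim) && any(sim$truth$is_hybrid)
    if (!hyb) {
      .write_tsv_report(
        data.frame(allele_id = character(), individual_id = character(),
                   genepool = character(), margin = numeric(),
                   identical = logical(), tie = logical(),
                   putative_hybrid = logical()),
        f("assignments.tsv"), hdr)
      return(NULL)
    }
    hrows <- sim$truth[sim$truth$is_hybrid, ]
    parents <- unique(c(hrows$parent_a, hrows$parent_b))
    pools <- lapply(parents, function(sp) {
      r <- records[records$species == sp, ]
      stats::setNames(r$sequence, r$id)
    })
    names(pools) <- parents
    hyb_rec <- records[records$id %in% hrows$id, ]
    alleles <- data.frame(allele_id = hyb_rec$id,
                          individual_id = sub("_(a|b)$", "", hyb_rec$id),
                          sequence = hyb_rec$sequence,
                          stringsAsFactors = FALSE)
    asn <- assign_alleles(alleles, pools, config$scoring)
    .write_tsv_report(asn, f("assignments.tsv"), hdr)
    asn
  })
  out
}

#' Compare two marker datasets
#'
#' Side-by-side site statistics and identification-success metrics for
#' two markers scored over (ideally) the same species, plus per-level
#' K2P distance summaries. Warns when the species overlap is below 50%.
#'
#' @param dataset_a,dataset_b lists with elements `records`, `msa`, and
#'   `label` (see [marker_dataset()]).
#' @param scoring a [scoring_scheme()].
#' @return list with `site_stats`, `identification`, `k2p_levels`
#'   data frames (one row per marker and stratum).
#' @export
compare_markers <- function(dataset_a, dataset_b,
                            scoring = scoring_scheme()) {
  sp_a <- unique(dataset_a$records$species)
  sp_b <- unique(dataset_b$records$species)
  ov <- length(intersect(sp_a, sp_b)) / min(length(sp_a), length(sp_b))
  if (ov < 0.5)
    warning(sprintf("species overlap between markers is only %.0f%%",
                    100 * ov))
  one <- function(ds) {
    ss <- site_stats(ds$msa)
    d <- distance_matrix(ds$msa)
    lv <- classify_pairs(d, ds$records)
    med <- stats::aggregate(distance ~ level, lv, stats::median)
    med$marker <- ds$label
    queries <- select_queries(ds$records)
    idt <- if (nrow(queries)) {
      db <- build_reference_db(ds$records, "exon_intron")
      success_table(identify_all(queries, db, scoring,
                                 bit_score_params(scoring)),
                    marker = ds$label)
    } else NULL
    list(ss = data.frame(marker = ds$label, aln_length = ss$aln_length,
                         variable = ss$variable,
                         informative = ss$informative),
         med = med, idt = idt)
  }
  a <- one(dataset_a); b <- one(dataset_b)
  list(site_stats = rbind(a$ss, b$ss),
       identification = rbind(a$idt, b$idt),
       k2p_levels = rbind(a$med, b$med))
}

#' Bundle records and an alignment as a named marker dataset
#'
#' @param records marker record `data.frame`.
#' @param msa exon alignment for the records.
#' @param label marker name used in comparison tables.
#' @return list understood by [compare_markers()].
#' @export
marker_dataset <- function(records, msa, label) {
  list(records = records, msa = as_msa(msa), label = label)
}
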