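#' Simulation parameters for synthetic two-part barcode datasets
#'
#' The defaults state a world resembling a low-copy nuclear barcode in a
#' recently radiated plant family: a slowly evolving 264-bp exon with an
#' expected interspecific K2P divergence near 0.01, an adjacent
#' 100-400 bp intron evolving several times faster and accumulating
#' indels, a conserved 14-bp terminal exon remnant, several accessions
#' per species whose intraspecific divergence (0.004) overlaps the
#' interspecific range, occasional heterozygous intron alleles differing
#' by indels, and optional hybrid individuals carrying alleles from two
#' parental species.
#'
#' @param n_subfamilies,n_groups_per_subfamily,n_species_per_group
#'   taxonomy shape (>= 1 each).
#' @param accessions_per_species single count or `c(min, max)` range.
#' @param exon_length,remnant_length exon and terminal-remnant lengths.
#' @param intron_length_range root intron length range (uniform draw).
#' @param kappa transition/transversion odds per substitution event.
#' @param exon_divergence_target expected within-group interspecific
#'   exon K2P.
#' @param group_divergence,subfamily_divergence expected exon K2P between
#'   groups / between subfamilies.
#' @param intron_rate_multiplier intron substitution rate relative to
#'   the exon (>= 1).
#' @param intraspecific_divergence expected within-species exon K2P.
#' @param indel_rate per-branch intron indel probability.
#' @param indel_mean_length mean geometric indel length.
#' @param het_fraction fraction of accessions emitting two intron
#'   alleles that differ by at least one indel.
#' @param n_hybrids number of F1 hybrid individuals (two alleles, one
#'   per parental species).
#' @param seed RNG seed; the whole dataset is a pure function of the
#'   parameters and this seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_subfamilies = 3L, n_groups_per_subfamily = 2L,
                       n_species_per_group = 4L,
                       accessions_per_species = 3L,
                       exon_length = 264L, remnant_length = 14L,
                       intron_length_range = c(100L, 400L),
                       kappa = 2, exon_divergence_target = 0.01,
                       group_divergence = 0.03,
                       subfamily_divergence = 0.08,
                       intron_rate_multiplier = 5,
                       intraspecific_divergence = 0.004,
                       indel_rate = 0.2, indel_mean_length = 4,
                       het_fraction = 0.2, n_hybrids = 0L, seed = 1L) {
  p <- list(n_subfamilies = as.integer(n_subfamilies),
            n_groups_per_subfamily = as.integer(n_groups_per_subfamily),
            n_species_per_group = as.integer(n_species_per_group),
            accessions_per_species = as.integer(accessions_per_species),
            exon_length = as.integer(exon_length),
            remnant_length = as.integer(remnant_length),
            intron_length_range = as.integer(intron_length_range),
            kappa = kappa,
            exon_divergence_target = exon_divergence_target,
            group_divergence = group_divergence,
            subfamily_divergence = subfamily_divergence,
            intron_rate_multiplier = intron_rate_multiplier,
            intraspecific_divergence = intraspecific_divergence,
            indel_rate = indel_rate, indel_mean_length = indel_mean_length,
            het_fraction = het_fraction, n_hybrids = as.integer(n_hybrids),
            seed = as.integer(seed))
  stopifnot(p$n_subfamilies >= 1L, p$n_groups_per_subfamily >= 1L,
            p$n_species_per_group >= 1L,
            all(p$accessions_per_species >= 1L),
            p$exon_length >= 1L, p$intron_rate_multiplier >= 1,
            p$kappa > 0, p$het_fraction >= 0, p$het_fraction <= 1,
            p$indel_rate >= 0, p$indel_rate <= 1, p$n_hybrids >= 0L)
  # K80 saturates as divergence approaches 0.75; the fast intron must
  # stay clear of it
  if (p$subfamily_divergence * p$intron_rate_multiplier >= 0.6)
    stop("infeasible calibration: intron divergence approaches K80 ",
         "saturation")
  structure(p, class = "sim_params")
}

.random_codes <- function(L) sample.int(4L, L, replace = TRUE) - 1L

# One K80-style substitution process step: Poisson number of events at
# the given expected substitutions/site, transition vs transversion with
# odds kappa:1 per event.
.evolve_codes <- function(codes, subs_per_site, kappa) {
  L <- length(codes)
  n_ev <- stats::rpois(1L, subs_per_site * L)
  if (n_ev == 0L) return(codes)
  sites <- sample.int(L, n_ev, replace = TRUE)
  is_ts <- stats::runif(n_ev) < kappa / (kappa + 1)
  for (e in seq_len(n_ev)) {
    x <- codes[sites[e]]
    codes[sites[e]] <- if (is_ts[e]) (x + 2L) %% 4L
      else (x + sample(c(1L, 3L), 1L)) %% 4L
  }
  codes
}

# Insert or delete one geometric-length segment at a uniform position.
.one_indel <- function(codes, mean_len) {
  len <- 1L + stats::rgeom(1L, 1 / max(mean_len, 1))
  L <- length(codes)
  if (stats::runif(1) < 0.5 && L > len + 10L) {         # deletion
    at <- sample.int(L - len + 1L, 1L)
    codes[-(at:(at + len - 1L))]
  } else {                                              # insertion
    at <- sample.int(L + 1L, 1L)
    append(codes, .random_codes(len), after = at - 1L)
  }
}

.apply_branch_indels <- function(codes, rate, mean_len) {
  if (stats::runif(1) < rate) codes <- .one_indel(codes, mean_len)
  codes
}

.codes_to_seq <- function(codes) paste(c("A", "C", "G", "T")[codes + 1L],
                                       collapse = "")

# Evolve exon/intron/remnant down a tree whose edge lengths are expected
# exon substitutions per site.
.evolve_down_tree <- function(tree, root, p) {
  tree <- stats::reorder(tree, "cladewise")
  n <- length(tree$tip.label)
  nodes <- vector("list", n + tree$Nnode)
  nodes[[n + 1L]] <- root
  for (k in seq_len(nrow(tree$edge))) {
    par <- nodes[[tree$edge[k, 1]]]
    l <- tree$edge.length[k]
    nodes[[tree$edge[k, 2]]] <- .evolve_lineage(par, l, p)
  }
  stats::setNames(nodes[seq_len(n)], tree$tip.label)
}

.evolve_lineage <- function(node, l, p) {
  list(exon = .evolve_codes(node$exon, l, p$kappa),
       intron = .apply_branch_indels(
         .evolve_codes(node$intron, l * p$intron_rate_multiplier, p$kappa),
         p$indel_rate, p$indel_mean_length),
       remnant = .evolve_codes(node$remnant, l, p$kappa))
}

.yule_tree <- function(n, mean_pairwise) {
  if (n == 1L) return(NULL)
  if (n == 2L) {
    t <- ape::read.tree(text = "(t1:1,t2:1);")
  } else {
    t <- ape::rphylo(n, birth = 1, death = 0)
  }
  cd <- ape::dist.nodes(t)[seq_len(n), seq_len(n)]
  t$edge.length <- t$edge.length * mean_pairwise / mean(cd[upper.tri(cd)])
  t
}

#' Simulate a synthetic two-part barcode dataset with known truth
#'
#' Root exon/intron/remnant sequences are drawn uniformly; subfamily and
#' group ancestors diverge by the configured expected K2P amounts;
#' species evolve along a pure-birth tree per group scaled to the
#' interspecific target; accessions sit on a within-species star at the
#' intraspecific divergence. The intron additionally accumulates indels
#' per branch. Heterozygous accessions emit two intron alleles differing
#' by at least one indel; hybrid individuals receive allele `a` from one
#' parental species' pool and allele `b` from another.
#'
#' @param params a [sim_params()].
#' @return list with `records` (marker record `data.frame`, one row per
#'   emitted allele, boundaries set), `msa_exon` (true exon alignment,
#'   gap-free by construction), `truth` (per-record `data.frame` with
#'   heterozygosity and hybrid parentage), and `params`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  root <- list(exon = .random_codes(p$exon_length),
               intron = .random_codes(sample(
                 p$intron_length_range[1]:p$intron_length_range[2], 1L)),
               remnant = .random_codes(p$remnant_length))
  recs <- list()
  truth <- list()
  tips <- list()     # species name -> tip node (for hybrids)
  meta <- list()     # species name -> c(genus, subfamily, group)
  for (sf in seq_len(p$n_subfamilies)) {
    sf_name <- sprintf("Subfam%02d", sf)
    sf_node <- .evolve_lineage(root, p$subfamily_divergence / 2, p)
    for (g in seq_len(p$n_groups_per_subfamily)) {
      genus <- sprintf("Genus%02d%02d", sf, g)
      grp_name <- sprintf("group_%02d_%02d", sf, g)
      g_node <- .evolve_lineage(sf_node, p$group_divergence / 2, p)
      nsp <- p$n_species_per_group
      tree <- .yule_tree(nsp, p$exon_divergence_target)
      sp_nodes <- if (is.null(tree)) {
        stats::setNames(list(.evolve_lineage(g_node, 0, p)), "t1")
      } else .evolve_down_tree(tree, g_node, p)
      for (si in seq_len(nsp)) {
        sp_name <- sprintf("%s_sp%02d", genus, si)
        tips[[sp_name]] <- sp_nodes[[paste0("t", si)]]
        meta[[sp_name]] <- c(genus, sf_name, grp_name)
      }
    }
  }
  # accessions per species (star at the intraspecific divergence)
  acc_rng <- p$accessions_per_species
  all_acc <- list()
  for (sp_name in names(tips)) {
    n_acc <- if (length(acc_rng) == 2L)
      sample(acc_rng[1]:acc_rng[2], 1L) else acc_rng
    for (ai in seq_len(n_acc)) {
      node <- .evolve_lineage(tips[[sp_name]],
                              p$intraspecific_divergence / 2, p)
      all_acc[[length(all_acc) + 1L]] <-
        list(species = sp_name, acc = ai, node = node,
             provenance = sprintf("P%02d", ai))
    }
  }
  n_het <- round(p$het_fraction * length(all_acc))
  het_idx <- if (n_het) sample(seq_along(all_acc), n_het) else integer(0)
  emit <- function(id, species, provenance, allele_id, node,
                   is_het, is_hybrid, parent_a, parent_b) {
    m <- meta[[species]]
    if (is.null(m)) m <- c("Hybrid", m_sf_hyb, NA_character_)
    recs[[length(recs) + 1L]] <<- data.frame(
      id = id, species = species, genus = m[1], subfamily = m[2],
      species_group = m[3], provenance = provenance, allele_id = allele_id,
      sequence = paste0(.codes_to_seq(node$exon), .codes_to_seq(node$intron),
                        .codes_to_seq(node$remnant)),
      exon_end = length(node$exon),
      intron_end = length(node$exon) + length(node$intron),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, species = species, is_het = is_het, is_hybrid = is_hybrid,
      parent_a = parent_a, parent_b = parent_b,
      exon = .codes_to_seq(node$exon), stringsAsFactors = FALSE)
  }
  m_sf_hyb <- NA_character_
  for (k in seq_along(all_acc)) {
    a <- all_acc[[k]]
    base_id <- sprintf("%s_%02d", a$species, a$acc)
    if (k %in% het_idx) {
      node_b <- a$node
      node_b$intron <- .one_indel(
        .evolve_codes(node_b$intron, p$intraspecific_divergence / 2,
                      p$kappa), p$indel_mean_length)
      emit(paste0(base_id, "_a"), a$species, a$provenance, "a", a$node,
           TRUE, FALSE, NA, NA)
      emit(paste0(base_id, "_b"), a$species, a$provenance, "b", node_b,
           TRUE, FALSE, NA, NA)
    } else {
      emit(base_id, a$species, a$provenance, NA_character_, a$node,
           FALSE, FALSE, NA, NA)
    }
  }
  # hybrids: two parental species from different groups of one subfamily
  if (p$n_hybrids > 0L) {
    sp_names <- names(tips)
    sfs <- vapply(meta, `[`, character(1), 2)
    grps <- vapply(meta, `[`, character(1), 3)
    for (h in seq_len(p$n_hybrids)) {
      sf_pick <- sample(unique(sfs), 1L)
      cand <- sp_names[sfs == sf_pick]
      gr <- grps[cand]
      if (length(unique(gr)) >= 2L) {
        pa <- sample(cand[gr == unique(gr)[1]], 1L)
        pb <- sample(cand[gr == unique(gr)[2]], 1L)
      } else {
        pick <- sample(cand, 2L)
        pa <- pick[1]; pb <- pick[2]
      }
      hyb_sp <- sprintf("Hybrid%02d", h)
      m_sf_hyb <- meta[[pa]][2]
      node_a <- .evolve_lineage(tips[[pa]],
                                p$intraspecific_divergence / 2, p)
      node_b <- .evolve_lineage(tips[[pb]],
                                p$intraspecific_divergence / 2, p)
      emit(sprintf("%s_01_a", hyb_sp), hyb_sp, "P01", "a", node_a,
           FALSE, TRUE, pa, pb)
      emit(sprintf("%s_01_b", hyb_sp), hyb_sp, "P01", "b", node_b,
           FALSE, TRUE, pa, pb)
    }
  }
  records <- validate_records(do.call(rbind, recs))
  truth <- do.call(rbind, truth)
  msa_exon <- as_msa(stats::setNames(truth$exon, truth$id))
  truth$exon <- NULL
  list(records = records, msa_exon = msa_exon, truth = truth,
       params = p)
}

#' Write a simulated dataset to files
#'
#' Emits `barcode.fasta` (full exon+intron+remnant sequences with
#' structured headers), `exon.fasta` (exon trimmed to 264), `truth.tsv`
#' (per-record truth incl. boundaries), and `taxonomy.tsv`.
#'
#' @param sim result of [simulate_dataset()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the four file paths, invisibly.
#' @export
emit_dataset <- function(sim, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(barcode = file.path(out_dir, "barcode.fasta"),
             exon = file.path(out_dir, "exon.fasta"),
             truth = file.path(out_dir, "truth.tsv"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"))
  write_fasta(sim$records, paths[["barcode"]])
  parts <- split_regions(sim$records)
  exon_recs <- sim$records
  exon_recs$sequence <- parts$exon
  exon_recs$exon_end <- nchar(parts$exon)
  exon_recs$intron_end <- nchar(parts$exon)
  write_fasta(exon_recs, paths[["exon"]])
  tr <- merge(sim$truth,
              sim$records[c("id", "exon_end", "intron_end")], by = "id")
  utils::write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_taxonomy(records_taxonomy(sim$records), paths[["taxonomy"]])
  invisible(paths)
}
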