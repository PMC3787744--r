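# End-to-end orchestration: align -> cluster -> map -> coverage ->
# colocate -> diversity -> (conserve/enrich) -> report, with an exclusion
# ledger that accounts for every superfamily the way the dataset filters do.

#' Pipeline configuration
#'
#' All defaults are the protocol's standard parameters, so a bare run
#' reproduces the canonical analysis on whatever data is supplied.
#'
#' @param min_rep_length minimum representative length (residues).
#' @param dominance single-domain coverage fraction above which a
#'   superfamily is excluded.
#' @param colocation_min_clusters minimum s60 clusters with data for the
#'   colocation statistic.
#' @param s60_identity sequence-identity threshold for subfamily clustering.
#' @param nrmsd_cutoffs normalised-RMSD cutoffs (A) for structural
#'   clustering; the first is used for the diversity label.
#' @param conservation_threshold conserved-column score threshold.
#' @param fragment_fraction fragment-removal length fraction.
#' @param hub_min_interactions hub-superfamily interaction threshold.
#' @param site_types site types to analyse.
#' @param ledger_site_type site type used for the exclusion ledger's
#'   coverage filters.
#' @param recluster_s60 ignore supplied s60 ids and recluster from
#'   sequences.
#' @param compute_diversity run the all-pairs structural clustering stage.
#' @param align parameters passed to [align_structures()].
#' @param seed seed recorded in the manifest.
#' @return List of class `RunConfig`.
#' @export
run_config <- function(min_rep_length = 100,
                       dominance = 0.5,
                       colocation_min_clusters = 10,
                       s60_identity = 0.60,
                       nrmsd_cutoffs = c(9.0, 5.0),
                       conservation_threshold = 0.7,
                       fragment_fraction = 0.8,
                       hub_min_interactions = 10,
                       site_types = c("catalytic", "protein_protein",
                                      "nucleic_acid", "small_ligand"),
                       ledger_site_type = "protein_protein",
                       recluster_s60 = FALSE,
                       compute_diversity = TRUE,
                       align = list(),
                       seed = 1) {
  structure(as.list(environment()), class = "RunConfig")
}

# s60 ClusterSet from a family-membership table (ground-truth ids)
clusters_from_table <- function(families) {
  cl <- split(families$domain_id, families$s60_cluster_id)
  new_cluster_set("s60", cl, parameter = 0.60)
}

#' Analyse one superfamily
#'
#' Runs the mapping protocol for a single superfamily: s60 clustering (or
#' the supplied cluster ids), representative selection, member-to-
#' representative alignment, profile building, coverage per site type,
#' colocation, and structural-diversity clustering. Superfamilies are
#' excluded - with the reason recorded - when they have a single s60
#' cluster, no site data at all, a representative shorter than
#' `min_rep_length`, or a single member covering more than `dominance` of
#' the representative (judged on `ledger_site_type`).
#'
#' @param domains named list of the superfamily's `DomainStructure`s.
#' @param annotations list of `SiteAnnotation`s for those domains.
#' @param config a [run_config()].
#' @param s60_clusters optional `ClusterSet`; computed from sequences when
#'   absent or when `config$recluster_s60` is set.
#' @return List of class `SuperfamilyAnalysis`: `exclusion` (`"pass"` or a
#'   reason), and when not excluded early: `representative_id`, `profile`,
#'   `coverages`, `colocations`, `diversity` (per cutoff), `diverse`.
#' @export
analyse_superfamily <- function(domains, annotations, config = run_config(),
                                s60_clusters = NULL) {
  names(domains) <- vapply(domains, `[[`, "", "domain_id")
  sf_id <- domains[[1]]$superfamily_id
  out <- list(superfamily_id = sf_id, exclusion = "pass")
  class(out) <- "SuperfamilyAnalysis"

  if (is.null(s60_clusters) || config$recluster_s60) {
    s60_clusters <- cluster_s60(domains, config$s60_identity)
  }
  out$s60 <- s60_clusters
  if (s60_clusters$n_clusters < 2L) {
    out$exclusion <- "single_s60_cluster"
    return(out)
  }
  if (!length(annotations)) {
    out$exclusion <- "no_site_data"
    return(out)
  }

  rep_id <- select_representative(domains, s60_clusters, config$align)
  pair_alns <- attr(rep_id, "alignments")
  out$representative_id <- as.character(rep_id)
  rep_dom <- domains[[out$representative_id]]

  # alignments of every member to the representative (reuse pairwise ones)
  member_alns <- list()
  for (id in names(domains)) {
    if (id == out$representative_id) next
    key1 <- paste(sort(c(id, out$representative_id)), collapse = "|")
    al <- pair_alns[[key1]]
    if (is.null(al)) {
      al <- align_structures(rep_dom, domains[[id]], config$align)
      pair_alns[[key1]] <- al
    }
    member_alns[[id]] <- al
  }

  profile <- build_profile(sf_id, rep_dom, domains, member_alns,
                           annotations, s60_clusters)
  out$profile <- profile
  out$coverages <- lapply(config$site_types, function(ty) {
    coverage(profile, ty, min_rep_length = config$min_rep_length,
             dominance = config$dominance)
  })
  names(out$coverages) <- config$site_types
  out$colocations <- lapply(config$site_types, function(ty) {
    colocation_statistic(profile, ty,
                         min_clusters = config$colocation_min_clusters)
  })
  names(out$colocations) <- config$site_types

  led <- out$coverages[[config$ledger_site_type]]
  if (!is.null(led) && led$excluded) out$exclusion <- led$exclusion_reason

  if (config$compute_diversity) {
    ids <- sort(names(domains))
    all_alns <- pair_alns
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        key <- paste(ids[i], ids[j], sep = "|")
        if (is.null(all_alns[[key]])) {
          all_alns[[key]] <- align_structures(domains[[ids[i]]],
                                              domains[[ids[j]]], config$align)
        }
      }
    }
    out$diversity <- lapply(config$nrmsd_cutoffs, function(cut) {
      cluster_structures(domains, all_alns, cutoff = cut)
    })
    names(out$diversity) <- paste0("cutoff_", config$nrmsd_cutoffs)
    out$diverse <- is_structurally_diverse(out$diversity[[1]])
  }
  out
}

#' @export
print.SuperfamilyAnalysis <- function(x, ...) {
  cat("SuperfamilyAnalysis", x$superfamily_id, "-",
      if (x$exclusion == "pass") "passes all filters" else
        paste("excluded:", x$exclusion), "\n")
  invisible(x)
}

# read pipeline inputs from a directory written by write_superfamily()
# (or assembled by hand in the same formats)
load_run_inputs <- function(dir) {
  families <- read_family_table(file.path(dir, "families.tsv"))
  pdb_dir <- file.path(dir, "pdb")
  domains <- list()
  for (i in seq_len(nrow(families))) {
    id <- families$domain_id[i]
    path <- file.path(pdb_dir, paste0(id, ".pdb"))
    if (!file.exists(path)) {
      stop("align stage: missing structure for domain ", id)
    }
    domains[[id]] <- read_domain_pdb(path, id, families$superfamily_id[i])
    domains[[id]]$s60_cluster_id <- families$s60_cluster_id[i]
  }
  ann_path <- file.path(dir, "sites.tsv")
  annotations <- if (file.exists(ann_path)) {
    read_site_annotations(ann_path, domains)
  } else {
    list()
  }
  int_path <- file.path(dir, "interactions.tsv")
  counts <- if (file.exists(int_path)) {
    tab <- read.delim(int_path)
    setNames(as.integer(tab$n_interactions), tab$domain_id)
  } else {
    integer()
  }
  list(domains = domains, annotations = annotations, families = families,
       interaction_counts = counts)
}

#' Run the whole pipeline
#'
#' Orchestrates all stages over a set of superfamilies and writes summary
#' tables: `coverage_summary.tsv` (one row per superfamily x site type),
#' `colocation.tsv`, `diversity.tsv`, `exclusions.tsv` (the ledger: one row
#' per superfamily with the first exclusion rule it hit, or `pass`),
#' `hubs.tsv`, and a `manifest.txt` recording package version, parameters
#' and input digests. The run is deterministic: identical inputs and
#' configuration produce byte-identical summary tables.
#'
#' @param input either a directory of pipeline inputs (as written by
#'   [write_superfamily()]), or a list of `SyntheticSuperfamily` objects.
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with per-superfamily `analyses`, the
#'   `exclusions` ledger data.frame, `hubs`, and the output tables.
#' @export
run_all <- function(input, config = run_config(), out_dir = tempfile("run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(input)) {
    loaded <- load_run_inputs(input)
    sf_ids <- unique(loaded$families$superfamily_id)
    sims <- lapply(sf_ids, function(sf) {
      rows <- loaded$families$superfamily_id == sf
      ids <- loaded$families$domain_id[rows]
      list(superfamily_id = sf,
           domains = loaded$domains[ids],
           annotations = Filter(function(a) a$domain_id %in% ids,
                                loaded$annotations),
           families = loaded$families[rows, , drop = FALSE],
           interaction_counts = loaded$interaction_counts[
             names(loaded$interaction_counts) %in% ids])
    })
    digests <- tools::md5sum(list.files(input, recursive = TRUE,
                                        full.names = TRUE))
  } else {
    sims <- input
    digests <- NULL
  }

  analyses <- list()
  for (sim in sims) {
    s60 <- if (all(!is.na(sim$families$s60_cluster_id))) {
      clusters_from_table(sim$families)
    } else {
      NULL
    }
    analyses[[sim$superfamily_id]] <-
      analyse_superfamily(sim$domains, sim$annotations, config, s60)
  }

  exclusions <- data.frame(
    superfamily_id = vapply(analyses, `[[`, "", "superfamily_id"),
    reason = vapply(analyses, `[[`, "", "exclusion"))
  rownames(exclusions) <- NULL
  message("exclusion ledger: ",
          paste(names(table(exclusions$reason)), table(exclusions$reason),
                sep = "=", collapse = ", "))

  cov_tab <- do.call(rbind, lapply(analyses, function(a) {
    if (is.null(a$coverages)) return(NULL)
    do.call(rbind, lapply(a$coverages, function(cv) {
      data.frame(superfamily_id = cv$superfamily_id, site_type = cv$site_type,
                 coverage = cv$coverage,
                 n_contributing_domains = cv$n_contributing_domains,
                 excluded = cv$excluded, exclusion_reason = cv$exclusion_reason)
    }))
  }))
  col_tab <- do.call(rbind, lapply(analyses, function(a) {
    if (is.null(a$colocations)) return(NULL)
    do.call(rbind, lapply(a$colocations, function(cl) {
      data.frame(superfamily_id = cl$superfamily_id, site_type = cl$site_type,
                 n_clusters_with_data = cl$n_clusters_with_data,
                 max_fraction = cl$max_fraction, included = cl$included)
    }))
  }))
  div_tab <- do.call(rbind, lapply(analyses, function(a) {
    if (is.null(a$diversity)) return(NULL)
    do.call(rbind, Map(function(cs, nm) {
      data.frame(superfamily_id = a$superfamily_id,
                 cutoff = cs$parameter, n_clusters = cs$n_clusters,
                 diverse = is_structurally_diverse(cs))
    }, a$diversity, names(a$diversity)))
  }))

  counts <- unlist(lapply(sims, `[[`, "interaction_counts"))
  membership <- do.call(rbind, lapply(sims, `[[`, "families"))
  hubs <- if (length(counts)) {
    flag_hub_superfamilies(counts, membership, config$hub_min_interactions)
  } else {
    character()
  }

  wr <- function(tab, name) {
    if (is.null(tab)) tab <- data.frame()
    rownames(tab) <- NULL
    write.table(tab, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(cov_tab, "coverage_summary.tsv")
  wr(col_tab, "colocation.tsv")
  wr(div_tab, "diversity.tsv")
  wr(exclusions, "exclusions.tsv")
  wr(data.frame(superfamily_id = hubs), "hubs.tsv")

  manifest <- c(paste0("siteplast ",
                       as.character(utils::packageVersion("siteplast"))),
                paste0("parameters: ",
                       paste(names(config), vapply(config, function(v)
                         paste(unlist(v), collapse = ","), ""),
                         sep = "=", collapse = "; ")),
                if (!is.null(digests)) paste0("input ", names(digests), " ",
                                              unname(digests)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(analyses = analyses, exclusions = exclusions, hubs = hubs,
                 coverage = cov_tab, colocation = col_tab,
                 diversity = div_tab, out_dir = out_dir))
}
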