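# The core mapping protocol: choose the superfamily representative, map
# every member's functional-site residues onto it through pairwise
# structural alignments, and summarise the per-position contributor sets.

#' Select the superfamily representative
#'
#' Each s60 cluster has a designated cluster representative (its first
#' member by id when unset). All cluster representatives are aligned
#' pairwise and the one with the highest cumulative similarity score to all
#' other cluster representatives is chosen; ties break to the
#' lexicographically smallest domain id. Superfamilies with a single s60
#' cluster carry no information about site diversity and are rejected.
#'
#' @param domains named list of the superfamily's `DomainStructure` objects.
#' @param s60_clusters a `ClusterSet` of kind `s60` over those domains.
#' @param params alignment parameters passed to [align_structures()].
#' @param cluster_reps optional named character vector (cluster id ->
#'   domain id) overriding the default first-by-id cluster representatives.
#' @return The representative's domain id, with attributes `cum_scores`
#'   (named cumulative scores) and `alignments` (the pairwise alignments
#'   computed along the way, for reuse).
#' @export
select_representative <- function(domains, s60_clusters, params = list(),
                                  cluster_reps = NULL) {
  names(domains) <- vapply(domains, `[[`, "", "domain_id")
  if (s60_clusters$n_clusters < 2L) {
    stop("excluded: single s60 cluster")
  }
  if (is.null(cluster_reps)) {
    cluster_reps <- vapply(s60_clusters$clusters, function(m) sort(m)[1], "")
  }
  reps <- sort(unname(cluster_reps))
  alignments <- list()
  scores <- matrix(0, length(reps), length(reps), dimnames = list(reps, reps))
  for (i in seq_along(reps)[-length(reps)]) {
    for (j in (i + 1):length(reps)) {
      al <- align_structures(domains[[reps[i]]], domains[[reps[j]]], params)
      alignments[[paste(reps[i], reps[j], sep = "|")]] <- al
      scores[i, j] <- scores[j, i] <- al$score
    }
  }
  cum <- rowSums(scores)
  best <- reps[order(-cum, reps)][1]  # ties -> smallest id
  structure(best, cum_scores = cum, alignments = alignments)
}

#' Map one member's site residues onto the representative
#'
#' Each annotated member residue contributes the representative position it
#' is paired with in the structural alignment; residues aligned to a gap
#' contribute nothing (they are ignored, as sites falling outside the
#' common core cannot be expressed in the representative's frame).
#'
#' @param rep the representative `DomainStructure`.
#' @param member the member `DomainStructure` (may equal `rep`).
#' @param alignment a `StructuralAlignment` between member and
#'   representative, in either orientation.
#' @param site_annotation a `SiteAnnotation` for the member.
#' @return Sorted integer vector of representative positions (1-based).
#' @export
map_domain_sites <- function(rep, member, alignment, site_annotation) {
  if (site_annotation$domain_id != member$domain_id) {
    stop("annotation is for domain ", site_annotation$domain_id,
         ", not member ", member$domain_id)
  }
  if (alignment$domain_a == member$domain_id &&
      alignment$domain_b == rep$domain_id) {
    mpos <- alignment$pairs[, 1]
    rpos <- alignment$pairs[, 2]
  } else if (alignment$domain_a == rep$domain_id &&
             alignment$domain_b == member$domain_id) {
    mpos <- alignment$pairs[, 2]
    rpos <- alignment$pairs[, 1]
  } else {
    stop("alignment does not connect ", member$domain_id, " and ",
         rep$domain_id)
  }
  idx <- annotation_positions(site_annotation, member)
  hit <- rpos[match(idx, mpos)]
  sort(unique(hit[!is.na(hit)]))
}

# identity self-alignment used when the representative maps onto itself
identity_alignment <- function(dom) {
  new_alignment(dom$domain_id, dom$domain_id,
                cbind(seq_len(dom$length), seq_len(dom$length)),
                rmsd = 0, score = 100)
}

#' Build the per-position site profile of a superfamily representative
#'
#' Unions, per site type and per representative position, the set of
#' members (and of their s60 clusters) whose annotated residues map to
#' that position. The representative's own annotations are included via an
#' identity self-alignment.
#'
#' @param superfamily_id superfamily identifier.
#' @param representative the representative `DomainStructure`.
#' @param members named list of all member `DomainStructure` objects
#'   (including the representative).
#' @param alignments list of `StructuralAlignment` objects connecting each
#'   member to the representative (either orientation).
#' @param annotations list of `SiteAnnotation` objects for the members.
#' @param s60_clusters optional `ClusterSet` of kind `s60`; when absent all
#'   members count as one-cluster-per-domain.
#' @return Object of class `RepresentativeProfile`. For each site type it
#'   holds an edge table `(position, domain_id, cluster_id)` of mapped
#'   contributions, the per-domain mapped position sets, and the sets of
#'   domains/clusters possessing annotations of that type (whether or not
#'   any of their residues survived mapping).
#' @export
build_profile <- function(superfamily_id, representative, members, alignments,
                          annotations, s60_clusters = NULL) {
  names(members) <- vapply(members, `[[`, "", "domain_id")
  cluster_of <- if (is.null(s60_clusters)) {
    setNames(names(members), names(members))
  } else {
    s60_clusters$membership
  }
  aln_of <- list()
  for (al in alignments) {
    other <- setdiff(c(al$domain_a, al$domain_b), representative$domain_id)
    if (length(other) == 0L) other <- representative$domain_id
    if (al$domain_a == representative$domain_id ||
        al$domain_b == representative$domain_id) {
      aln_of[[other]] <- al
    }
  }
  aln_of[[representative$domain_id]] <- identity_alignment(representative)

  types <- unique(vapply(annotations, `[[`, "", "site_type"))
  sites <- list()
  for (ty in types) {
    anns <- Filter(function(a) a$site_type == ty, annotations)
    edges <- list()
    with_data <- character()
    for (a in anns) {
      if (!a$domain_id %in% names(members)) {
        stop("annotation references non-member domain ", a$domain_id)
      }
      with_data <- c(with_data, a$domain_id)
      al <- aln_of[[a$domain_id]]
      if (is.null(al)) {
        stop("member ", a$domain_id, " has annotations but no alignment ",
             "to the representative")
      }
      pos <- map_domain_sites(representative, members[[a$domain_id]], al, a)
      if (length(pos)) {
        edges[[length(edges) + 1L]] <-
          data.frame(position = pos, domain_id = a$domain_id,
                     cluster_id = unname(cluster_of[a$domain_id]))
      }
    }
    edges <- if (length(edges)) unique(do.call(rbind, edges)) else
      data.frame(position = integer(), domain_id = character(),
                 cluster_id = character())
    rownames(edges) <- NULL
    sites[[ty]] <- list(
      edges = edges,
      domain_positions = split(edges$position, edges$domain_id),
      domains_with_data = sort(unique(with_data)),
      clusters_with_data = sort(unique(unname(cluster_of[unique(with_data)]))))
  }
  structure(list(superfamily_id = superfamily_id,
                 representative_id = representative$domain_id,
                 rep_length = representative$length,
                 members = names(members),
                 n_members = length(members),
                 cluster_of = cluster_of,
                 n_clusters = length(unique(cluster_of[names(members)])),
                 sites = sites),
            class = "RepresentativeProfile")
}

#' @export
print.RepresentativeProfile <- function(x, ...) {
  cat("RepresentativeProfile", x$superfamily_id, "- representative",
      x$representative_id, paste0("(", x$rep_length, " residues)\n"))
  for (ty in names(x$sites)) {
    cat("  ", ty, ": ", length(unique(x$sites[[ty]]$edges$position)),
        " positions from ", length(x$sites[[ty]]$domains_with_data),
        " annotated domains\n", sep = "")
  }
  invisible(x)
}

# per-position contributor counts (domains or s60 clusters)
position_counts <- function(profile, site_type,
                            by = c("domains", "s60_clusters")) {
  by <- match.arg(by)
  counts <- integer(profile$rep_length)
  s <- profile$sites[[site_type]]
  if (is.null(s) || nrow(s$edges) == 0L) return(counts)
  col <- if (by == "domains") "domain_id" else "cluster_id"
  e <- unique(s$edges[, c("position", col)])
  tab <- table(e$position)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Functional-site coverage of the representative
#'
#' Coverage is the number of representative positions that map to at least
#' one functional residue of the given type in any member, divided by the
#' representative length. Two confounders are filtered: very small
#' representatives (length below `min_rep_length`) are excluded, and so are
#' superfamilies where a single member by itself covers more than
#' `dominance` of the representative (high coverage then reflects one
#' domain, not diversity between members).
#'
#' @param profile a `RepresentativeProfile`.
#' @param site_type site type to evaluate.
#' @param min_rep_length minimum representative length (default 100).
#' @param dominance single-domain coverage above which the superfamily is
#'   excluded (default 0.5, strict inequality).
#' @param apply_filters set `FALSE` to disable both filters.
#' @return Object of class `CoverageResult`: `coverage`,
#'   `n_contributing_domains`, `excluded` and `exclusion_reason` (one of
#'   `none`, `rep_too_short`, `single_domain_dominance`, `no_site_data`).
#'   A superfamily with no annotation of the requested type gets coverage 0
#'   (and is not excluded).
#' @export
coverage <- function(profile, site_type, min_rep_length = 100,
                     dominance = 0.5, apply_filters = TRUE) {
  s <- profile$sites[[site_type]]
  edges <- if (is.null(s)) data.frame(position = integer(),
                                      domain_id = character()) else s$edges
  cov <- length(unique(edges$position)) / profile$rep_length
  ndom <- length(unique(edges$domain_id))
  excluded <- FALSE
  reason <- "none"
  if (apply_filters && profile$rep_length < min_rep_length) {
    excluded <- TRUE
    reason <- "rep_too_short"
  } else if (apply_filters && nrow(edges)) {
    per_dom <- vapply(split(edges$position, edges$domain_id),
                      function(p) length(unique(p)), 0L)
    if (max(per_dom) / profile$rep_length > dominance) {
      excluded <- TRUE
      reason <- "single_domain_dominance"
    }
  }
  structure(list(superfamily_id = profile$superfamily_id,
                 site_type = site_type,
                 coverage = cov,
                 n_contributing_domains = ndom,
                 excluded = excluded,
                 exclusion_reason = reason),
            class = "CoverageResult")
}

#' @export
print.CoverageResult <- function(x, ...) {
  cat("CoverageResult ", x$superfamily_id, " / ", x$site_type, ": ",
      round(x$coverage, 3), if (x$excluded) paste0(" [excluded: ",
      x$exclusion_reason, "]") else "", "\n", sep = "")
  invisible(x)
}

#' Per-position site frequencies with heat-map colour bins
#'
#' The fraction of members (or of s60 clusters) contributing a site at each
#' representative position, binned on the conventional colour scale:
#' exactly 0 grey, then half-open bins (0-20\%) blue, (20-40\%) green,
#' (40-60\%) yellow, (60-80\%) orange and (80-100\%) red, boundaries
#' assigned upward and 100\% in red.
#'
#' @param profile a `RepresentativeProfile`.
#' @param site_type site type.
#' @param denominator `domains` or `s60_clusters`.
#' @return data.frame with `position`, `fraction`, `bin`.
#' @export
heatmap_fractions <- function(profile, site_type,
                              denominator = c("domains", "s60_clusters")) {
  denominator <- match.arg(denominator)
  n <- if (denominator == "domains") profile$n_members else profile$n_clusters
  if (n <= 0) stop("empty denominator")
  f <- position_counts(profile, site_type, by = denominator) / n
  bin <- character(length(f))
  bin[f == 0] <- "grey"
  bin[f > 0    & f < 0.2] <- "blue"
  bin[f >= 0.2 & f < 0.4] <- "green"
  bin[f >= 0.4 & f < 0.6] <- "yellow"
  bin[f >= 0.6 & f < 0.8] <- "orange"
  bin[f >= 0.8] <- "red"
  data.frame(position = seq_along(f), fraction = f, bin = bin)
}

#' Flag hub superfamilies
#'
#' A superfamily is a hub superfamily when at least one member domain's
#' parent protein takes part in at least `min_interactions` physical
#' interactions.
#'
#' @param interaction_counts named integer vector, domain id -> interaction
#'   count (already mapped down from parent proteins).
#' @param membership data.frame with `domain_id` and `superfamily_id`.
#' @param min_interactions hub threshold (default 10, inclusive).
#' @return Character vector of hub superfamily ids.
#' @export
flag_hub_superfamilies <- function(interaction_counts, membership,
                                   min_interactions = 10) {
  counts <- interaction_counts[membership$domain_id]
  counts[is.na(counts)] <- 0
  mx <- tapply(counts, membership$superfamily_id, max)
  sort(names(mx)[mx >= min_interactions])
}
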