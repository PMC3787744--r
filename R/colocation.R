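# Preferential colocation: does some representative position carry a
# functional site in a large fraction of the superfamily's s60 clusters?

#' Preferential-colocation statistic
#'
#' For each representative position, the fraction of s60 clusters with a
#' functional site mapped there; the statistic is the maximum over
#' positions. A cluster "has a site at position p" when at least one of its
#' member domains contributes at p; the denominator counts only clusters
#' that possess at least one annotation of the site type (a cluster whose
#' annotated residues all fall in alignment gaps still counts - it has
#' data, it simply hits no position). Superfamilies with fewer than
#' `min_clusters` clusters with data are marked not included, to avoid
#' meaningless fractions from under-sampled superfamilies.
#'
#' @param profile a `RepresentativeProfile` built by [build_profile()].
#' @param site_type site type.
#' @param min_clusters minimum number of clusters with data (default 10).
#' @return Object of class `ColocationResult`: `n_clusters_with_data`,
#'   `max_fraction`, `argmax_positions`, `included`.
#' @export
colocation_statistic <- function(profile, site_type, min_clusters = 10) {
  s <- profile$sites[[site_type]]
  n_data <- if (is.null(s)) 0L else length(s$clusters_with_data)
  counts <- position_counts(profile, site_type, by = "s60_clusters")
  if (n_data == 0L || all(counts == 0L)) {
    max_fraction <- if (n_data == 0L) NA_real_ else 0
    argmax <- integer()
  } else {
    frac <- counts / n_data
    max_fraction <- max(frac)
    argmax <- which(frac == max_fraction)
  }
  structure(list(superfamily_id = profile$superfamily_id,
                 site_type = site_type,
                 n_clusters_with_data = n_data,
                 max_fraction = max_fraction,
                 argmax_positions = argmax,
                 included = n_data >= min_clusters),
            class = "ColocationResult")
}

#' @export
print.ColocationResult <- function(x, ...) {
  cat("ColocationResult ", x$superfamily_id, " / ", x$site_type,
      ": max_fraction ", round(x$max_fraction, 3), " over ",
      x$n_clusters_with_data, " clusters with data",
      if (!x$included) " [not included]" else "", "\n", sep = "")
  invisible(x)
}

#' Site coverage of a functional family
#'
#' The superfamily coverage protocol scoped to one functional family: a
#' family representative is chosen (highest cumulative similarity to the
#' other members), every member's sites are mapped onto it, and coverage is
#' computed. A single-member family is evaluated against itself and the
#' result is flagged (attribute `single_member`).
#'
#' @param family_id family identifier (used as the result's id).
#' @param members named list of the family's `DomainStructure` objects.
#' @param annotations list of `SiteAnnotation` objects for those members.
#' @param site_type site type.
#' @param params alignment parameters for [align_structures()].
#' @param min_rep_length,dominance,apply_filters passed to [coverage()];
#'   filters are off by default here because functional families are often
#'   small.
#' @return A `CoverageResult` (with attributes `representative_id`,
#'   `profile`).
#' @export
subfamily_coverage <- function(family_id, members, annotations, site_type,
                               params = list(), min_rep_length = 100,
                               dominance = 0.5, apply_filters = FALSE) {
  names(members) <- vapply(members, `[[`, "", "domain_id")
  ids <- sort(names(members))
  if (length(ids) == 1L) {
    rep <- members[[ids]]
    alns <- list(identity_alignment(rep))
  } else {
    scores <- setNames(numeric(length(ids)), ids)
    alns <- list()
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        al <- align_structures(members[[ids[i]]], members[[ids[j]]], params)
        alns[[length(alns) + 1L]] <- al
        scores[ids[i]] <- scores[ids[i]] + al$score
        scores[ids[j]] <- scores[ids[j]] + al$score
      }
    }
    rep <- members[[ids[order(-scores, ids)][1]]]
  }
  keep <- vapply(alns, function(a) {
    a$domain_a == rep$domain_id || a$domain_b == rep$domain_id
  }, TRUE)
  profile <- build_profile(family_id, rep, members, alns[keep], annotations)
  out <- coverage(profile, site_type, min_rep_length = min_rep_length,
                  dominance = dominance, apply_filters = apply_filters)
  out$superfamily_id <- family_id
  attr(out, "representative_id") <- rep$domain_id
  attr(out, "profile") <- profile
  attr(out, "single_member") <- length(ids) == 1L
  out
}
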