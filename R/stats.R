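# Enrichment of functional residues among conserved residues, Wilcoxon
# rank-sum testing, and the summary comparisons (diverse vs similar
# coverage; high-coverage proportions).

#' Enrichment of functional residues among conserved residues
#'
#' `Pc` is the proportion of conserved residues that are also functional,
#' `Pa` the proportion of all residues that are functional, and the
#' enrichment `E = Pc - Pa`. A family with no conserved residues has
#' undefined `Pc` and is flagged for exclusion from averaging.
#'
#' @param conserved_residues,functional_residues,all_residues character
#'   vectors of residue identifiers; conserved and functional must be
#'   subsets of all, and all must be non-empty.
#' @param family_id optional identifier carried through to the result.
#' @return Object of class `EnrichmentResult` with `Pc`, `Pa`, `E`,
#'   `excluded`.
#' @export
enrichment <- function(conserved_residues, functional_residues, all_residues,
                       family_id = NA_character_) {
  conserved_residues <- unique(conserved_residues)
  functional_residues <- unique(functional_residues)
  all_residues <- unique(all_residues)
  if (!length(all_residues)) stop("all_residues is empty")
  if (!all(conserved_residues %in% all_residues) ||
      !all(functional_residues %in% all_residues)) {
    stop("conserved and functional residues must be subsets of all residues")
  }
  Pa <- length(functional_residues) / length(all_residues)
  if (!length(conserved_residues)) {
    out <- list(family_id = family_id, Pc = NA_real_, Pa = Pa, E = NA_real_,
                excluded = TRUE)
  } else {
    Pc <- length(intersect(conserved_residues, functional_residues)) /
      length(conserved_residues)
    out <- list(family_id = family_id, Pc = Pc, Pa = Pa, E = Pc - Pa,
                excluded = FALSE)
  }
  structure(out, class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult", x$family_id, "- Pc", round(x$Pc, 4), "Pa",
      round(x$Pa, 4), "E", round(x$E, 4),
      if (x$excluded) "[excluded: no conserved residues]" else "", "\n")
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Thin wrapper with a fixed method rule: the exact distribution is used
#' when both samples have at most 25 observations and the pooled values are
#' tie-free; otherwise the normal approximation with tie correction and 0.5
#' continuity correction. When every pooled value is identical the test is
#' uninformative and p = 1 is returned with a warning.
#'
#' @param sample_x,sample_y numeric vectors (each non-empty).
#' @param alternative `greater` (is x stochastically larger than y?) or
#'   `two_sided`.
#' @return Object of class `TestOutcome`: `statistic` (the rank-sum W as
#'   reported by [stats::wilcox.test()]), `p_value`, `method`
#'   (`exact`/`normal_approx`), `alternative`.
#' @export
wilcoxon_rank_sum <- function(sample_x, sample_y,
                              alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!length(sample_x) || !length(sample_y)) stop("both samples must be non-empty")
  pooled <- c(sample_x, sample_y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; test uninformative")
    return(structure(list(statistic = length(sample_x) * length(sample_y) / 2,
                          p_value = 1, method = "normal_approx",
                          alternative = alternative),
                     class = "TestOutcome"))
  }
  exact <- length(sample_x) <= 25 && length(sample_y) <= 25 &&
    !anyDuplicated(pooled)
  alt <- if (alternative == "two_sided") "two.sided" else "greater"
  wt <- suppressWarnings(wilcox.test(sample_x, sample_y, alternative = alt,
                                     exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value),
                 method = if (exact) "exact" else "normal_approx",
                 alternative = alternative),
            class = "TestOutcome")
}

#' @export
print.TestOutcome <- function(x, ...) {
  cat("TestOutcome: W =", x$statistic, ", p =", signif(x$p_value, 4),
      paste0("(", x$method, ", ", x$alternative, ")"), "\n")
  invisible(x)
}

#' Compare coverage of structurally diverse vs similar superfamilies
#'
#' One-sided (greater) rank-sum test of the coverage values of structurally
#' diverse superfamilies against the rest, asking whether diverse
#' superfamilies have systematically higher site coverage.
#'
#' @param coverages numeric vector of coverage values (or a list of
#'   `CoverageResult` objects).
#' @param diversity_flags logical vector, `TRUE` for structurally diverse.
#' @param alternative passed to [wilcoxon_rank_sum()] (default `greater`).
#' @return A `TestOutcome`.
#' @export
compare_diverse_vs_similar <- function(coverages, diversity_flags,
                                       alternative = "greater") {
  if (is.list(coverages)) {
    coverages <- vapply(coverages, `[[`, 0, "coverage")
  }
  stopifnot(length(coverages) == length(diversity_flags))
  x <- coverages[diversity_flags]
  y <- coverages[!diversity_flags]
  if (!length(x) || !length(y)) {
    stop("both the diverse and the similar group must be non-empty")
  }
  wilcoxon_rank_sum(x, y, alternative = alternative)
}

#' Proportion of superfamilies with high coverage
#'
#' @param coverage_results numeric coverage values, or a list of
#'   `CoverageResult` objects (excluded ones are dropped).
#' @param threshold coverage threshold (default 0.5; strictly greater
#'   counts).
#' @return List with `count`, `total`, `fraction`.
#' @export
high_coverage_proportion <- function(coverage_results, threshold = 0.5) {
  if (is.list(coverage_results)) {
    keep <- !vapply(coverage_results, `[[`, TRUE, "excluded")
    coverage_results <- vapply(coverage_results[keep], `[[`, 0, "coverage")
  }
  if (!length(coverage_results)) stop("no coverage values")
  count <- sum(coverage_results > threshold)
  list(count = count, total = length(coverage_results),
       fraction = count / length(coverage_results))
}

#' Enrichment summary and test over a set of families
#'
#' Computes per-family enrichment, optionally averages family results
#' within superfamilies, and runs the rank-sum test of the Pc values
#' against the Pa values (one-sided: are conserved residues enriched in
#' functional residues?). Families with undefined Pc are excluded and
#' counted.
#'
#' @param results list of `EnrichmentResult` objects.
#' @param superfamily_of optional named character vector mapping family id
#'   to superfamily id; when given, Pc/Pa/E are first averaged per
#'   superfamily (unweighted) and the test runs at superfamily level.
#' @param alternative passed to [wilcoxon_rank_sum()].
#' @return List with `table` (one row per unit), `mean_E`, `test` (a
#'   `TestOutcome`), `n_excluded`.
#' @export
enrichment_test <- function(results, superfamily_of = NULL,
                            alternative = "greater") {
  excluded <- vapply(results, `[[`, TRUE, "excluded")
  res <- results[!excluded]
  if (!length(res)) stop("no families with defined Pc")
  tab <- data.frame(
    family_id = vapply(res, `[[`, "", "family_id"),
    Pc = vapply(res, `[[`, 0, "Pc"),
    Pa = vapply(res, `[[`, 0, "Pa"),
    E = vapply(res, `[[`, 0, "E"))
  if (!is.null(superfamily_of)) {
    sf <- unname(superfamily_of[tab$family_id])
    grp <- split(tab, sf)
    tab <- do.call(rbind, Map(function(g, id) {
      data.frame(family_id = id, Pc = mean(g$Pc), Pa = mean(g$Pa),
                 E = mean(g$E))
    }, grp, names(grp)))
    rownames(tab) <- NULL
  }
  test <- wilcoxon_rank_sum(tab$Pc, tab$Pa, alternative = alternative)
  list(table = tab, mean_E = mean(tab$E), test = test,
       n_excluded = sum(excluded))
}
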