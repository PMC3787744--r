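# Conservation scoring of functional-family alignments: fragment removal,
# a Valdar-style sum-of-pairs scorer with Henikoff sequence weights,
# conserved-residue calling at a 0.7 threshold, and projection of conserved
# columns back onto member structures as a "conserved" site type.

# residue alphabet used by the scorer; gap is its own symbol for weighting
cons_alphabet <- function() c(AA20, "-")

# Pair-similarity matrix: BLOSUM62 with each entry floored at zero and
# divided by the geometric mean of the two diagonal entries, so every
# identical pair scores exactly 1 and dissimilar pairs score 0. Any pair
# involving a gap scores 0.
cons_sim_matrix <- function() {
  b62 <- get_blosum62()[AA20, AA20]
  d <- sqrt(diag(b62))
  m <- pmax(b62, 0) / outer(d, d)
  full <- matrix(0, 21, 21, dimnames = list(cons_alphabet(), cons_alphabet()))
  full[AA20, AA20] <- m
  full
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Henikoff position-based sequence weights, normalised to mean 1.
# Gap is treated as a 21st symbol.
henikoff_weights <- function(mat) {
  n <- nrow(mat)
  w <- numeric(n)
  for (c in seq_len(ncol(mat))) {
    col <- mat[, c]
    tab <- table(col)
    k <- length(tab)
    w <- w + 1 / (k * as.numeric(tab[col]))
  }
  w / mean(w)
}

#' Remove fragment sequences from a functional family
#'
#' Partial sequences (deposition fragments) litter family alignments with
#' gaps and depress conservation scores. A sequence is a fragment when its
#' ungapped length is strictly less than 80\% of the family's mean ungapped
#' length; the mean is computed once over all input sequences, before any
#' removal.
#'
#' @param family_sequences a `FamilyAlignment`, or a (possibly gapped)
#'   named character vector of sequences.
#' @param min_fraction retention threshold as a fraction of the mean length
#'   (default 0.8).
#' @return Same class as the input, restricted to retained sequences, with
#'   attribute `removed` naming the dropped sequences.
#' @export
remove_fragments <- function(family_sequences, min_fraction = 0.8) {
  is_aln <- inherits(family_sequences, "FamilyAlignment")
  seqs <- if (is_aln) family_sequences$rows else family_sequences
  if (length(seqs) < 1L) stop("no sequences")
  len <- nchar(gsub("-", "", seqs))
  cutoff <- min_fraction * mean(len)
  keep <- len >= cutoff
  if (!any(keep)) stop("all sequences removed as fragments")
  removed <- names(seqs)[!keep]
  out <- if (is_aln) {
    new_family_alignment(family_sequences$family_id, seqs[keep],
                         family_sequences$family_kind)
  } else {
    seqs[keep]
  }
  attr(out, "removed") <- removed
  out
}

#' Per-column conservation scores of a family alignment
#'
#' Valdar-style weighted sum of pairs: for column c,
#' `score(c) = sum_{i<j} w_i w_j m(a_ic, a_jc) / sum_{i<j} w_i w_j`, with
#' `m` a normalised BLOSUM62 similarity (identical pair 1, dissimilar or
#' gap-involving pair 0) and `w` the Henikoff position-based sequence
#' weights (mean 1). Scores lie in `[0, 1]`; a gap-free identical column
#' scores exactly 1 and an all-gap column 0. Columns scoring at or above
#' `threshold` are called conserved. Exact duplicate rows are collapsed to
#' one before scoring (redundant identical sequences add no evidence), so
#' scores are invariant both to row order and to appending a copy of the
#' alignment to itself.
#'
#' @param alignment a `FamilyAlignment` with at least 2 rows.
#' @param threshold conservation threshold (default 0.7, chosen empirically
#'   against known functional residues).
#' @return Object of class `ConservationProfile`: `scores` (per column),
#'   `conserved_columns`, `threshold`, `weights`.
#' @export
conservation_scores <- function(alignment, threshold = 0.7) {
  stopifnot(inherits(alignment, "FamilyAlignment"))
  if (length(alignment$rows) < 2L) stop("need at least 2 sequences to score")
  # exact duplicate rows (redundant database entries) carry no information
  # and would otherwise contribute identical-pair terms; keep one of each
  rows <- alignment$rows[!duplicated(unname(alignment$rows))]
  if (length(rows) == 1L) {
    chars <- strsplit(unname(rows), "")[[1]]
    scores <- as.numeric(chars != "-")
    return(structure(list(scores = scores,
                          conserved_columns = which(scores >= threshold),
                          threshold = threshold,
                          weights = setNames(1, names(rows))),
                     class = "ConservationProfile"))
  }
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  mat[!mat %in% cons_alphabet()] <- "-"
  w <- henikoff_weights(mat)
  m <- cons_sim_matrix()
  ww <- outer(w, w)
  denom <- (sum(ww) - sum(w * w)) / 2  # sum over i<j of w_i w_j
  scores <- vapply(seq_len(ncol(mat)), function(c) {
    idx <- match(mat[, c], cons_alphabet())
    pm <- m[idx, idx]
    (sum(ww * pm) - sum(w * w * diag(pm))) / 2 / denom
  }, 0)
  structure(list(scores = scores,
                 conserved_columns = which(scores >= threshold),
                 threshold = threshold,
                 weights = setNames(w, names(rows))),
            class = "ConservationProfile")
}

#' @export
print.ConservationProfile <- function(x, ...) {
  cat("ConservationProfile:", length(x$scores), "columns,",
      length(x$conserved_columns), "conserved at threshold", x$threshold, "\n")
  invisible(x)
}

#' Project conserved columns onto member structures
#'
#' For every alignment row with a matching structure, the residues sitting
#' in conserved columns (where that row is ungapped) become a
#' `SiteAnnotation` of type `conserved`, expressed in the member's own
#' residue identifiers. These annotations can then be mapped onto the
#' representative exactly like experimentally known sites.
#'
#' @param profile a `ConservationProfile`.
#' @param alignment the `FamilyAlignment` it was computed from.
#' @param domains list of `DomainStructure` objects; rows without a
#'   matching domain id (or whose ungapped length disagrees with the
#'   structure) are skipped with a warning.
#' @return List of `SiteAnnotation` objects of type `conserved`.
#' @export
conserved_to_sites <- function(profile, alignment, domains) {
  names(domains) <- vapply(domains, `[[`, "", "domain_id")
  out <- list()
  for (id in names(alignment$rows)) {
    if (!id %in% names(domains)) {
      warning("alignment row ", id, " has no structure; skipped")
      next
    }
    dom <- domains[[id]]
    chars <- strsplit(alignment$rows[[id]], "")[[1]]
    ungapped <- chars != "-"
    if (sum(ungapped) != dom$length) {
      warning("row ", id, " length disagrees with structure; skipped")
      next
    }
    respos <- cumsum(ungapped)  # alignment column -> residue index
    idx <- respos[intersect(profile$conserved_columns, which(ungapped))]
    if (!length(idx)) next
    out[[length(out) + 1L]] <- new_site_annotation(
      id, "conserved",
      data.frame(chain = dom$chain[idx], number = dom$number[idx],
                 icode = dom$icode[idx]),
      evidence_ids = alignment$family_id)
  }
  out
}

#' Proportion of functional residues recovered by conserved residues
#'
#' Over all residues of all family members: the size of the intersection of
#' functional and conserved residue sets, divided by the number of
#' functional residues. `NA` (undefined) when no functional residues exist.
#'
#' @param conserved_sites list of `SiteAnnotation` objects of type
#'   `conserved`.
#' @param functional_sites list of `SiteAnnotation` objects.
#' @param site_type functional site type to compare against.
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
overlap_proportion <- function(conserved_sites, functional_sites, site_type) {
  fun <- Filter(function(a) a$site_type == site_type, functional_sites)
  fun_keys <- unlist(lapply(fun, function(a) {
    paste0(a$domain_id, "/", annotation_keys(a))
  }))
  fun_keys <- unique(fun_keys)
  if (!length(fun_keys)) return(NA_real_)
  cons_keys <- unique(unlist(lapply(conserved_sites, function(a) {
    paste0(a$domain_id, "/", annotation_keys(a))
  })))
  length(intersect(fun_keys, cons_keys)) / length(fun_keys)
}
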