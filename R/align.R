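# Pairwise structural alignment: Kabsch superposition, an iterative
# superposition-DP aligner, the 0-100 similarity score, and normalised RMSD.
#
# The aligner treats structure comparison the way the field's classic tools
# do at CA level: seed a residue correspondence (from a global sequence
# alignment when sequences are available, else from the best gapless offset
# of centroid-distance profiles), then iterate {rigid superposition on the
# current pairs -> distance-based score matrix s(i,j) = 1/(1+(d_ij/d0)^2)
# with d0 = 3.8 A -> global dynamic programming with linear gap penalty
# 0.1 -> new pairs} until the pair set stabilises.

#' Construct a StructuralAlignment
#'
#' @param domain_a,domain_b domain ids.
#' @param pairs two-column integer matrix of aligned positions (1-based,
#'   strictly increasing in both columns).
#' @param rmsd RMSD (Angstrom) over aligned CA pairs after optimal
#'   superposition.
#' @param score similarity score in `[0, 100]`.
#' @param converged logical; `FALSE` when the aligner stopped at its
#'   iteration cap without the pair set stabilising.
#' @return Object of class `StructuralAlignment`.
#' @export
new_alignment <- function(domain_a, domain_b, pairs, rmsd, score = NA_real_,
                          converged = TRUE) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) < 1L) stop("an alignment needs at least one residue pair")
  if (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0)) {
    stop("alignment pairs must be strictly increasing in both columns")
  }
  dimnames(pairs) <- NULL
  structure(list(domain_a = as.character(domain_a),
                 domain_b = as.character(domain_b),
                 pairs = pairs,
                 rmsd = rmsd,
                 n_aligned = nrow(pairs),
                 score = score,
                 converged = converged),
            class = "StructuralAlignment")
}

#' @export
print.StructuralAlignment <- function(x, ...) {
  cat("StructuralAlignment", x$domain_a, "vs", x$domain_b, "\n  ",
      x$n_aligned, "pairs, rmsd", round(x$rmsd, 3), "A, score",
      round(x$score, 1), "\n")
  invisible(x)
}

# swap the two sides of an alignment
mirror_alignment <- function(al) {
  new_alignment(al$domain_b, al$domain_a, al$pairs[, 2:1, drop = FALSE],
                rmsd = al$rmsd, score = al$score, converged = al$converged)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two equal-length coordinate sets; apply as `coords_b %*% t(rotation)`
#' plus `translation` to superpose set B onto set A.
#'
#' @param coords_a,coords_b n x 3 numeric matrices, n >= 3, not collinear.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3), and `rmsd`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate sets differ in length")
  if (nrow(coords_a) < 3) stop("need at least 3 points")
  out <- kabsch_cpp(coords_a, coords_b)
  out$translation <- as.numeric(out$translation)
  out
}

# seed correspondence from a global sequence alignment (plain NW over
# BLOSUM62 with a linear gap penalty; the correspondence is only a seed and
# is refined structurally, so affine gaps are not needed here)
seed_pairs_sequence <- function(seq_a, seq_b) {
  b62 <- blosum62_cached()
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  x <- match(a, rownames(b62))
  y <- match(b, colnames(b62))
  x[is.na(x)] <- match("X", rownames(b62))
  y[is.na(y)] <- match("X", colnames(b62))
  S <- b62[x, y, drop = FALSE]
  nw_pairs_cpp(S, gap = 4)
}

# seed correspondence from the best gapless offset of centroid-distance
# profiles (fallback when no sequences are available)
seed_pairs_offset <- function(xyz_a, xyz_b) {
  prof <- function(x) sqrt(colSums((t(x) - colMeans(x))^2))
  pa <- prof(xyz_a)
  pb <- prof(xyz_b)
  na <- length(pa)
  nb <- length(pb)
  best <- NULL
  best_msd <- Inf
  for (off in (-(nb - 3)):(na - 3)) {
    ia <- max(1, 1 + off):min(na, nb + off)
    ib <- ia - off
    if (length(ia) < 3) next
    msd <- mean((pa[ia] - pb[ib])^2)
    if (msd < best_msd) {
      best_msd <- msd
      best <- cbind(ia, ib)
    }
  }
  best
}

#' Align two domain structures
#'
#' Iterative superposition-DP alignment of the CA traces of two domains
#' (see the package vignette for the algorithm and its parameters). The
#' result is deterministic for fixed inputs, symmetric in its arguments
#' (swapping them mirrors the pairs and leaves RMSD and score unchanged),
#' and a self-alignment returns the identity pairing with RMSD 0 and
#' score 100.
#'
#' @param dom_a,dom_b `DomainStructure` objects with at least 3 residues.
#' @param params optional list overriding `d0` (3.8), `gap` (0.1),
#'   `max_iter` (20), and `seed_pairs` (a precomputed two-column matrix of
#'   1-based seed pairs, positions of `dom_a` in column 1).
#' @return A `StructuralAlignment`; `converged = FALSE` (with a warning)
#'   when the pair set had not stabilised after `max_iter` iterations.
#' @export
align_structures <- function(dom_a, dom_b, params = list()) {
  if (dom_a$length < 3 || dom_b$length < 3) stop("domains need >= 3 residues")
  p <- utils::modifyList(list(d0 = 3.8, gap = 0.1, max_iter = 20,
                              seed_pairs = NULL), params)
  # canonical orientation: smaller id first, so the result is symmetric
  flip <- dom_a$domain_id > dom_b$domain_id
  if (flip) {
    tmp <- dom_a; dom_a <- dom_b; dom_b <- tmp
    if (!is.null(p$seed_pairs)) p$seed_pairs <- p$seed_pairs[, 2:1, drop = FALSE]
  }
  seeds <- list()
  if (!is.null(p$seed_pairs)) {
    seeds <- list(p$seed_pairs)
  } else {
    have_seq <- !anyNA(dom_a$aa) && !anyNA(dom_b$aa)
    base <- if (have_seq) {
      seed_pairs_sequence(domain_sequence(dom_a), domain_sequence(dom_b))
    } else {
      seed_pairs_offset(dom_a$xyz, dom_b$xyz)
    }
    if (is.null(base) || nrow(base) < 3) {
      base <- seed_pairs_offset(dom_a$xyz, dom_b$xyz)
    }
    # full seed plus fragment seeds (thirds of the chain): when the two
    # domains differ by a hinge no single frame fits the whole seed, and a
    # fragment seed anchored in the rigid part escapes the compromise fit
    seeds <- list(base)
    n <- nrow(base)
    if (n >= 30) {
      cuts <- list(1:floor(n / 3),
                   (floor(n / 3) + 1):floor(2 * n / 3),
                   (floor(2 * n / 3) + 1):n)
      for (idx in cuts) seeds[[length(seeds) + 1L]] <- base[idx, , drop = FALSE]
    }
  }
  res <- NULL
  for (seed in seeds) {
    cand <- align_iterate_cpp(dom_a$xyz, dom_b$xyz, seed,
                              p$d0, p$gap, p$max_iter)
    if (is.null(res) || cand$n_close > res$n_close ||
        (cand$n_close == res$n_close && cand$rmsd < res$rmsd)) {
      res <- cand
    }
  }
  if (!res$converged) {
    warning("alignment of ", dom_a$domain_id, " vs ", dom_b$domain_id,
            " did not converge in ", p$max_iter, " iterations; ",
            "returning best-so-far")
  }
  rmsd <- res$rmsd
  if (rmsd < 1e-9) rmsd <- 0
  al <- new_alignment(dom_a$domain_id, dom_b$domain_id, res$pairs,
                      rmsd = rmsd, converged = res$converged)
  al$score <- similarity_score(al, dom_a$length, dom_b$length, d0 = p$d0)
  if (flip) mirror_alignment(al) else al
}

#' Structural similarity score (0-100)
#'
#' `score = 100 * (n_aligned / max(len_a, len_b)) / (1 + (rmsd/d0)^2)`:
#' 100 iff identical structures fully aligned at RMSD 0, monotonically
#' decreasing in RMSD at fixed alignment length and increasing in alignment
#' length at fixed RMSD, and symmetric in the two domains. Only the ranking
#' matters downstream (representative selection).
#'
#' @param alignment a `StructuralAlignment`.
#' @param len_a,len_b domain lengths (residues).
#' @param d0 distance scale in Angstrom.
#' @return Numeric score in `[0, 100]`.
#' @export
similarity_score <- function(alignment, len_a, len_b, d0 = 3.8) {
  s <- 100 * (alignment$n_aligned / max(len_a, len_b)) /
    (1 + (alignment$rmsd / d0)^2)
  min(100, s)
}

#' Normalised RMSD
#'
#' RMSD multiplied by the length of the larger domain in the pair and
#' divided by the number of aligned residue pairs; penalises short
#' alignments between long domains, so that a high plain RMSD over a small
#' common core is not mistaken for similarity.
#'
#' @param rmsd RMSD in Angstrom.
#' @param len_a,len_b domain lengths.
#' @param n_aligned number of aligned residue pairs (>= 1).
#' @return Normalised RMSD in Angstrom.
#' @export
normalised_rmsd <- function(rmsd, len_a, len_b, n_aligned) {
  if (length(n_aligned) != 1L || n_aligned < 1) {
    stop("n_aligned must be a positive count")
  }
  stopifnot(len_a >= 1, len_b >= 1, rmsd >= 0)
  rmsd * max(len_a, len_b) / n_aligned
}

# normalised RMSD straight from an alignment object
alignment_nrmsd <- function(al, len_a, len_b) {
  normalised_rmsd(al$rmsd, len_a, len_b, al$n_aligned)
}
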