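# Subfamily (s60) clustering by sequence identity and structural clustering
# by normalised RMSD.

#' Construct a ClusterSet
#'
#' @param kind `s60` (sequence) or `structural`.
#' @param clusters named list of character vectors of domain ids; names are
#'   cluster ids. Clusters must partition the domain set.
#' @param parameter the identity threshold (s60) or normalised-RMSD cutoff
#'   in Angstrom (structural).
#' @return Object of class `ClusterSet`.
#' @export
new_cluster_set <- function(kind, clusters, parameter) {
  kind <- match.arg(kind, c("s60", "structural"))
  ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(ids)) stop("clusters overlap: not a partition")
  if (length(clusters) < 1L) stop("need at least one cluster")
  if (is.null(names(clusters))) {
    names(clusters) <- sprintf("%s_%03d", kind, seq_along(clusters))
  }
  membership <- setNames(rep(names(clusters), lengths(clusters)), ids)
  structure(list(kind = kind, clusters = clusters, parameter = parameter,
                 membership = membership,
                 n_clusters = length(clusters)),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat("ClusterSet (", x$kind, "): ", x$n_clusters, " clusters over ",
      length(x$membership), " domains (parameter ", x$parameter, ")\n",
      sep = "")
  invisible(x)
}

#' Pairwise sequence identity
#'
#' Global Needleman-Wunsch alignment (BLOSUM62, gap opening 10, extension
#' 0.5); identity is the number of identical aligned positions divided by
#' the length of the shorter sequence (the convention of the common greedy
#' clustering tools).
#'
#' @param seq_a,seq_b character strings (one-letter amino-acid codes).
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b,
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  Biostrings::pid(pa, type = "PID3") / 100
}

#' Cluster superfamily members at 60% sequence identity
#'
#' Greedy longest-first clustering: domains are visited in order of
#' decreasing sequence length (ties by id), and each joins the first
#' existing cluster whose seed is at least `threshold` identical to it,
#' else seeds a new cluster. Deterministic given the input; duplicated
#' records are ignored.
#'
#' @param domains list of `DomainStructure` objects with sequences.
#' @param threshold identity threshold (default 0.60).
#' @return A `ClusterSet` of kind `s60`.
#' @export
cluster_s60 <- function(domains, threshold = 0.60) {
  ids <- vapply(domains, `[[`, "", "domain_id")
  domains <- domains[!duplicated(ids)]
  ids <- ids[!duplicated(ids)]
  seqs <- vapply(domains, domain_sequence, "")
  ord <- order(-nchar(seqs), ids)
  seeds <- integer()      # index of each cluster's seed domain
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(seeds)) {
      if (sequence_identity(seqs[seeds[k]], seqs[i]) >= threshold) {
        clusters[[k]] <- c(clusters[[k]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, i)
      clusters <- c(clusters, list(ids[i]))
    }
  }
  names(clusters) <- sprintf("s60_%03d", seq_along(clusters))
  new_cluster_set("s60", clusters, parameter = threshold)
}

#' Cluster domains by structural similarity
#'
#' Single-linkage agglomerative clustering on normalised RMSD: two domains
#' share a cluster iff they are connected by a chain of pairs with
#' normalised RMSD strictly below `cutoff`. The usual cutoffs are 9.0 A
#' (the default used to call a superfamily structurally diverse) and 5.0 A.
#'
#' @param domains list of `DomainStructure` objects.
#' @param alignments list of `StructuralAlignment` objects covering every
#'   unordered pair of domains.
#' @param cutoff normalised-RMSD cutoff in Angstrom.
#' @return A `ClusterSet` of kind `structural`.
#' @export
cluster_structures <- function(domains, alignments, cutoff = 9.0) {
  ids <- vapply(domains, `[[`, "", "domain_id")
  names(domains) <- ids
  n <- length(ids)
  if (n == 1L) {
    return(new_cluster_set("structural", list(str_001 = ids), cutoff))
  }
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(M) <- 0
  for (al in alignments) {
    if (!al$domain_a %in% ids || !al$domain_b %in% ids) next
    v <- alignment_nrmsd(al, domains[[al$domain_a]]$length,
                         domains[[al$domain_b]]$length)
    M[al$domain_a, al$domain_b] <- v
    M[al$domain_b, al$domain_a] <- v
  }
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("no alignment for pair ", ids[miss[1]], " / ", ids[miss[2]])
  }
  tree <- hclust(as.dist(M), method = "single")
  grp <- cutree(tree, h = cutoff - 1e-9)  # strict '< cutoff' chains
  clusters <- split(ids, grp)
  names(clusters) <- sprintf("str_%03d", seq_along(clusters))
  new_cluster_set("structural", clusters, cutoff)
}

#' Is a superfamily structurally diverse?
#'
#' A superfamily is structurally diverse when its members fall into at
#' least two structural clusters at the chosen normalised-RMSD cutoff.
#'
#' @param cluster_set a `ClusterSet` of kind `structural`.
#' @return Logical.
#' @export
is_structurally_diverse <- function(cluster_set) {
  stopifnot(inherits(cluster_set, "ClusterSet"), cluster_set$kind == "structural")
  cluster_set$n_clusters >= 2L
}
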