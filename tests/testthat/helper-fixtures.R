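# Shared fixture builders and independent brute-force oracles. Oracles are
# written as plain loops, deliberately separate from the package's
# vectorised implementations.

# toy domain on a straight-ish line; geometry is irrelevant where
# alignments are supplied by hand
toy_domain <- function(id, n, sf = "SF") {
  new_domain(id, sf, chain = rep("A", n), number = seq_len(n),
             icode = rep("", n), aa = rep("A", n),
             xyz = cbind(seq_len(n) * 3.8, (seq_len(n) %% 2) * 0.5, 0))
}

# random strictly monotone alignment between two toy domains
random_alignment <- function(da, db, k = NULL) {
  kmax <- min(da$length, db$length)
  if (is.null(k)) k <- sample(3:kmax, 1)
  new_alignment(da$domain_id, db$domain_id,
                cbind(sort(sample(da$length, k)), sort(sample(db$length, k))),
                rmsd = runif(1, 0.2, 3), score = runif(1, 20, 90))
}

# a random small mapping instance: profile plus the raw pieces an oracle
# needs (alignments, annotations, cluster assignment)
random_profile_instance <- function(seed) {
  set.seed(seed)
  L <- sample(15:30, 1)
  nm <- sample(3:8, 1)
  rep_dom <- toy_domain("rep", L)
  members <- list(rep_dom)
  for (i in seq_len(nm)) {
    members[[i + 1]] <- toy_domain(sprintf("m%02d", i), sample(10:25, 1))
  }
  names(members) <- vapply(members, `[[`, "", "domain_id")
  ncl <- sample(2:min(nm + 1, 5), 1)
  assign <- sample(ncl, nm + 1, replace = TRUE)
  clusters <- split(names(members), assign)
  names(clusters) <- sprintf("cl%02d", seq_along(clusters))
  s60 <- new_cluster_set("s60", clusters, 0.6)
  alignments <- list()
  for (i in seq_len(nm)) {
    m <- members[[i + 1]]
    alignments[[i]] <- random_alignment(m, rep_dom,
                                        k = sample(3:min(L, m$length), 1))
  }
  annotations <- list()
  for (i in seq_len(nm + 1)) {
    if (runif(1) < 0.8) {
      m <- members[[i]]
      idx <- sort(sample(m$length, sample(1:6, 1)))
      annotations[[length(annotations) + 1]] <- new_site_annotation(
        m$domain_id, "protein_protein",
        data.frame(chain = "A", number = idx, icode = ""), "e1")
    }
  }
  profile <- build_profile("SF", rep_dom, members, alignments, annotations,
                           s60)
  list(profile = profile, rep = rep_dom, members = members,
       alignments = alignments, annotations = annotations, s60 = s60, L = L)
}

# oracle: map one member's annotated residues by walking the pair list
oracle_mapped_positions <- function(inst, ann) {
  if (ann$domain_id == "rep") {
    return(ann$residues$number)
  }
  al <- NULL
  for (a in inst$alignments) {
    if (a$domain_a == ann$domain_id || a$domain_b == ann$domain_id) al <- a
  }
  out <- integer()
  for (r in ann$residues$number) {
    for (p in seq_len(nrow(al$pairs))) {
      mp <- if (al$domain_a == ann$domain_id) al$pairs[p, 1] else al$pairs[p, 2]
      rp <- if (al$domain_a == ann$domain_id) al$pairs[p, 2] else al$pairs[p, 1]
      if (mp == r) out <- c(out, rp)
    }
  }
  sort(unique(out))
}

# oracle: coverage as the union over (member, residue) mappings
oracle_coverage <- function(inst) {
  covered <- integer()
  for (ann in inst$annotations) {
    covered <- union(covered, oracle_mapped_positions(inst, ann))
  }
  length(covered) / inst$L
}

# oracle: colocation by exhaustive position scan
oracle_colocation <- function(inst) {
  cl_of <- inst$s60$membership
  with_data <- unique(unname(cl_of[vapply(inst$annotations, `[[`, "",
                                          "domain_id")]))
  hits <- matrix(FALSE, inst$L, length(with_data),
                 dimnames = list(NULL, with_data))
  for (ann in inst$annotations) {
    pos <- oracle_mapped_positions(inst, ann)
    hits[pos, cl_of[ann$domain_id]] <- TRUE
  }
  best <- 0
  for (p in seq_len(inst$L)) {
    best <- max(best, sum(hits[p, ]) / length(with_data))
  }
  best
}

# oracle: connected components of the thresholded graph (BFS)
oracle_components <- function(M, cutoff) {
  n <- nrow(M)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in seq_len(n)) {
        if (is.na(comp[u]) && M[v, u] < cutoff) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

# oracle: exact Wilcoxon rank-sum p by full enumeration of rank assignments
oracle_wilcoxon <- function(x, y, alternative) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ws <- apply(combn(n + m, n), 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  if (alternative == "greater") {
    mean(ws >= W)
  } else {
    min(1, 2 * min(mean(ws >= W), mean(ws <= W)))
  }
}

# partitions as canonical sorted list-of-sets for comparison
canonical_partition <- function(clusters) {
  out <- unname(lapply(clusters, function(x) sort(unname(x))))
  out[order(vapply(out, `[`, "", 1))]
}

# measured coverage + diversity for a cohort, then the group comparison
cohort_pvalue <- function(cohort, cfgrun = run_config(nrmsd_cutoffs = 9.0)) {
  covs <- numeric()
  flags <- logical()
  for (sim in cohort) {
    s60 <- siteplast:::clusters_from_table(sim$families)
    an <- suppressWarnings(
      analyse_superfamily(sim$domains, sim$annotations, cfgrun, s60))
    if (an$exclusion != "pass") next
    covs <- c(covs, an$coverages$protein_protein$coverage)
    flags <- c(flags, an$diverse)
  }
  compare_diverse_vs_similar(covs, flags)$p_value
}
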