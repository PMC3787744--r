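# Tabular interchange: site annotations, family membership, pairwise
# alignment TSVs, FASTA sequences.

#' Read functional-site annotations from TSV
#'
#' Expected columns: `domain_id`, `site_type`, `chain`, `resnum`, `icode`,
#' `evidence_id`, and optionally a logical `biologically_relevant` column
#' (rows with `FALSE` are dropped; upstream curation is assumed to have
#' produced it). Rows for the same `(domain_id, site_type)` are merged by
#' residue-set union, so every structure of a protein contributes to one
#' annotation. Rows whose residue does not resolve against the named domain
#' (or whose domain is unknown) are rejected, counted, and reported.
#'
#' @param path TSV path.
#' @param domains list of `DomainStructure` objects the annotations refer to.
#' @return List of `SiteAnnotation` objects, with attributes `n_rejected`
#'   (count of rejected rows) and `rejected` (a data.frame describing them).
#' @export
read_site_annotations <- function(path, domains) {
  tab <- read.delim(path, colClasses = "character")
  need <- c("domain_id", "site_type", "chain", "resnum", "icode", "evidence_id")
  if (!all(need %in% names(tab))) {
    stop("site annotation table must have columns: ", paste(need, collapse = ", "))
  }
  if ("biologically_relevant" %in% names(tab)) {
    tab <- tab[toupper(tab$biologically_relevant) != "FALSE", , drop = FALSE]
  }
  bad_type <- setdiff(unique(tab$site_type), SITE_TYPES)
  if (length(bad_type)) {
    stop("unknown site_type: ", paste(bad_type, collapse = ", "))
  }
  tab$icode[is.na(tab$icode)] <- ""
  annotations_from_table(tab, domains)
}

# shared core: merge + validate a site-annotation data.frame
annotations_from_table <- function(tab, domains) {
  names(domains) <- vapply(domains, `[[`, "", "domain_id")
  ok <- rep(TRUE, nrow(tab))
  reason <- rep(NA_character_, nrow(tab))
  known <- tab$domain_id %in% names(domains)
  ok[!known] <- FALSE
  reason[!known] <- "unknown domain"
  for (i in which(known)) {
    dom <- domains[[tab$domain_id[i]]]
    k <- residue_key(tab$chain[i], as.integer(tab$resnum[i]), tab$icode[i])
    if (!k %in% domain_keys(dom)) {
      ok[i] <- FALSE
      reason[i] <- paste0("residue ", k, " not in domain")
    }
  }
  rejected <- data.frame(row = which(!ok),
                         domain_id = tab$domain_id[!ok],
                         reason = reason[!ok])
  if (nrow(rejected)) {
    message(nrow(rejected), " annotation row(s) rejected (unresolvable residues)")
  }
  tab <- tab[ok, , drop = FALSE]
  out <- list()
  if (nrow(tab)) {
    grp <- split(tab, paste(tab$domain_id, tab$site_type, sep = "\r"))
    out <- lapply(grp, function(g) {
      new_site_annotation(g$domain_id[1], g$site_type[1],
                          data.frame(chain = g$chain,
                                     number = as.integer(g$resnum),
                                     icode = g$icode),
                          evidence_ids = g$evidence_id)
    })
    names(out) <- NULL
  }
  attr(out, "n_rejected") <- nrow(rejected)
  attr(out, "rejected") <- rejected
  out
}

#' Write site annotations to TSV
#'
#' One row per (residue, evidence record); the inverse of
#' [read_site_annotations()] up to row order.
#'
#' @param annotations list of `SiteAnnotation` objects.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_site_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    ev <- if (length(a$evidence_ids)) a$evidence_ids else "unknown"
    do.call(rbind, lapply(ev, function(e) {
      data.frame(domain_id = a$domain_id, site_type = a$site_type,
                 chain = a$residues$chain, resnum = a$residues$number,
                 icode = a$residues$icode, evidence_id = e)
    }))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a family-membership table
#'
#' Columns: `domain_id`, `superfamily_id`, and optionally `s60_cluster_id`
#' and `funfam_id`.
#'
#' @param path TSV path.
#' @return data.frame with one row per domain.
#' @export
read_family_table <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  if (!all(c("domain_id", "superfamily_id") %in% names(tab))) {
    stop("family table needs columns domain_id and superfamily_id")
  }
  for (col in c("s60_cluster_id", "funfam_id")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab
}

#' @rdname read_family_table
#' @param table data.frame as returned by [read_family_table()].
#' @export
write_family_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pairwise structural alignments from interchange TSV
#'
#' Each alignment block starts with header lines `#score`, `#rmsd`,
#' `#n_aligned` (tab-separated value after the tag), followed by one row
#' per aligned residue pair: `domain_a chain_a resnum_a icode_a domain_b
#' chain_b resnum_b icode_b`. Several blocks may be concatenated in one
#' file. Residue identities are converted to positional indices against
#' `domains`, so precomputed alignments (e.g. converted SSAP or TM-align
#' output) can stand in for the built-in aligner.
#'
#' @param path TSV path.
#' @param domains list of `DomainStructure` objects covering every domain id
#'   named in the file.
#' @return List of `StructuralAlignment` objects.
#' @export
read_alignment_tsv <- function(path, domains) {
  names(domains) <- vapply(domains, `[[`, "", "domain_id")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^#score", lines)
  if (!length(starts)) stop("no '#score' header found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    hdr <- function(tag) {
      ln <- grep(paste0("^#", tag), block, value = TRUE)[1]
      as.numeric(strsplit(ln, "\t")[[1]][2])
    }
    rows <- block[!startsWith(block, "#")]
    f <- do.call(rbind, lapply(strsplit(rows, "\t"), function(x) {
      length(x) <- 8  # trailing blank insertion codes drop off strsplit
      x
    }))
    f[is.na(f)] <- ""
    da <- f[1, 1]; db <- f[1, 5]
    if (!da %in% names(domains) || !db %in% names(domains)) {
      stop("alignment references unknown domain: ",
           paste(setdiff(c(da, db), names(domains)), collapse = ", "))
    }
    ia <- match(residue_key(f[, 2], as.integer(f[, 3]), f[, 4]),
                domain_keys(domains[[da]]))
    ib <- match(residue_key(f[, 6], as.integer(f[, 7]), f[, 8]),
                domain_keys(domains[[db]]))
    if (anyNA(ia) || anyNA(ib)) {
      stop("alignment row references residue absent from structure (block ", b, ")")
    }
    out[[b]] <- new_alignment(da, db, cbind(ia, ib),
                              rmsd = hdr("rmsd"), score = hdr("score"))
  }
  out
}

#' @rdname read_alignment_tsv
#' @param alignments list of `StructuralAlignment` objects.
#' @export
write_alignment_tsv <- function(alignments, domains, path) {
  names(domains) <- vapply(domains, `[[`, "", "domain_id")
  con <- file(path, "w")
  on.exit(close(con))
  for (al in alignments) {
    a <- domains[[al$domain_a]]; b <- domains[[al$domain_b]]
    writeLines(c(paste0("#score\t", al$score),
                 paste0("#rmsd\t", al$rmsd),
                 paste0("#n_aligned\t", al$n_aligned)), con)
    ia <- al$pairs[, 1]; ib <- al$pairs[, 2]
    writeLines(paste(al$domain_a, a$chain[ia], a$number[ia], a$icode[ia],
                     al$domain_b, b$chain[ib], b$number[ib], b$icode[ib],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read sequences or an aligned family FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of (possibly gapped) sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Construct a family alignment object
#'
#' @param family_id family identifier.
#' @param rows named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @param family_kind `funfam` (coarse) or `finefam` (fine) partition.
#' @return Object of class `FamilyAlignment`.
#' @export
new_family_alignment <- function(family_id, rows, family_kind = "funfam") {
  family_kind <- match.arg(family_kind, c("funfam", "finefam"))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("alignment rows need unique sequence ids")
  }
  structure(list(family_id = family_id, family_kind = family_kind,
                 rows = rows, columns = w),
            class = "FamilyAlignment")
}

#' @export
print.FamilyAlignment <- function(x, ...) {
  cat("FamilyAlignment", x$family_id, paste0("(", x$family_kind, "):"),
      length(x$rows), "sequences x", x$columns, "columns\n")
  invisible(x)
}
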