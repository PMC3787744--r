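# PDB-format input/output (CA level), via bio3d.

#' Read a domain structure from a PDB file
#'
#' Reads CA atoms only, in file order, from the first model. Alternate
#' locations are resolved to the highest-occupancy record (ties: first in
#' file). Non-CA atoms and HETATM records are ignored.
#'
#' @param path path to a PDB-format file.
#' @param domain_id identifier to assign to the domain.
#' @param superfamily_id identifier of the superfamily the domain belongs to.
#'
#' @return A [new_domain()] `DomainStructure`.
#' @export
read_domain_pdb <- function(path, domain_id, superfamily_id) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no CA atoms in ", path)
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- residue_key(at$chain, at$resno, at$insert)
  # altloc: per residue keep the highest-occupancy record; a residue with
  # several CA records sharing the same altloc indicator is malformed
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(i) {
    if (anyDuplicated(at$alt[i])) {
      stop("duplicate CA records for residue ", key[i[1]], " in ", path)
    }
    i[which.max(at$o[i])]
  }), use.names = FALSE)
  keep <- sort(keep)  # preserve file order
  at <- at[keep, , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa)] <- "X"
  new_domain(domain_id, superfamily_id,
             chain = at$chain, number = at$resno, icode = at$insert, aa = aa,
             xyz = cbind(at$x, at$y, at$z))
}

#' Write a domain structure as a CA-only PDB file
#'
#' @param dom a `DomainStructure`.
#' @param path output path.
#' @param b optional numeric vector of per-residue B-factors.
#' @return Invisibly, `path`.
#' @export
write_domain_pdb <- function(dom, path, b = NULL) {
  if (is.null(b)) b <- rep(0, dom$length)
  stopifnot(length(b) == dom$length)
  resid <- bio3d::aa123(dom$aa)
  resid[is.na(resid) | resid == "X"] <- "UNK"
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(dom$xyz)),
                   type = rep("ATOM", dom$length),
                   resno = dom$number,
                   resid = resid,
                   chain = dom$chain,
                   insert = ifelse(dom$icode == "", "", dom$icode),
                   elety = rep("CA", dom$length),
                   o = rep(1, dom$length),
                   b = b)
  invisible(path)
}

#' Write a representative coloured by per-position site frequency
#'
#' Writes the representative as a PDB file whose B-factor column holds the
#' per-position fraction of contributing members (scaled to 0-100, two
#' decimals), plus a companion TSV with the exact fractions. Loading the PDB
#' in a molecular viewer and colouring by B-factor reproduces the usual
#' site-frequency heat map on the structure.
#'
#' @param rep_domain the representative `DomainStructure`.
#' @param per_position_fraction numeric vector in `[0, 1]`, one value per
#'   representative position.
#' @param path output PDB path; the companion table is written to
#'   `paste0(path, ".tsv")`.
#' @return Invisibly, `path`.
#' @export
write_profile_pdb <- function(rep_domain, per_position_fraction, path) {
  f <- per_position_fraction
  if (length(f) != rep_domain$length) {
    stop("length mismatch: representative has ", rep_domain$length,
         " residues but ", length(f), " fractions were supplied")
  }
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  write_domain_pdb(rep_domain, path, b = round(f * 100, 2))
  tab <- data.frame(position = seq_len(rep_domain$length),
                    chain = rep_domain$chain,
                    number = rep_domain$number,
                    icode = rep_domain$icode,
                    fraction = f)
  write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
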