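# Core containers: DomainStructure and SiteAnnotation.
#
# A DomainStructure is an ordered list of CA residues. Residue identity on
# disk follows PDB author numbering (chain, number, insertion code); inside
# the package residues are addressed by their dense 1-based position in file
# order.

#' Construct a DomainStructure
#'
#' @param domain_id character scalar, domain identifier.
#' @param superfamily_id character scalar, superfamily identifier.
#' @param chain character vector of one-character chain ids.
#' @param number integer vector of author residue numbers.
#' @param icode character vector of insertion codes ("" when absent).
#' @param aa character vector of one-letter amino-acid codes.
#' @param xyz numeric matrix, one CA coordinate per residue (n x 3, Angstrom).
#' @param s60_cluster_id optional sequence-cluster id (NA before clustering).
#'
#' @return An object of class `DomainStructure`: residues are ordered, the
#'   positional index is 1-based and dense, and `(chain, number, icode)` is
#'   unique within the domain.
#' @export
new_domain <- function(domain_id, superfamily_id, chain, number, icode, aa,
                       xyz, s60_cluster_id = NA_character_) {
  xyz <- as.matrix(xyz)
  n <- length(aa)
  if (n < 1L) stop("a domain needs at least one residue")
  stopifnot(length(chain) == n, length(number) == n, length(icode) == n,
            nrow(xyz) == n, ncol(xyz) == 3)
  icode[is.na(icode)] <- ""
  key <- residue_key(chain, number, icode)
  if (anyDuplicated(key)) {
    stop("duplicate residue identity in domain ", domain_id, ": ",
         key[duplicated(key)][1])
  }
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  structure(list(domain_id = as.character(domain_id),
                 superfamily_id = as.character(superfamily_id),
                 s60_cluster_id = s60_cluster_id,
                 chain = as.character(chain),
                 number = as.integer(number),
                 icode = as.character(icode),
                 aa = as.character(aa),
                 xyz = xyz,
                 length = n),
            class = "DomainStructure")
}

# canonical string key for a residue identity, vectorised
residue_key <- function(chain, number, icode = "") {
  if (!length(chain)) return(character(0))
  icode[is.na(icode) | icode == " "] <- ""
  paste0(chain, ":", number, icode)
}

domain_keys <- function(dom) residue_key(dom$chain, dom$number, dom$icode)

#' Amino-acid sequence of a domain
#'
#' @param dom a `DomainStructure`.
#' @return Single character string of one-letter codes, in residue order.
#' @export
domain_sequence <- function(dom) paste0(dom$aa, collapse = "")

#' @export
print.DomainStructure <- function(x, ...) {
  cat("DomainStructure", x$domain_id, "(superfamily", paste0(x$superfamily_id, ")"),
      "\n  residues:", x$length,
      "\n  chains:", paste(unique(x$chain), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.DomainStructure <- function(x) x$length

#' Construct a SiteAnnotation
#'
#' Typed functional residues of one domain; the residue set is the union
#' over all evidence records (all deposited structures of the protein).
#'
#' @param domain_id domain the annotation belongs to.
#' @param site_type one of `catalytic`, `protein_protein`, `nucleic_acid`,
#'   `small_ligand`, `conserved`.
#' @param residues data.frame with columns `chain`, `number`, `icode`.
#' @param evidence_ids character vector of evidence record identifiers.
#'
#' @return An object of class `SiteAnnotation`.
#' @export
new_site_annotation <- function(domain_id, site_type, residues,
                                evidence_ids = character()) {
  site_type <- match.arg(site_type, SITE_TYPES)
  residues$icode[is.na(residues$icode)] <- ""
  key <- residue_key(residues$chain, residues$number, residues$icode)
  residues <- residues[!duplicated(key), c("chain", "number", "icode"), drop = FALSE]
  rownames(residues) <- NULL
  residues$number <- as.integer(residues$number)
  structure(list(domain_id = as.character(domain_id),
                 site_type = site_type,
                 residues = residues,
                 evidence_ids = sort(unique(as.character(evidence_ids)))),
            class = "SiteAnnotation")
}

annotation_keys <- function(ann) {
  residue_key(ann$residues$chain, ann$residues$number, ann$residues$icode)
}

#' @export
print.SiteAnnotation <- function(x, ...) {
  cat("SiteAnnotation:", x$domain_id, "/", x$site_type, "-",
      nrow(x$residues), "residues,", length(x$evidence_ids), "evidence records\n")
  invisible(x)
}

# positions (1-based) of annotated residues within their domain
annotation_positions <- function(ann, dom) {
  if (ann$domain_id != dom$domain_id) {
    stop("annotation is for domain ", ann$domain_id, ", not ", dom$domain_id)
  }
  idx <- match(annotation_keys(ann), domain_keys(dom))
  if (anyNA(idx)) {
    stop("annotation for ", ann$domain_id, " references residues absent from ",
         "the structure: ", paste(annotation_keys(ann)[is.na(idx)], collapse = ", "))
  }
  sort(idx)
}
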