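# Reading and writing structures, site annotations and interchange tables.

test_that("PDB round-trip preserves residue order, identity and coordinates", {
  dom <- make_template(25, seed = 42, domain_id = "t25")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_domain_pdb(dom, path)
  back <- read_domain_pdb(path, "t25", "SYN")
  expect_equal(back$length, 25)
  expect_equal(back$chain, dom$chain)
  expect_equal(back$number, dom$number)
  expect_equal(back$icode, dom$icode)
  expect_equal(back$aa, dom$aa)
  expect_true(max(abs(back$xyz - dom$xyz)) < 1e-3)
})

test_that("reader resolves altlocs to highest occupancy and rejects junk", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00 10.00           C",
    "ATOM      4  CA  TRP A   3       7.600   0.000   0.000  1.00 10.00           C",
    "END"), path)
  dom <- read_domain_pdb(path, "d", "SF")
  expect_equal(dom$length, 3)
  expect_equal(dom$xyz[1, 1], 0)       # altloc A (occupancy 0.60) retained
  expect_equal(dom$aa, c("A", "G", "W"))

  # sidechain-only file has no CA atoms
  writeLines(c(
    "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "END"), path)
  expect_error(read_domain_pdb(path, "d", "SF"), "no CA atoms")

  # duplicate CA records for one residue with the same altloc
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00 10.00           C",
    "END"), path)
  expect_error(read_domain_pdb(path, "d", "SF"), "A:1")
})

test_that("site annotations merge by union, keep evidence, reject bad rows", {
  doms <- list(toy_domain("d1", 20), toy_domain("d2", 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    domain_id = c("d1", "d1", "d1", "d1", "d2"),
    site_type = c("protein_protein", "protein_protein", "protein_protein",
                  "protein_protein", "catalytic"),
    chain = "A",
    resnum = c(10, 12, 10, 99, 5),   # 10 twice (e1, e2); 99 unresolvable
    icode = "",
    evidence_id = c("e1", "e1", "e2", "e1", "e3"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  anns <- suppressMessages(read_site_annotations(path, doms))
  expect_equal(attr(anns, "n_rejected"), 1)
  pp <- Filter(function(a) a$site_type == "protein_protein", anns)[[1]]
  expect_equal(sort(pp$residues$number), c(10, 12))
  expect_equal(pp$evidence_ids, c("e1", "e2"))

  # idempotent under full row duplication (union semantics)
  write.table(rbind(tab, tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  anns2 <- suppressMessages(read_site_annotations(path, doms))
  pp2 <- Filter(function(a) a$site_type == "protein_protein", anns2)[[1]]
  expect_equal(pp2$residues, pp$residues)

  # unknown site type is fatal
  tab$site_type[1] <- "allosteric"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_site_annotations(path, doms), "unknown site_type")
})

test_that("biologically_relevant = FALSE rows are dropped upstream-style", {
  doms <- list(toy_domain("d1", 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(domain_id = "d1", site_type = "small_ligand", chain = "A",
                    resnum = c(1, 2), icode = "", evidence_id = "e",
                    biologically_relevant = c("TRUE", "FALSE"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  anns <- read_site_annotations(path, doms)
  expect_equal(anns[[1]]$residues$number, 1L)
})

test_that("profile PDB writes scaled B-factors and an exact companion table", {
  dom <- make_template(10, seed = 7)
  path <- withr::local_tempfile(fileext = ".pdb")
  f <- rep(0, 10)
  f[4] <- 0.835
  write_profile_pdb(dom, f, path)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  b <- as.numeric(substr(lines, 61, 66))
  expect_equal(b[4], 83.50)
  expect_equal(b[-4], rep(0, 9))
  tsv <- read.delim(paste0(path, ".tsv"))
  expect_equal(tsv$fraction, f)
  expect_error(write_profile_pdb(dom, rep(0, 11), path), "length mismatch")
})

test_that("alignment interchange TSV round-trips pairs and header values", {
  set.seed(1)
  da <- toy_domain("dA", 15)
  db <- toy_domain("dB", 18)
  al <- random_alignment(da, db, k = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(list(al, mirror_al <- random_alignment(db, da, k = 5)),
                      list(da, db), path)
  back <- read_alignment_tsv(path, list(da, db))
  expect_length(back, 2)
  expect_equal(back[[1]]$pairs, al$pairs)
  expect_equal(back[[1]]$rmsd, al$rmsd)
  expect_equal(back[[1]]$n_aligned, al$n_aligned)
  expect_error(read_alignment_tsv(path, list(da)), "unknown domain")
})

test_that("family table round-trips and fills optional columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(domain_id = c("a", "b"), superfamily_id = "SF1")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_family_table(path)
  expect_true(all(c("s60_cluster_id", "funfam_id") %in% names(back)))
  write_family_table(back, path)
  expect_equal(read_family_table(path), back)
})
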