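# Fragment removal, conservation scoring, conserved-site projection and
# conserved/functional overlap.

aln_from <- function(..., id = "FF") {
  rows <- c(...)
  names(rows) <- sprintf("s%02d", seq_along(rows))
  new_family_alignment(id, rows)
}

test_that("fragment removal uses a single pre-removal mean and strict inequality", {
  seqs <- c(a = strrep("A", 100), b = strrep("A", 95), c = strrep("A", 60))
  kept <- remove_fragments(seqs)
  expect_equal(names(kept), c("a", "b"))
  expect_equal(attr(kept, "removed"), "c")

  same <- c(a = strrep("A", 50), b = strrep("A", 50))
  expect_equal(names(remove_fragments(same)), c("a", "b"))

  # exactly 0.8 x mean is retained ("less than 80%" is removed)
  seqs <- c(a = strrep("A", 120), b = strrep("A", 80))  # mean 100, cutoff 80
  expect_equal(names(remove_fragments(seqs)), c("a", "b"))

  # gaps do not count toward length
  aln <- aln_from(paste0(strrep("A", 50), strrep("-", 50)), strrep("C", 100),
                  strrep("D", 100))
  kept <- remove_fragments(aln)
  expect_equal(names(kept$rows), c("s02", "s03"))

  tiny <- c(a = strrep("A", 10), b = strrep("A", 100), c = strrep("A", 100))
  expect_equal(names(remove_fragments(tiny)), c("b", "c"))
  expect_error(remove_fragments(character(0)), "no sequences")
})

test_that("conservation scores meet the column contracts", {
  aln <- aln_from("AWAC", "AWGC", "AW-C", "AWCC")
  prof <- conservation_scores(aln)
  expect_equal(prof$scores[1], 1.0)           # identical, gap-free
  expect_equal(prof$scores[2], 1.0)
  expect_lt(prof$scores[3], prof$scores[2])   # gapped column scores lower
  expect_true(all(prof$scores >= 0 & prof$scores <= 1))

  # a gapped identity column scores below a gap-free one
  g <- conservation_scores(aln_from("AA", "AA", "-A", "AA"))
  expect_lt(g$scores[1], g$scores[2])

  # all-gap column scores 0
  z <- conservation_scores(aln_from("-A", "-A", "-C"))
  expect_equal(z$scores[1], 0)

  # 50 rows uniform over the 20 amino acids: near-random column scores low
  set.seed(40)
  rows <- vapply(1:50, function(i)
    paste0(sample(siteplast:::AA20, 50, replace = TRUE), collapse = ""), "")
  names(rows) <- sprintf("r%02d", 1:50)
  u <- conservation_scores(new_family_alignment("U", rows))
  expect_lt(mean(u$scores), 0.2)
})

test_that("vectorised scorer matches a naive double-loop evaluation", {
  m <- siteplast:::cons_sim_matrix()
  naive <- function(aln) {
    mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
    w <- siteplast:::henikoff_weights(mat)
    vapply(seq_len(ncol(mat)), function(c) {
      num <- 0
      den <- 0
      for (i in seq_len(nrow(mat) - 1)) {
        for (j in (i + 1):nrow(mat)) {
          num <- num + w[i] * w[j] * m[mat[i, c], mat[j, c]]
          den <- den + w[i] * w[j]
        }
      }
      num / den
    }, 0)
  }
  for (s in 1:5) {
    set.seed(s)
    rows <- vapply(1:6, function(i)
      paste0(sample(c(siteplast:::AA20, "-"), 12, replace = TRUE),
             collapse = ""), "")
    names(rows) <- sprintf("r%d", 1:6)
    aln <- new_family_alignment("X", rows)
    expect_equal(conservation_scores(aln)$scores, naive(aln),
                 tolerance = 1e-10)
  }
})

test_that("scores are invariant to row order and to duplicating the row set", {
  fam <- make_conservation_family(n_full = 8, length = 40, n_functional = 6,
                                  seed = 3)
  aln <- fam$alignment
  base <- conservation_scores(aln)$scores

  perm <- new_family_alignment("P", sample(aln$rows), "finefam")
  expect_equal(conservation_scores(perm)$scores, base, tolerance = 1e-12)

  dup_rows <- c(aln$rows, setNames(aln$rows, paste0(names(aln$rows), "_dup")))
  dup <- new_family_alignment("D", dup_rows, "finefam")
  expect_equal(conservation_scores(dup)$scores, base, tolerance = 1e-12)
})

test_that("conserved columns shrink monotonically as the threshold rises", {
  fam <- make_conservation_family(n_full = 8, n_fragments = 4, length = 60,
                                  n_functional = 8, seed = 5)
  ths <- c(0.3, 0.5, 0.7, 0.9)
  sizes <- vapply(ths, function(t)
    length(conservation_scores(fam$alignment, threshold = t)$conserved_columns),
    0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("conserved columns project onto member residues through the alignment", {
  # 3 members; member 2 has a 2-column gap, so its residues shift
  rows <- c(d1 = "AWCDEF", d2 = "AW--EF", d3 = "AWCDEF")
  aln <- new_family_alignment("FF", rows)
  doms <- list(toy_domain("d1", 6), toy_domain("d2", 4), toy_domain("d3", 6))
  prof <- conservation_scores(aln, threshold = 0.99)
  expect_equal(prof$conserved_columns, c(1, 2, 5, 6))
  sites <- conserved_to_sites(prof, aln, doms)
  expect_equal(vapply(sites, `[[`, "", "domain_id"), c("d1", "d2", "d3"))
  expect_equal(sites[[1]]$residues$number, c(1, 2, 5, 6))
  # member 2: columns 5,6 are its residues 3,4
  expect_equal(sites[[2]]$residues$number, c(1, 2, 3, 4))
  expect_true(all(vapply(sites, `[[`, "", "site_type") == "conserved"))

  # rows without a structure, or with a length mismatch, are skipped
  expect_warning(conserved_to_sites(prof, aln, doms[1:2]), "no structure")
  bad <- list(toy_domain("d1", 6), toy_domain("d2", 5), toy_domain("d3", 6))
  expect_warning(conserved_to_sites(prof, aln, bad), "disagrees")
})

test_that("overlap proportion is intersection over functional residues", {
  fun <- list(new_site_annotation("d1", "catalytic",
                                  data.frame(chain = "A", number = 1:10,
                                             icode = "")))
  cons_all <- list(new_site_annotation("d1", "conserved",
                                       data.frame(chain = "A", number = 1:15,
                                                  icode = "")))
  expect_equal(overlap_proportion(cons_all, fun, "catalytic"), 1.0)
  cons_none <- list(new_site_annotation("d1", "conserved",
                                        data.frame(chain = "A",
                                                   number = 20:25,
                                                   icode = "")))
  expect_equal(overlap_proportion(cons_none, fun, "catalytic"), 0.0)
  expect_true(is.na(overlap_proportion(cons_all, fun, "nucleic_acid")))
})

test_that("removing planted fragments raises conservation at functional columns", {
  hits <- vapply(1:5, function(s) {
    fam <- make_conservation_family(n_full = 8, n_fragments = 8,
                                    length = 120, n_functional = 12,
                                    seed = 200 + s)
    before <- conservation_scores(fam$alignment)
    after <- conservation_scores(remove_fragments(fam$alignment))
    mean(fam$functional_columns %in% after$conserved_columns) >
      mean(fam$functional_columns %in% before$conserved_columns)
  }, TRUE)
  expect_gte(sum(hits), 4)
})
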