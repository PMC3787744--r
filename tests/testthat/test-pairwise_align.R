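# Kabsch superposition, the iterative aligner, similarity score and
# normalised RMSD.

test_that("kabsch superposition is exact on rigidly moved copies", {
  set.seed(3)
  A <- matrix(rnorm(30), 10, 3)

  out <- kabsch_superpose(A, A)
  expect_equal(out$rmsd, 0, tolerance = 1e-10)
  expect_equal(out$rotation, diag(3), tolerance = 1e-8)

  out <- kabsch_superpose(A, sweep(A, 2, c(5, 0, 0), `+`))
  expect_equal(out$rmsd, 0, tolerance = 1e-10)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  out <- kabsch_superpose(A, A %*% t(R))
  expect_equal(out$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(out$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch rmsd matches brute-force minimisation over rotations", {
  # unit triangle with one vertex displaced by 1 A
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  B <- A
  B[3, ] <- B[3, ] + c(0, 1, 0)
  got <- kabsch_superpose(A, B)$rmsd

  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3) %*%
      matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3) %*%
      matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  }
  obj <- function(ang) {
    Ac <- sweep(A, 2, colMeans(A))
    Bc <- sweep(B, 2, colMeans(B)) %*% t(rot(ang))
    sqrt(mean(rowSums((Ac - Bc)^2)))
  }
  best <- Inf
  for (s in 1:25) {
    set.seed(s)
    o <- optim(runif(3, -pi, pi), obj)
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-4)
})

test_that("kabsch rmsd agrees with bio3d on random coordinate sets", {
  set.seed(11)
  for (i in 1:5) {
    A <- matrix(rnorm(60, sd = 5), 20, 3)
    B <- A + matrix(rnorm(60, sd = 0.8), 20, 3)
    got <- kabsch_superpose(A, B)$rmsd
    fit <- bio3d::fit.xyz(as.numeric(t(A)), as.numeric(t(B)),
                          fixed.inds = 1:60, mobile.inds = 1:60)
    ref <- bio3d::rmsd(as.numeric(t(A)), fit)  # bio3d reports 3 decimals
    expect_equal(got, ref, tolerance = 1e-3)
  }
})

test_that("kabsch rejects malformed input", {
  A <- matrix(rnorm(30), 10, 3)
  expect_error(kabsch_superpose(A, A[1:9, ]), "length")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("self-alignment is the identity pairing with rmsd 0 and score 100", {
  dom <- make_template(40, seed = 2)
  al <- align_structures(dom, dom)
  expect_equal(al$pairs, cbind(1:40, 1:40))
  expect_equal(al$rmsd, 0)
  expect_equal(al$score, 100)
})

test_that("alignment is invariant to rigid motion of one copy", {
  dom <- make_template(50, seed = 8)
  set.seed(1)
  Q <- siteplast:::rand_rotation()
  moved <- new_domain("moved", dom$superfamily_id, dom$chain, dom$number,
                      dom$icode, dom$aa,
                      sweep(dom$xyz %*% t(Q), 2, c(10, -4, 2), `+`))
  al <- align_structures(dom, moved)
  expect_equal(al$pairs, cbind(1:50, 1:50))
  expect_lt(al$rmsd, 1e-6)
})

test_that("an inserted loop is gapped out and the core stays paired", {
  dom <- make_template(60, seed = 13)
  set.seed(4)
  loop <- siteplast:::insert_loop_coords(dom$xyz, 30, 10)
  xyz <- rbind(dom$xyz[1:30, ], loop, dom$xyz[31:60, ])
  aa <- c(dom$aa[1:30], sample(siteplast:::AA20, 10, replace = TRUE),
          dom$aa[31:60])
  big <- new_domain("big", "SYN", rep("A", 70), 1:70, rep("", 70), aa, xyz)
  al <- align_structures(dom, big)
  # original residue i sits at position i (i <= 30) or i + 10 (i > 30)
  want <- ifelse(al$pairs[, 1] <= 30, al$pairs[, 1], al$pairs[, 1] + 10)
  expect_gte(sum(al$pairs[, 2] == want), 55)
})

test_that("aligner recovers >= 95% of true correspondences under 1 A noise", {
  tm <- make_template(80, seed = 21)
  for (s in 1:5) {
    set.seed(s)
    xa <- tm$xyz + matrix(rnorm(240, 0, 1), 80, 3)
    xb <- tm$xyz + matrix(rnorm(240, 0, 1), 80, 3)
    db <- new_domain("b", "SYN", tm$chain, tm$number, tm$icode, tm$aa,
                     xb %*% t(siteplast:::rand_rotation()))
    da <- new_domain("a", "SYN", tm$chain, tm$number, tm$icode, tm$aa, xa)
    al <- align_structures(da, db)
    recovered <- sum(al$pairs[, 1] == al$pairs[, 2]) / 80
    expect_gte(recovered, 0.95)
  }
})

test_that("alignments are symmetric and never cross", {
  tm <- make_template(45, seed = 30)
  for (s in 1:5) {
    set.seed(s)
    xb <- tm$xyz + matrix(rnorm(135, 0, 1.5), 45, 3)
    da <- new_domain("dA", "SYN", tm$chain, tm$number, tm$icode, tm$aa, tm$xyz)
    db <- new_domain("dB", "SYN", tm$chain, tm$number, tm$icode,
                     siteplast:::mutate_seq(tm$aa, 0.7), xb)
    ab <- align_structures(da, db)
    ba <- align_structures(db, da)
    expect_equal(ab$pairs, ba$pairs[, 2:1])
    expect_equal(ab$rmsd, ba$rmsd)
    expect_equal(ab$score, ba$score)
    expect_true(all(diff(ab$pairs[, 1]) > 0))
    expect_true(all(diff(ab$pairs[, 2]) > 0))
  }
})

test_that("similarity score meets its contract", {
  al <- function(rmsd, n) list(rmsd = rmsd, n_aligned = n)
  expect_equal(similarity_score(al(0, 100), 100, 100), 100)
  # monotone decreasing in rmsd at fixed n_aligned
  s <- vapply(c(0, 1, 2, 5, 10), function(r)
    similarity_score(al(r, 80), 100, 100), 0)
  expect_true(all(diff(s) < 0))
  # monotone increasing in n_aligned at fixed rmsd
  s <- vapply(c(10, 40, 70, 100), function(n)
    similarity_score(al(2, n), 100, 100), 0)
  expect_true(all(diff(s) > 0))
  # symmetric in the two lengths
  expect_equal(similarity_score(al(2, 60), 100, 80),
               similarity_score(al(2, 60), 80, 100))
  # a single aligned residue out of 100 scores < 5
  expect_lt(similarity_score(al(0, 1), 100, 100), 5)
})

test_that("normalised RMSD follows its formula and bounds", {
  expect_equal(normalised_rmsd(2.0, 150, 120, 100), 3.0)
  expect_equal(normalised_rmsd(0, 80, 200, 50), 0)
  expect_equal(normalised_rmsd(1.7, 90, 90, 90), 1.7)  # full-length collapse
  expect_error(normalised_rmsd(1, 10, 10, 0), "positive")
  # nrmsd >= rmsd whenever the alignment cannot exceed the larger domain
  set.seed(5)
  for (i in 1:20) {
    la <- sample(50:200, 1); lb <- sample(50:200, 1)
    n <- sample(10:min(la, lb), 1); r <- runif(1, 0, 10)
    expect_gte(normalised_rmsd(r, la, lb, n), r)
  }
})
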