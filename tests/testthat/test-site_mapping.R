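# Representative selection, site mapping, profiles, coverage, heat-map
# binning and hub flagging.

test_that("representative selection maximises cumulative similarity", {
  tm <- make_template(60, seed = 17)
  set.seed(2)
  mk <- function(id, sd) {
    new_domain(id, "SF", tm$chain, tm$number, tm$icode, tm$aa,
               tm$xyz + matrix(rnorm(180, 0, sd), 60, 3))
  }
  # star topology: d1 is a near-copy of the template, the rest are far out
  doms <- list(mk("d1", 0.2), mk("d2", 3), mk("d3", 3), mk("d4", 3))
  names(doms) <- sprintf("d%d", 1:4)
  s60 <- new_cluster_set("s60", as.list(setNames(names(doms), names(doms))),
                         0.6)
  rep_id <- select_representative(doms, s60)
  expect_equal(as.character(rep_id), "d1")
  # brute-force cumulative-score ranking agrees
  cum <- setNames(numeric(4), names(doms))
  for (i in 1:3) for (j in (i + 1):4) {
    al <- align_structures(doms[[i]], doms[[j]])
    cum[i] <- cum[i] + al$score
    cum[j] <- cum[j] + al$score
  }
  expect_equal(as.character(rep_id), names(which.max(cum)))
  expect_equal(unname(attr(rep_id, "cum_scores")[names(cum)]), unname(cum),
               tolerance = 1e-9)
})

test_that("identical domains tie-break to the smallest id and single-cluster superfamilies are excluded", {
  tm <- make_template(40, seed = 23)
  mk <- function(id) new_domain(id, "SF", tm$chain, tm$number, tm$icode,
                                tm$aa, tm$xyz)
  doms <- list(mk("dC"), mk("dA"), mk("dB"))
  names(doms) <- c("dC", "dA", "dB")
  s60 <- new_cluster_set("s60", list(c1 = "dC", c2 = "dA", c3 = "dB"), 0.6)
  expect_equal(as.character(select_representative(doms, s60)), "dA")

  one <- new_cluster_set("s60", list(c1 = c("dA", "dB", "dC")), 0.6)
  expect_error(select_representative(doms, one), "single s60 cluster")
})

test_that("site mapping follows alignment pairs and ignores gap-aligned residues", {
  rep_dom <- toy_domain("rep", 20)
  member <- toy_domain("mem", 15)
  al <- new_alignment("mem", "rep", cbind(c(2, 7, 9), c(3, 10, 15)),
                      rmsd = 1, score = 80)
  ann <- new_site_annotation("mem", "catalytic",
                             data.frame(chain = "A", number = c(7, 8),
                                        icode = ""))
  # residue 7 pairs with rep position 10; residue 8 is gap-aligned
  expect_equal(map_domain_sites(rep_dom, member, al, ann), 10)
  # orientation is mirrored automatically
  expect_equal(map_domain_sites(rep_dom, member, mirror_alignment(al), ann), 10)
  # representative against itself
  self_ann <- new_site_annotation("rep", "catalytic",
                                  data.frame(chain = "A",
                                             number = c(1, 5, 20), icode = ""))
  expect_equal(map_domain_sites(rep_dom, rep_dom,
                                siteplast:::identity_alignment(rep_dom),
                                self_ann),
               c(1, 5, 20))
  expect_error(map_domain_sites(rep_dom, member, al,
                                new_site_annotation("other", "catalytic",
                                                    data.frame(chain = "A",
                                                               number = 1,
                                                               icode = ""))),
               "annotation is for domain")
})

test_that("profiles union contributors per position, by hand enumeration", {
  rep_dom <- toy_domain("rep", 10)
  m1 <- toy_domain("m1", 10)
  m2 <- toy_domain("m2", 10)
  m3 <- toy_domain("m3", 8)
  members <- list(rep = rep_dom, m1 = m1, m2 = m2, m3 = m3)
  full <- function(a) new_alignment(a, "rep", cbind(1:10, 1:10), 0.5, 80)
  alns <- list(full("m1"), full("m2"),
               new_alignment("m3", "rep", cbind(1:8, 3:10), 0.5, 70))
  site <- function(d, pos) new_site_annotation(d, "protein_protein",
                                               data.frame(chain = "A",
                                                          number = pos,
                                                          icode = ""))
  anns <- list(site("m1", c(4, 5)), site("m2", c(5, 6)), site("m3", c(2, 3)),
               site("rep", 4))
  prof <- build_profile("SF", rep_dom, members, alns, anns)
  counts <- siteplast:::position_counts(prof, "protein_protein", "domains")
  # hand enumeration: pos4 {m1, rep}, pos5 {m1, m2(5), m3(res3->5)},
  # pos6 {m2}, pos4 also m3? res2 -> pos4 -> {m1, rep, m3}
  expect_equal(counts, c(0, 0, 0, 3, 3, 1, 0, 0, 0, 0))

  # no annotations at all -> empty contributor sets
  empty <- build_profile("SF", rep_dom, members, alns, list())
  expect_length(empty$sites, 0)
  expect_equal(coverage(empty, "protein_protein",
                        apply_filters = FALSE)$coverage, 0)

  # annotated member without an alignment is an error
  expect_error(build_profile("SF", rep_dom, members, alns[-1], anns),
               "no alignment")
})

test_that("coverage applies the length and dominance filters exactly", {
  mkprof <- function(L, positions_by_domain) {
    rep_dom <- toy_domain("rep", L)
    members <- list(rep = rep_dom)
    alns <- list()
    anns <- list()
    for (id in names(positions_by_domain)) {
      members[[id]] <- toy_domain(id, L)
      alns[[length(alns) + 1]] <- new_alignment(id, "rep",
                                                cbind(1:L, 1:L), 0.5, 90)
      anns[[length(anns) + 1]] <- new_site_annotation(
        id, "protein_protein",
        data.frame(chain = "A", number = positions_by_domain[[id]],
                   icode = ""))
    }
    build_profile("SF", rep_dom, members, alns, anns)
  }
  cv <- coverage(mkprof(100, list(mA = 1:20, mB = 11:25)), "protein_protein")
  expect_equal(cv$coverage, 0.25)
  expect_false(cv$excluded)
  expect_equal(cv$n_contributing_domains, 2)

  cv <- coverage(mkprof(99, list(mA = 1:20)), "protein_protein")
  expect_true(cv$excluded)
  expect_equal(cv$exclusion_reason, "rep_too_short")
  expect_false(coverage(mkprof(99, list(mA = 1:20)), "protein_protein",
                        apply_filters = FALSE)$excluded)

  cv51 <- coverage(mkprof(100, list(mA = 1:51, mB = 60:62)), "protein_protein")
  expect_true(cv51$excluded)
  expect_equal(cv51$exclusion_reason, "single_domain_dominance")
  cv50 <- coverage(mkprof(100, list(mA = 1:50, mB = 60:62)), "protein_protein")
  expect_false(cv50$excluded)
})

test_that("coverage is monotone under added annotations and removed members", {
  for (s in 1:10) {
    set.seed(s)
    inst <- random_profile_instance(s)
    base <- coverage(inst$profile, "protein_protein",
                     apply_filters = FALSE)$coverage
    # add one more annotation to some member
    m <- inst$members[[sample(length(inst$members), 1)]]
    extra <- new_site_annotation(m$domain_id, "protein_protein",
                                 data.frame(chain = "A",
                                            number = sample(m$length, 2),
                                            icode = ""))
    prof2 <- build_profile("SF", inst$rep, inst$members,
                           inst$alignments, c(inst$annotations, list(extra)),
                           inst$s60)
    expect_gte(coverage(prof2, "protein_protein",
                        apply_filters = FALSE)$coverage, base)
  }
})

test_that("heat-map fractions bin on the conventional colour scale", {
  rep_dom <- toy_domain("rep", 5)
  members <- list(rep = rep_dom)
  alns <- list()
  anns <- list()
  for (i in 1:9) {
    id <- sprintf("m%02d", i)
    members[[id]] <- toy_domain(id, 5)
    alns[[i]] <- new_alignment(id, "rep", cbind(1:5, 1:5), 0.5, 90)
    pos <- integer()
    if (i <= 7) pos <- c(pos, 2)   # position 2: 7/10 of domains
    if (i <= 2) pos <- c(pos, 3)   # position 3: 2/10
    if (length(pos)) {
      anns[[length(anns) + 1]] <- new_site_annotation(
        id, "protein_protein",
        data.frame(chain = "A", number = pos, icode = ""))
    }
  }
  prof <- build_profile("SF", rep_dom, members, alns, anns)
  hm <- heatmap_fractions(prof, "protein_protein", "domains")
  expect_equal(hm$bin[1], "grey")      # exactly 0
  expect_equal(hm$fraction[2], 0.7)
  expect_equal(hm$bin[2], "orange")    # 60-80%
  expect_equal(hm$fraction[3], 0.2)
  expect_equal(hm$bin[3], "green")     # boundary assigned upward
  # saturated position is red
  anns2 <- lapply(names(members), function(id) {
    new_site_annotation(id, "catalytic",
                        data.frame(chain = "A", number = 1, icode = ""))
  })
  prof2 <- build_profile("SF", rep_dom, members, alns, anns2)
  expect_equal(heatmap_fractions(prof2, "catalytic", "domains")$bin[1], "red")
})

test_that("hub superfamilies are flagged at 10 interactions inclusive", {
  membership <- data.frame(domain_id = c("a", "b", "c", "d"),
                           superfamily_id = c("SF1", "SF1", "SF2", "SF3"))
  expect_equal(flag_hub_superfamilies(c(a = 3, b = 12, c = 9, d = 10),
                                      membership),
               c("SF1", "SF3"))
  expect_equal(flag_hub_superfamilies(c(a = 3, b = 9, c = 2, d = 1),
                                      membership),
               character(0))
})
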