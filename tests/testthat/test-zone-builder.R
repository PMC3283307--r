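test_that("syntenies sharing two witness genes agglomerate into one zone", {
  ex5 <- loadExample(5)
  agg <- agglomerateZones(ex5$syntenies)
  expect_length(agg$zones, 1L)
  expect_length(agg$weakBonds, 0L)
  z <- agg$zones[[1]]
  expect_equal(families(z), ex5$expected$zoneFamilies)
  w <- witness(z)
  excl <- ex5$expected$excludedGene
  expect_false(any(w$chromosome == excl$chromosome & w$position == excl$position))
  shared <- ex5$expected$sharedWitness
  expect_true(all(paste(shared$chromosome, shared$position) %in%
                  paste(w$chromosome, w$position)))
})

test_that("disjoint witnesses give singleton zones; chains agglomerate transitively", {
  a <- makeSynteny(c("fa", "fb"), list(x = c(`1` = "fa", `2` = "fb"),
                                       y = c(`1` = "fa", `2` = "fb")))
  b <- makeSynteny(c("fc", "fd"), list(x = c(`9` = "fc", `10` = "fd"),
                                       y = c(`9` = "fc", `10` = "fd")))
  agg <- agglomerateZones(list(a, b))
  expect_length(agg$zones, 2L)
  expect_length(agg$weakBonds, 0L)

  ## chain a-b-c through pairwise overlaps >= 2: one zone by transitivity,
  ## matching a connected-component computation done by hand
  s1 <- makeSynteny(c("f1", "f2"), list(x = c(`1` = "f1", `2` = "f2"),
                                        y = c(`1` = "f1", `2` = "f2")))
  s2 <- makeSynteny(c("f2", "f3"), list(x = c(`2` = "f2", `3` = "f3"),
                                        y = c(`2` = "f2", `3` = "f3")))
  s3 <- makeSynteny(c("f3", "f4"), list(x = c(`3` = "f3", `4` = "f4"),
                                        y = c(`3` = "f3", `4` = "f4")))
  agg2 <- agglomerateZones(list(s1, s2, s3))
  expect_length(agg2$zones, 1L)
  expect_equal(families(agg2$zones[[1]]), c("f1", "f2", "f3", "f4"))
  ## s1 and s3 share no witness yet sit in the zone through s2
  expect_length(intersect(
    paste(witness(s1)$chromosome, witness(s1)$position),
    paste(witness(s3)$chromosome, witness(s3)$position)), 0L)
})

test_that("the weak-bond example resolves into orthologous and paralogous syntenies", {
  ex6 <- loadExample(6)
  res <- synsRun(ex6$genomes, delta = ex6$delta,
                 focalFamilies = ex6$expected$focal)
  expect_length(syntenies(res), 2L)
  ## the two computed syntenies carry exactly the printed witnesses, up to
  ## the weak-bond gene removed from the paralogous side
  expect_equal(familySetSignature(syntenies(res)), c("f2,f8", "f4,f8"))
  expect_length(weakBonds(res), 1L)
  bond <- weakBonds(res)[[1]]
  wg <- bond@witnessGene
  exp_wg <- ex6$expected$weakBondWitness
  expect_equal(paste(wg$chromosome, wg$position, wg$family),
               paste(exp_wg$chromosome, exp_wg$position, exp_wg$family))
  resol <- res@resolutions[[1]]
  expect_equal(resol$case, "AB")
  expect_equal(families(resol$orthologous), ex6$expected$orthologousFamilies)
  expect_equal(families(resol$paralogous), ex6$expected$paralogousFamilies)
  ## orthologous witness is the full printed S2
  exp_syn <- ex6$expected$syntenies
  s2 <- exp_syn[[which(vapply(exp_syn, function(s)
    setequal(s$families, families(resol$orthologous)), TRUE))]]
  expect_identical(witness(resol$orthologous)[, c("chromosome", "position", "family")],
                   s2$witness[, c("chromosome", "position", "family")])
  ## paralogous witness is S1 minus the weak-bond gene
  expect_identical(witness(resol$paralogous)[, c("chromosome", "position", "family")],
                   ex6$expected$paralogousWitness[, c("chromosome", "position", "family")])
  ## zone labels follow the resolution
  labs <- sort(vapply(zones(res), zoneLabel, ""))
  expect_equal(labs, c("orthologous", "paralogous"))
})

test_that("the implausible weak-bond topology is recognised (no valid zone)", {
  ## three species, sp1 diverged most recently; the shared gene g lies in sp1
  ## while the smaller witness also has genes in the earlier-diverged sp3:
  ## a single-gene connection in the youngest species cannot be explained by
  ## a speciation-time-consistent history
  order <- c("sp1", "sp2", "sp3")
  sj <- makeSynteny(c("fb", "fc"), list(
    sp1 = c(`7` = "fb", `8` = "fc"), sp3 = c(`5` = "fb", `6` = "fc")))
  ## the overlap is exactly (7,fb)@sp1
  si2 <- makeSynteny(c("fa", "fb"), list(
    sp2 = c(`1` = "fa", `2` = "fb"),
    sp3 = c(`1` = "fa", `2` = "fb"),
    sp1 = c(`7` = "fb", `6` = "fa")))
  g <- witness(sj)[witness(sj)$species == "sp1" & witness(sj)$position == 7, ]
  bond <- new("WeakBond", syntenyA = si2, syntenyB = sj, witnessGene = g)
  res <- resolveWeakBond(bond, order)
  expect_equal(res$case, "C")
  expect_equal(families(res$orthologous), c("fa", "fb"))
  expect_equal(families(res$paralogous), c("fb", "fc"))
  expect_false(any(witness(res$paralogous)$species == "sp1" &
                   witness(res$paralogous)$position == 7))
  ## a pair sharing two genes is not a weak bond
  t1 <- makeSynteny(c("fa", "fb"), list(x = c(`1` = "fa", `2` = "fb"),
                                        y = c(`1` = "fa", `2` = "fb")))
  t2 <- makeSynteny(c("fb", "fc"), list(x = c(`1` = "fa", `2` = "fb"),
                                        y = c(`2` = "fb", `3` = "fc")))
  badBond <- new("WeakBond", syntenyA = t1, syntenyB = t2,
                 witnessGene = witness(t1)[1, ])
  expect_error(resolveWeakBond(badBond, c("x", "y")), "not a weak bond")
})

test_that("finalization keeps the largest orthologous zone per family", {
  ex6 <- loadExample(6)
  res <- synsRun(ex6$genomes, delta = 3, focalFamilies = "f8")
  tab <- partitionTable(res)
  f8 <- tab[tab$family_id == "f8", ]
  ortho <- f8[f8$subgroup_type == "ortholog", ]
  expect_setequal(paste(ortho$chromosome, ortho$position),
                  c("c2 9", "c3 2", "c3 5"))
  para <- f8[f8$subgroup_type == "paralog", ]
  expect_setequal(paste(para$chromosome, para$position), "c3 8")
  sing <- f8[f8$subgroup_type == "singleton", ]
  expect_setequal(paste(sing$chromosome, sing$position), "c3 6")
  ## ortho and para subgroups of one family never share a gene
  expect_length(intersect(ortho$gene_id, para$gene_id), 0L)

  ## two orthologous zones covering one family: only the larger is retained
  zBig <- new("Zone", label = "orthologous", members = list(
    makeSynteny(c("fa", "fb"), list(x = c(`1` = "fa", `2` = "fb"),
                                    y = c(`1` = "fa", `2` = "fb"),
                                    w = c(`1` = "fa", `2` = "fb")))))
  zSmall <- new("Zone", label = "orthologous", members = list(
    makeSynteny(c("fa", "fc"), list(x = c(`20` = "fa", `21` = "fc"),
                                    z = c(`20` = "fa", `21` = "fc")))))
  gs <- GenomeSet(rbind(witness(members(zBig)[[1]]),
                        witness(members(zSmall)[[1]])))
  part <- partitionTable(finalizePartition(list(zBig, zSmall), gs))
  fa <- part[part$family_id == "fa", ]
  expect_equal(sum(fa$subgroup_type == "ortholog"), 3L)  # the larger zone's copies
  expect_true(all(fa$position[fa$subgroup_type == "ortholog"] == 1))
  expect_true(all(fa$subgroup_type[fa$position == 20] == "singleton"))
})

test_that("degenerate and local inputs behave predictably", {
  ## single chromosome: no zones, every family member a singleton
  solo <- GenomeSet(list(parseCompactNotation("f1 f2 f1 * f3", "s1", "c1")))
  res <- synsRun(solo, delta = 3)
  expect_length(zones(res), 0L)
  tab <- partitionTable(res)
  expect_true(all(tab$subgroup_type == "singleton"))
  expect_equal(nrow(tab), 4L)  # all assigned genes

  ## locality: adding a chromosome with fresh families leaves zones unchanged
  ex4 <- loadExample(4)
  res1 <- synsRun(ex4$genomes, delta = 3, focalFamilies = "f8")
  extra <- parseCompactNotation("g1 g2 g1 g2", "s9", "c9")
  gs2 <- GenomeSet(c(ex4$chromosomes, list(extra)))
  res2 <- synsRun(gs2, delta = 3, focalFamilies = "f8")
  zsig <- function(r) sort(vapply(zones(r), function(z)
    paste(paste(families(z), collapse = ","),
          paste(witness(z)$chromosome, witness(z)$position, collapse = ";")), ""))
  expect_identical(zsig(res1), zsig(res2))
})
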