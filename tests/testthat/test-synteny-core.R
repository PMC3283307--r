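test_that("neighbourhood windows are contiguous delta-segments inside +-delta", {
  ex2 <- loadExample(2)
  c2 <- ex2$chromosomes[[1]]
  w <- neighborhoodWindows(c2, "c2:2", delta = 3)
  posSets <- lapply(w, function(x) x@genes$position)
  expect_equal(posSets, list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L)))
  for (x in w) {
    expect_true(isContiguous(x@genes, c2))
    expect_true(isDeltaSegment(x@genes, 3))
    expect_true(all(x@genes$position >= 2 - 3 & x@genes$position <= 2 + 3))
  }
  ## delta = 1: single-gene windows only
  w1 <- neighborhoodWindows(c2, "c2:2", delta = 1)
  expect_true(all(vapply(w1, function(x) nrow(x@genes), 0L) == 1L))
  ## boundary: no window extends below position 1
  wb <- neighborhoodWindows(c2, "c2:1", delta = 3)
  expect_true(all(vapply(wb, function(x) x@start, 0L) >= 1L))
  expect_error(neighborhoodWindows(c2, "nope", 3), "not on this chromosome")
})

test_that("delta-subsets carry complete witness lists", {
  ex2 <- loadExample(2)
  ds <- deltaSubsets(ex2$chromosomes[[1]], ex2$delta)
  got <- lapply(ds, function(d)
    lapply(witnessSegments(d), function(s) s$position))
  names(got) <- vapply(ds, function(d) paste(families(d), collapse = ","), "")
  exp <- ex2$expected$subsets
  expect_setequal(names(got), names(exp))
  for (k in names(exp)) {
    canon <- function(L) sort(vapply(L, function(p)
      paste(sort(p), collapse = ","), ""))
    expect_identical(canon(got[[k]]), canon(exp[[k]]), label = k)
  }
  ## delta = 1 admits no pair at all
  expect_length(deltaSubsets(ex2$chromosomes[[1]], 1), 0L)
})

test_that("delta-subsets equal exhaustive enumeration on random chromosomes", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    fams <- paste0("f", sample.int(4, n, replace = TRUE))
    fams[stats::runif(n) < 0.2] <- "*"
    chr <- parseCompactNotation(paste(fams, collapse = " "))
    delta <- sample(2:4, 1)
    got <- deltaSubsets(chr, delta)
    gotSegs <- unlist(lapply(got, function(d)
      vapply(witnessSegments(d), function(s)
        paste(sort(s$position), collapse = ","), "")))
    ## independent route: full power set with the all-pairs distance rule
    g <- geneTable(chr)[geneTable(chr)$family != "*", ]
    expSegs <- character()
    if (nrow(g) >= 2) for (m in 1:(2^nrow(g) - 1)) {
      idx <- which(bitwAnd(m, 2^(seq_len(nrow(g)) - 1)) > 0)
      if (length(idx) < 2) next
      p <- g$position[idx]
      if (any(outer(p, p, function(a, b) abs(a - b)) >= delta)) next
      if (length(unique(g$family[idx])) < 2) next
      expSegs <- c(expSegs, paste(sort(p), collapse = ","))
    }
    expect_setequal(as.character(unlist(gotSegs)), unique(expSegs))
  }
})

test_that("clusters of the three-chromosome example match per pair", {
  ex3 <- loadExample(3)
  cl <- deltaClusters(ex3$genomes, ex3$delta, focalFamily = ex3$expected$focal)
  expect_equal(
    clusterPairFamilies(cl, "c1|c1", "c2|c2"),
    sort(c("f1,f2", "f1,f4", "f1,f4,f5", "f1,f5")))
  expect_equal(clusterPairFamilies(cl, "c1|c1", "c3|c3"),
               sort(c("f1,f4", "f1,f5")))
  clAll <- deltaClusters(ex3$genomes, ex3$delta)
  expPairs <- ex3$expected$clusterPairs
  expect_equal(clusterPairFamilies(clAll, "c1|c1", "c2|c2"),
    sort(vapply(expPairs$`c1,c2`, function(f) paste(sort(f), collapse = ","), "")))
  expect_equal(clusterPairFamilies(clAll, "c1|c1", "c3|c3"),
    sort(vapply(expPairs$`c1,c3`, function(f) paste(sort(f), collapse = ","), "")))
  expect_error(deltaClusters(ex3$genomes, 3, focalFamily = "f99"),
               "unknown focal family")
  ## single chromosome: the cover condition is unsatisfiable
  solo <- GenomeSet(ex3$chromosomes[1])
  expect_length(deltaClusters(solo, 3), 0L)
})

test_that("maximality merges covered clusters and keeps the rest", {
  ex4 <- loadExample(4)
  cl <- deltaClusters(ex4$genomes, ex4$delta, focalFamily = ex4$expected$focal)
  expect_equal(familySetSignature(cl),
               sort(c("f2,f8", "f4,f8", "f7,f8", "f7,f8,f9", "f8,f9")))
  syn <- maximalSyntenies(cl)
  expect_equal(familySetSignature(syn),
    sort(vapply(ex4$expected$syntenies, function(f)
      paste(sort(f), collapse = ","), "")))
  idx <- vapply(syn, function(s) paste(families(s), collapse = ","), "")
  big <- syn[[which(idx == "f7,f8,f9")]]
  expect_equal(familySetSignature(mergedFrom(big)), "f8,f9")
  ## disjoint family sets: nothing merges
  a <- makeSynteny(c("fa", "fb"), list(x = c(`1` = "fa", `2` = "fb"),
                                       y = c(`1` = "fa", `2` = "fb")))
  b <- makeSynteny(c("fc", "fd"), list(x = c(`5` = "fc", `6` = "fd"),
                                       y = c(`5` = "fc", `6` = "fd")))
  expect_length(maximalSyntenies(list(a, b)), 2L)
})

test_that("witness soundness: segments respect delta, syntenies span 2+ chromosomes", {
  for (seed in 1:10) {
    gs <- randomGenomeSet(seed)
    delta <- 3
    for (chrKey in unique(paste(geneTable(gs)$species, geneTable(gs)$chromosome))) {
      parts <- strsplit(chrKey, " ")[[1]]
      g <- geneTable(gs)
      g <- g[g$species == parts[1] & g$chromosome == parts[2], ]
      chr <- Chromosome(parts[1], parts[2], g[, c("gene_id", "position", "family")])
      for (d in deltaSubsets(chr, delta))
        for (s in witnessSegments(d))
          expect_true(diff(range(s$position)) < delta)
    }
    for (s in maximalSyntenies(deltaClusters(gs, delta)))
      expect_gte(length(chromosomeCover(s)), 2L)
  }
})

test_that("delta-subset family collections grow monotonically with delta", {
  for (seed in 1:10) {
    gs <- randomGenomeSet(seed, maxChromosomes = 2)
    g <- geneTable(gs)
    g1 <- g[g$chromosome == g$chromosome[1], ]
    chr <- Chromosome(g1$species[1], g1$chromosome[1],
                      g1[, c("gene_id", "position", "family")])
    prev <- character()
    for (delta in 1:5) {
      cur <- vapply(deltaSubsets(chr, delta), function(d)
        paste(families(d), collapse = ","), "")
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("results are invariant under input permutation", {
  for (seed in c(3, 14)) {
    gs <- randomGenomeSet(seed)
    df <- geneTable(gs)
    set.seed(seed + 100)
    shuffled <- GenomeSet(df[sample.int(nrow(df)), ],
                          speciesOrder = rev(speciesOrder(gs)))
    a <- maximalSyntenies(deltaClusters(gs, 3))
    b <- maximalSyntenies(deltaClusters(shuffled, 3))
    expect_identical(syntenySignature(a), syntenySignature(b))
  }
})
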