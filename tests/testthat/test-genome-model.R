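test_that("compact notation parses positions, gaps and the alphabet", {
  ex1 <- loadExample(1)
  c1 <- ex1$chromosomes[[1]]
  assigned <- geneTable(c1)[geneTable(c1)$family != "*", ]
  expect_equal(assigned$position, c(1L, 2L, 4L, 7L, 8L))
  expect_equal(assigned$family, c("f2", "f1", "f4", "f3", "f1"))
  expect_equal(geneTable(c1)$position[geneTable(c1)$family == "*"],
               ex1$expected$c1_unassigned_positions)
  expect_equal(families(c1), ex1$expected$alphabet)

  single <- parseCompactNotation("f1")
  expect_equal(families(single), "f1")
  expect_equal(nrow(geneTable(single)), 1L)

  gaps <- parseCompactNotation("* * *")
  expect_equal(families(gaps), character())
  expect_equal(nrow(geneTable(gaps)), 3L)

  expect_error(parseCompactNotation(""), "empty")
})

test_that("parse and render round-trip token sequences exactly", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    tok <- sample(c(paste0("f", 1:4), "*"), n, replace = TRUE)
    text <- paste(tok, collapse = " ")
    expect_identical(renderCompactNotation(parseCompactNotation(text)), text)
  }
})

test_that("gene distance is |pi - pj| and undefined across chromosomes", {
  ex1 <- loadExample(1)
  g <- geneTable(ex1$genomes)
  on_c1 <- function(p) g[g$chromosome == "c1" & g$position == p, ]
  expect_equal(geneDistance(on_c1(2), on_c1(8)), 6)
  expect_equal(geneDistance(on_c1(2), on_c1(2)), 0)
  on_c2 <- g[g$chromosome == "c2" & g$position == 4, ]
  expect_error(geneDistance(on_c1(2), on_c2), "different chromosomes")
})

test_that("induced family sets exclude the unassigned sentinel", {
  ex1 <- loadExample(1)
  g <- geneTable(ex1$genomes)
  seg <- g[g$chromosome == "c1" & g$position %in% c(2, 4, 8), ]
  expect_equal(inducedFamilies(seg), c("f1", "f4"))
  expect_equal(inducedFamilies(seg[0, ]), character())
  star <- g[g$chromosome == "c1" & g$position == 3, ]
  expect_equal(inducedFamilies(star), character())
})

test_that("contiguity tolerates gaps and unassigned but not skipped genes", {
  ex1 <- loadExample(1)
  c1 <- ex1$chromosomes[[1]]
  g <- geneTable(c1)
  expect_true(isContiguous(g[g$position %in% c(4, 7, 8), ], c1))
  expect_false(isContiguous(g[g$position %in% c(2, 4, 8), ], c1))
  expect_true(isContiguous(g[g$position == 4, , drop = FALSE], c1))
})

test_that("delta-segment span shortcut equals the all-pairs check", {
  ex2 <- loadExample(2)
  g <- geneTable(ex2$chromosomes[[1]])
  seg <- g[g$position %in% c(4, 6), ]
  expect_true(isDeltaSegment(seg, 3))
  expect_false(isDeltaSegment(g[g$position %in% c(2, 4, 6), ], 3))
  expect_true(isDeltaSegment(g[g$position == 1, , drop = FALSE], 1))
  set.seed(7)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    seg <- data.frame(gene_id = letters[1:n],
                      position = sort(sample.int(12, n)),
                      family = "f1")
    delta <- sample(1:5, 1)
    allPairs <- all(outer(seg$position, seg$position,
                          function(a, b) abs(a - b))[lower.tri(diag(n))] < delta)
    expect_identical(isDeltaSegment(seg, delta), allPairs)
  }
})

test_that("genome-set validity rejects inconsistent tables", {
  df <- data.frame(species = "s1", chromosome = "c1",
                   gene_id = c("a", "b"), position = c(1L, 1L),
                   family = c("f1", "f2"))
  expect_error(GenomeSet(df), "duplicated")
  df2 <- data.frame(species = "s1", chromosome = "c1", gene_id = "a",
                    position = 0L, family = "f1")
  expect_error(GenomeSet(df2), "positive")
  fam <- data.frame(family_id = "f1", gene_id = "a")
  df3 <- data.frame(species = "s1", chromosome = "c1",
                    gene_id = c("a", "b"), position = 1:2,
                    family = c("f1", "f9"))
  expect_error(GenomeSet(df3, familyTable = fam), "absent from the family table")
  expect_s4_class(GenomeSet(df3[1, ], familyTable = fam), "GenomeSet")
})
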