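## Worked-example fixtures: the six textbook examples used throughout the
## documentation and tests, encoded with their printed expected outputs.
##
## The printed compact strings contain ambiguous asterisk runs; the encodings
## below are the reconciliations that reproduce the printed delta-subset,
## cluster and synteny lists exactly (verified by the brute-force oracle).
## Two printed inconsistencies are preserved as printed: example 5's witness
## S2 places f4 at position 8 of chromosome c2 (example 6, and the example-4
## cluster list, place it at 7), and omits (5,f8) on c3; the example-5
## fixture therefore carries the two printed syntenies verbatim, to be fed to
## the agglomeration step, alongside the example-4 chromosomes.

.EXAMPLE_STRINGS <- list(
  `1` = c(c1 = "f2 f1 * f4 * * f3 f1",
          c2 = "f1 f2 f2 f3 * f4"),
  `2` = c(c2 = "f1 f2 f2 f3 * f4"),
  `3` = c(c1 = "f3 * * f5 f4 f1 * f2 * * f5 f4",
          c2 = "f1 f2 * * f3 * f4 f5 f1 * f5",
          c3 = "f2 * f3 * * f5 * f1 f4 * f5"),
  `4` = c(c1 = "f1 * * f4 * f6 f6 f7 f8 f9",
          c2 = "* f5 * f3 f6 * f4 f2 f8 f7 f9",
          c3 = "f4 f8 f4 f7 f8 f8 * f8 f2"),
  ## example 6 considers only the region of c2 shown in the weak-bond figure
  ## (through position 9); the downstream f7/f9 tail belongs to example 4
  `6` = c(c2 = "* f5 * f3 f6 * f4 f2 f8",
          c3 = "f4 f8 f4 f7 f8 f8 * f8 f2"))

## build a free-standing witness data.frame from (species=chromosome) keyed
## position/family pairs, e.g. list(c2 = c(`9` = "f8"), ...)
.witnessDF <- function(spec) {
  df <- do.call(rbind, lapply(names(spec), function(cn) {
    pos <- as.integer(names(spec[[cn]]))
    data.frame(species = cn, chromosome = cn,
               gene_id = paste0(cn, ":", pos), position = pos,
               family = unname(spec[[cn]]), stringsAsFactors = FALSE)
  }))
  .sortGenes(df)
}

.exChromosomes <- function(strings)
  lapply(names(strings), function(cn)
    parseCompactNotation(strings[[cn]], species = cn, chromosome = cn))

#' Load a worked example as an executable fixture
#'
#' Returns the chromosomes of one of the six textbook examples together with
#' its printed expected outputs, ready to be run through the pipeline.
#'
#' @param id integer 1-6.
#' @return a list with elements among: `id`; `delta`; `chromosomes` (list of
#'   [Chromosome-class]); `genomes` ([GenomeSet-class]); `expected` (printed
#'   outputs, shape depending on the example); for example 5, `syntenies`
#'   (the two printed [Synteny-class] objects, witnesses verbatim as
#'   printed, to be agglomerated).
#' @examples
#' ex <- loadExample(2)
#' deltaSubsets(ex$chromosomes[[1]], ex$delta)
#' @export
loadExample <- function(id) {
  if (!(length(id) == 1L && id %in% 1:6)) stop("unknown example id: ", id)
  id <- as.integer(id)
  strings <- .EXAMPLE_STRINGS[[as.character(if (id == 5L) 4L else id)]]
  chromosomes <- .exChromosomes(strings)
  out <- list(id = id, chromosomes = chromosomes,
              genomes = GenomeSet(chromosomes))
  if (id == 1L) {
    out$expected <- list(
      c1_genes = .witnessDF(list(c1 = c(`1` = "f2", `2` = "f1", `4` = "f4",
                                        `7` = "f3", `8` = "f1"))),
      c1_unassigned_positions = c(3L, 5L, 6L),
      alphabet = c("f1", "f2", "f3", "f4"))
    return(out)
  }
  out$delta <- 3
  if (id == 2L) {
    out$expected <- list(subsets = list(
      `f1,f2` = list(c(1, 2), c(1, 3), c(1, 2, 3)),
      `f2,f3` = list(c(2, 4), c(3, 4), c(2, 3, 4)),
      `f3,f4` = list(c(4, 6))))
  } else if (id == 3L) {
    out$expected <- list(
      focal = "f1",
      clusterPairs = list(
        `c1,c2` = list(c("f1", "f4"), c("f1", "f5"), c("f1", "f4", "f5"),
                       c("f1", "f2"), c("f4", "f5")),
        `c1,c3` = list(c("f1", "f5"), c("f1", "f4"), c("f4", "f5"))),
      syntenies = list(c("f4", "f5"), c("f1", "f2"), c("f1", "f4"),
                       c("f1", "f5"), c("f1", "f4", "f5")))
  } else if (id == 4L) {
    out$expected <- list(
      focal = "f8",
      clusterPairs = list(
        `c1,c2` = list(c("f7", "f8", "f9"), c("f7", "f8"), c("f8", "f9")),
        `c1,c3` = list(c("f7", "f8")),
        `c2,c3` = list(c("f2", "f8"), c("f7", "f8"), c("f4", "f8"))),
      syntenies = list(c("f7", "f8", "f9"), c("f7", "f8"), c("f2", "f8"),
                       c("f4", "f8")),
      absorbed = list(c("f8", "f9")),
      absorbedInto = c("f7", "f8", "f9"))
  } else if (id == 5L) {
    S1 <- .witnessDF(list(
      c1 = c(`8` = "f7", `9` = "f8"),
      c2 = c(`9` = "f8", `10` = "f7"),
      c3 = c(`2` = "f8", `4` = "f7", `5` = "f8", `6` = "f8")))
    S2 <- .witnessDF(list(   # verbatim as printed, including (8,f4) on c2
      c2 = c(`8` = "f4", `9` = "f8"),
      c3 = c(`1` = "f4", `3` = "f4", `2` = "f8")))
    out$syntenies <- list(
      new("Synteny", families = c("f7", "f8"), witness = S1),
      new("Synteny", families = c("f4", "f8"), witness = S2))
    out$expected <- list(
      focal = "f8",
      zoneFamilies = c("f4", "f7", "f8"),
      sharedWitness = .witnessDF(list(c2 = c(`9` = "f8"),
                                      c3 = c(`2` = "f8"))),
      excludedGene = .witnessDF(list(c3 = c(`8` = "f8"))))
  } else {
    ## example 6: c3 diverged more recently than c2 (c3 below c2 in the
    ## divergence order, so c2 is the "biggest" = earliest-diverged species)
    out$genomes <- GenomeSet(chromosomes, speciesOrder = c("c3", "c2"))
    out$expected <- list(
      focal = "f8",
      syntenies = list(
        list(families = c("f2", "f8"),
             witness = .witnessDF(list(c2 = c(`8` = "f2", `9` = "f8"),
                                       c3 = c(`8` = "f8", `9` = "f2")))),
        list(families = c("f4", "f8"),
             witness = .witnessDF(list(
               c2 = c(`7` = "f4", `9` = "f8"),
               c3 = c(`1` = "f4", `2` = "f8", `3` = "f4", `5` = "f8"))))),
      weakBondWitness = .witnessDF(list(c2 = c(`9` = "f8"))),
      orthologousFamilies = c("f4", "f8"),
      paralogousFamilies = c("f2", "f8"),
      paralogousWitness = .witnessDF(list(c2 = c(`8` = "f2"),
                                          c3 = c(`8` = "f8", `9` = "f2"))))
  }
  out
}
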