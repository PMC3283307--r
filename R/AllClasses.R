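#' @import methods
NULL

## Sentinel family label for genes not assigned to any homologous family.
## Such genes occupy positions (they count toward distances) but never enter
## a chromosome's family alphabet.
UNASSIGNED <- "*"

.GENE_COLS <- c("gene_id", "position", "family")
.GENOME_COLS <- c("species", "chromosome", "gene_id", "position", "family")

.checkGeneFrame <- function(df, cols) {
  if (!is.data.frame(df)) return("genes must be a data.frame")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    return(paste("missing gene columns:", paste(miss, collapse = ", ")))
  msgs <- character()
  if (nrow(df)) {
    if (!is.numeric(df$position) || anyNA(df$position) ||
        any(df$position < 1) || any(df$position != as.integer(df$position)))
      msgs <- c(msgs, "positions must be positive integers")
    if (!is.character(df$family) || anyNA(df$family) || any(df$family == ""))
      msgs <- c(msgs, "family labels must be non-empty strings ('*' = unassigned)")
    if (!is.character(df$gene_id) || anyNA(df$gene_id) || any(df$gene_id == ""))
      msgs <- c(msgs, "gene_id must be non-empty strings")
  }
  msgs
}

#' Chromosome: an ordered sequence of positioned genes
#'
#' A chromosome is a pair of a family alphabet and an ordered gene sequence.
#' Each gene is a couple (position, family); positions are 1-based integer
#' ranks along the chromosome.  Genes with family `"*"` are unassigned: they
#' occupy positions and count toward gene-to-gene distances but are never part
#' of the alphabet.
#'
#' @slot species single species identifier.
#' @slot chromosome single chromosome identifier.
#' @slot genes `data.frame` with columns `gene_id`, `position`, `family`,
#'   sorted by position; positions are unique.
#' @export
setClass("Chromosome",
  representation(species = "character", chromosome = "character",
                 genes = "data.frame"))

setValidity("Chromosome", function(object) {
  msgs <- character()
  if (length(object@species) != 1L || is.na(object@species))
    msgs <- c(msgs, "species must be a single identifier")
  if (length(object@chromosome) != 1L || is.na(object@chromosome))
    msgs <- c(msgs, "chromosome must be a single identifier")
  msgs <- c(msgs, .checkGeneFrame(object@genes, .GENE_COLS))
  if (!length(msgs) && nrow(object@genes)) {
    p <- object@genes$position
    if (is.unsorted(p, strictly = TRUE))
      msgs <- c(msgs, "gene positions must be strictly increasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenomeSet: positioned, family-labelled genes across one or more genomes
#'
#' The central container: every gene of every chromosome of every species in
#' the study, plus the total species order used to resolve weak bonds.  The
#' species order lists species from the most recently diverged (smallest under
#' the divergence order) to the earliest diverged (biggest).
#'
#' @slot genes `data.frame` with columns `species`, `chromosome`, `gene_id`,
#'   `position`, `family`; `(species, chromosome, position)` is unique.
#' @slot speciesOrder character vector covering every species present,
#'   most recently diverged first.
#' @export
setClass("GenomeSet",
  representation(genes = "data.frame", speciesOrder = "character"))

setValidity("GenomeSet", function(object) {
  msgs <- .checkGeneFrame(object@genes, .GENOME_COLS)
  df <- object@genes
  if (!length(msgs) && nrow(df)) {
    key <- paste(df$species, df$chromosome, df$position, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicated (species, chromosome, position)")
    sp <- unique(df$species)
    if (anyDuplicated(object@speciesOrder))
      msgs <- c(msgs, "speciesOrder contains duplicates")
    if (!all(sp %in% object@speciesOrder))
      msgs <- c(msgs, "speciesOrder must cover every species present")
  }
  if (length(msgs)) msgs else TRUE
})

#' Window: a contiguous delta-segment scanned around a focal gene
#'
#' @slot species,chromosome location of the window.
#' @slot start,end the covered position interval (width delta).
#' @slot genes assigned genes falling in the interval.
#' @export
setClass("Window",
  representation(species = "character", chromosome = "character",
                 start = "integer", end = "integer", genes = "data.frame"))

#' DeltaSubset: a family set witnessed on one chromosome
#'
#' A family set of size >= 2 is a delta-subset of a chromosome when at least
#' one delta-segment (gene set in which every pairwise distance is < delta)
#' induces exactly that family set.  Each such segment is a witness.
#'
#' @slot species,chromosome location.
#' @slot families the witnessed family set (sorted).
#' @slot witnessSegments list of `data.frame`s (`gene_id`, `position`,
#'   `family`), the complete list of witnessing segments.
#' @export
setClass("DeltaSubset",
  representation(species = "character", chromosome = "character",
                 families = "character", witnessSegments = "list"))

#' GeneCluster: a family set witnessed on at least two chromosomes
#'
#' A delta-cluster is a family set that is a delta-subset on every chromosome
#' of a cover of size >= 2.  Its witness is the union, over the cover, of all
#' genes participating in witnessing segments.
#'
#' @slot families sorted family set (size >= 2).
#' @slot witness `data.frame` with columns `species`, `chromosome`,
#'   `gene_id`, `position`, `family`, canonically sorted.
#' @export
setClass("GeneCluster",
  representation(families = "character", witness = "data.frame"))

setValidity("GeneCluster", function(object) {
  msgs <- character()
  if (length(object@families) < 2L)
    msgs <- c(msgs, "a non-trivial cluster needs >= 2 families")
  if (UNASSIGNED %in% object@families)
    msgs <- c(msgs, "'*' can never be part of a family set")
  msgs <- c(msgs, .checkGeneFrame(object@witness, .GENOME_COLS))
  if (length(msgs)) msgs else TRUE
})

#' Synteny: a maximal delta-cluster
#'
#' A delta-synteny is a delta-cluster whose witness spans at least two
#' chromosomes and that is not absorbed by any strictly larger cluster fully
#' covering its witness genes.  `mergedFrom` records the absorbed clusters;
#' `label` records the orthologous/paralogous call after weak-bond resolution
#' (`NA` before resolution).
#'
#' @slot mergedFrom list of absorbed [GeneCluster-class] objects.
#' @slot label `"orthologous"`, `"paralogous"` or `NA`.
#' @export
setClass("Synteny", contains = "GeneCluster",
  representation(mergedFrom = "list", label = "character"),
  prototype(mergedFrom = list(), label = NA_character_))

#' WeakBond: two syntenies sharing exactly one witness gene
#'
#' @slot syntenyA,syntenyB the bonded syntenies.
#' @slot witnessGene one-row `data.frame`: the single shared gene.
#' @export
setClass("WeakBond",
  representation(syntenyA = "Synteny", syntenyB = "Synteny",
                 witnessGene = "data.frame"))

setValidity("WeakBond", function(object) {
  if (nrow(object@witnessGene) != 1L)
    "a weak bond has exactly one shared witness gene" else TRUE
})

#' Zone: a union of transitively connected syntenies
#'
#' Syntenies whose witnesses share at least two genes are agglomerated,
#' transitively, into one delta-zone.  A zone is labelled paralogous when all
#' of its member syntenies were demoted by weak-bond resolution, orthologous
#' otherwise.
#'
#' @slot members list of [Synteny-class] objects.
#' @slot label `"orthologous"` or `"paralogous"`.
#' @export
setClass("Zone",
  representation(members = "list", label = "character"),
  prototype(label = "orthologous"))

#' FamilyPartition: the refined classification
#'
#' Per homologous family: one orthologous subgroup (from the largest
#' orthologous zone covering it), zero or more paralogous subgroups from
#' non-intersecting paralogous zones, and leftover singleton genes.
#'
#' @slot table `data.frame` with columns `family_id`, `subgroup_id`,
#'   `subgroup_type` (`ortholog`/`paralog`/`singleton`), `gene_id`,
#'   `species`, `chromosome`, `position`.
#' @export
setClass("FamilyPartition", representation(table = "data.frame"))

#' SynsResult: the output of a full run
#'
#' @slot delta the window parameter used.
#' @slot syntenies list of [Synteny-class] (after weak-bond resolution).
#' @slot weakBonds list of [WeakBond-class].
#' @slot resolutions list of weak-bond resolutions (see [resolveWeakBond()]).
#' @slot zones list of [Zone-class].
#' @slot partition a [FamilyPartition-class].
#' @export
setClass("SynsResult",
  representation(delta = "numeric", syntenies = "list", weakBonds = "list",
                 resolutions = "list", zones = "list",
                 partition = "FamilyPartition"))

#' Classification: named groups of gene identifiers
#'
#' A partition of a set of genes into named orthologous groups; a gene
#' belongs to at most one group.
#'
#' @slot name label used in reports.
#' @slot groups named list of character vectors of gene ids.
#' @export
setClass("Classification",
  representation(name = "character", groups = "list"))

setValidity("Classification", function(object) {
  msgs <- character()
  g <- object@groups
  if (length(g)) {
    if (is.null(names(g)) || any(names(g) == ""))
      msgs <- c(msgs, "groups must be named")
    if (any(lengths(g) == 0L))
      msgs <- c(msgs, "groups must be non-empty")
    all_genes <- unlist(g, use.names = FALSE)
    if (anyDuplicated(all_genes))
      msgs <- c(msgs, paste("gene(s) appear in more than one group:",
        paste(unique(all_genes[duplicated(all_genes)])[1:min(3, sum(duplicated(all_genes)))],
              collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' ComparisonReport: accounting of the agreement between two classifications
#'
#' @slot nameA,nameB the compared classifications.
#' @slot identicalGroups number of groups identical between the two.
#' @slot similarity mean per-gene Jaccard index between the gene's group in A
#'   and in B, over the common universe (a declared substitute similarity:
#'   this is not an externally defined metric).
#' @slot onlyInA,onlyInB genes covered by exactly one classification.
#' @slot singletons genes grouped alone by B while grouped (size >= 2) in A.
#' @slot merges,splits,messy component counts (see [compareClassifications()]).
#' @export
setClass("ComparisonReport",
  representation(nameA = "character", nameB = "character",
                 identicalGroups = "integer", similarity = "numeric",
                 onlyInA = "integer", onlyInB = "integer",
                 singletons = "integer", merges = "integer",
                 splits = "integer", messy = "integer"))
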