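## Enumeration of delta-segments on one chromosome.
##
## Every delta-segment (gene set with all pairwise distances < delta) lies
## within a position interval of width delta anchored at its leftmost gene,
## so anchoring the enumeration at each gene in turn and extending only to
## genes less than delta positions to the right enumerates every segment
## exactly once.  Unassigned genes are skipped: they induce no family and are
## never printed as witnesses.
##
## Returns, per family-set key: the union of witnessing gene rows
## (`union`, integer indices into `chr`) and optionally the complete list of
## witnessing segments (`segments`).
.enumerateSegments <- function(chr, delta, keepSegments = FALSE) {
  chr <- chr[chr$family != UNASSIGNED, , drop = FALSE]
  chr <- chr[order(chr$position), , drop = FALSE]
  n <- nrow(chr)
  un <- new.env(parent = emptyenv())
  sg <- new.env(parent = emptyenv())
  if (n >= 2L) {
    pos <- chr$position
    fam <- chr$family
    for (i in seq_len(n - 1L)) {
      right <- which(pos > pos[i] & pos < pos[i] + delta)
      k <- length(right)
      if (!k) next
      for (mask in seq_len(bitwShiftL(1L, k) - 1L)) {
        sel <- right[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L]
        membersIdx <- c(i, sel)
        fams <- unique(fam[membersIdx])
        if (length(fams) < 2L) next
        key <- .famKey(fams)
        un[[key]] <- unique(c(if (!is.null(un[[key]])) un[[key]], membersIdx))
        if (keepSegments)
          sg[[key]] <- c(if (!is.null(sg[[key]])) sg[[key]], list(membersIdx))
      }
    }
  }
  keys <- sort(ls(un))
  list(
    chr = chr,
    union = stats::setNames(lapply(keys, function(k) sort(un[[k]])), keys),
    segments = if (keepSegments)
      stats::setNames(lapply(keys, function(k) sg[[k]]), keys))
}

#' Sliding windows around a focal gene
#'
#' Scans the neighbourhood from `-delta` to `+delta` around a focal gene with
#' a sliding window of width `delta`: every position interval of width
#' `delta` lying inside the neighbourhood yields the window of assigned genes
#' it contains.  Windows are contiguous delta-segments by construction;
#' windows with identical gene content are reported once.
#'
#' @param chromosome a [Chromosome-class].
#' @param focal the focal gene: a `gene_id` string or a one-row gene
#'   `data.frame`; must lie on `chromosome`.
#' @param delta positive integer window parameter.
#' @return list of [Window-class] objects, ordered by interval start.
#' @examples
#' c2 <- parseCompactNotation("f1 f2 f2 f3 * f4", "s2", "c2")
#' neighborhoodWindows(c2, "c2:2", delta = 3)
#' @export
neighborhoodWindows <- function(chromosome, focal, delta) {
  stopifnot(is(chromosome, "Chromosome"), delta >= 1)
  chr <- chromosome@genes
  id <- if (is.character(focal)) focal else focal$gene_id[1]
  hit <- match(id, chr$gene_id)
  if (is.na(hit)) stop("focal gene '", id, "' is not on this chromosome")
  p <- chr$position[hit]
  starts <- max(1L, p - as.integer(delta)):(p + 1L)
  out <- list()
  seen <- character()
  for (a in starts) {
    b <- a + as.integer(delta) - 1L
    if (b > p + delta) break
    genes <- chr[chr$position >= a & chr$position <= b &
                   chr$family != UNASSIGNED, , drop = FALSE]
    if (!nrow(genes)) next
    sig <- paste(genes$position, collapse = ",")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1L]] <- new("Window",
      species = chromosome@species, chromosome = chromosome@chromosome,
      start = a, end = b, genes = genes)
  }
  out
}

#' All non-trivial delta-subsets of one chromosome
#'
#' A family set of size >= 2 is a delta-subset when some delta-segment of the
#' chromosome induces exactly that family set; every such segment is a
#' witness.  Witnessing segments need not be contiguous: a segment may skip
#' over non-member genes as long as all pairwise distances stay below delta.
#'
#' @param chromosome a [Chromosome-class].
#' @param delta positive integer window parameter.
#' @return list of [DeltaSubset-class] objects (sorted by family set), each
#'   carrying its complete witness list.
#' @examples
#' c2 <- parseCompactNotation("f1 f2 f2 f3 * f4", "s2", "c2")
#' deltaSubsets(c2, delta = 3)
#' @export
deltaSubsets <- function(chromosome, delta) {
  stopifnot(is(chromosome, "Chromosome"), delta >= 1)
  enum <- .enumerateSegments(chromosome@genes, delta, keepSegments = TRUE)
  lapply(names(enum$union), function(key) {
    segs <- enum$segments[[key]]
    segs <- segs[!duplicated(vapply(segs,
      function(s) paste(sort(s), collapse = ","), ""))]
    segs <- segs[order(vapply(segs, function(s) min(enum$chr$position[s]), 0),
                       lengths(segs),
                       vapply(segs, function(s) max(enum$chr$position[s]), 0))]
    new("DeltaSubset", species = chromosome@species,
        chromosome = chromosome@chromosome, families = .famUnkey(key),
        witnessSegments = lapply(segs, function(s) {
          seg <- enum$chr[sort(s), .GENE_COLS, drop = FALSE]
          rownames(seg) <- NULL
          seg
        }))
  })
}

#' Delta-clusters across the chromosomes of a genome set
#'
#' A family set is a delta-cluster when it is a delta-subset on at least two
#' chromosomes; its witness is the union over those chromosomes of all genes
#' participating in witnessing segments (paralogous copies falling inside one
#' segment are all included).  When `focalFamily` is given, the scan is the
#' neighbourhood scan of that family's members: only family sets containing
#' the focal family are reported.  Every witnessing segment of such a set
#' contains a focal-family gene, so its genes automatically lie within
#' `-delta..+delta` of a member.
#'
#' @param genomes a [GenomeSet-class].
#' @param delta positive integer window parameter.
#' @param focalFamily optional family id; must exist in `genomes`.
#' @return list of [GeneCluster-class] objects, sorted by family set.
#' @examples
#' ex <- loadExample(3)
#' deltaClusters(ex$genomes, delta = 3, focalFamily = "f1")
#' @export
deltaClusters <- function(genomes, delta, focalFamily = NULL) {
  stopifnot(is(genomes, "GenomeSet"), delta >= 1)
  if (!is.null(focalFamily) && !(focalFamily %in% families(genomes)))
    stop("unknown focal family '", focalFamily, "'")
  chrs <- .splitChromosomes(genomes)
  enums <- lapply(chrs, .enumerateSegments, delta = delta)
  keysByChr <- lapply(enums, function(e) names(e$union))
  counts <- table(unlist(keysByChr, use.names = FALSE))
  keys <- sort(names(counts)[counts >= 2L])  # on >= 2 chromosomes
  if (!is.null(focalFamily))
    keys <- keys[vapply(keys, function(k) focalFamily %in% .famUnkey(k), TRUE)]
  out <- list()
  for (key in keys) {
    hasIt <- vapply(keysByChr, function(k) key %in% k, TRUE)
    wit <- do.call(rbind, lapply(enums[hasIt], function(e)
      e$chr[e$union[[key]], .GENOME_COLS, drop = FALSE]))
    out[[length(out) + 1L]] <- new("GeneCluster",
      families = .famUnkey(key), witness = .sortGenes(wit))
  }
  out
}

#' Maximal delta-syntenies from a cluster set
#'
#' A cluster is absorbed when some other cluster has a strictly larger family
#' set and its witness contains, on every chromosome, all of the smaller
#' cluster's witness genes.  Surviving clusters are the delta-syntenies; the
#' clusters a synteny absorbed are recorded in its `mergedFrom` slot.  The
#' survival test is a per-cluster predicate, so the result is independent of
#' processing order.
#'
#' @param clusters list of [GeneCluster-class] objects (as returned by
#'   [deltaClusters()]).
#' @return list of [Synteny-class] objects, sorted by family set.
#' @export
maximalSyntenies <- function(clusters) {
  if (!length(clusters)) return(list())
  keysets <- lapply(clusters, function(cl) .geneKeys(cl@witness))
  fams <- lapply(clusters, function(cl) cl@families)
  covers <- function(big, small)  # witness of `small` fully inside `big`?
    length(fams[[small]]) < length(fams[[big]]) &&
      all(fams[[small]] %in% fams[[big]]) &&
      all(keysets[[small]] %in% keysets[[big]])
  n <- length(clusters)
  absorbed <- vapply(seq_len(n), function(a)
    any(vapply(seq_len(n), function(b) a != b && covers(b, a), TRUE)), TRUE)
  surv <- which(!absorbed)
  out <- lapply(surv, function(b) {
    taken <- which(vapply(seq_len(n), function(a) a != b && covers(b, a), TRUE))
    new("Synteny", families = clusters[[b]]@families,
        witness = clusters[[b]]@witness, mergedFrom = clusters[taken],
        label = NA_character_)
  })
  out[order(vapply(out, function(s) .famKey(s@families), ""))]
}

## ---- accessors / show -----------------------------------------------------

#' @rdname accessors
setMethod("families", "GeneCluster", function(x) x@families)

#' @rdname accessors
setMethod("families", "DeltaSubset", function(x) x@families)

#' @rdname accessors
setMethod("witness", "GeneCluster", function(x) x@witness)

#' @rdname accessors
setMethod("chromosomeCover", "GeneCluster", function(x)
  sort(unique(.chrKey(x@witness$species, x@witness$chromosome))))

#' @rdname accessors
setMethod("mergedFrom", "Synteny", function(x) x@mergedFrom)

#' @rdname accessors
setMethod("zoneLabel", "Synteny", function(x) x@label)

#' @rdname accessors
setMethod("witnessSegments", "DeltaSubset", function(x) x@witnessSegments)

.fmtGene <- function(df)
  paste0("(", df$position, ",", df$family, ")", df$chromosome)

setMethod("show", "DeltaSubset", function(object) {
  cat("DeltaSubset {", paste(object@families, collapse = ","), "} on ",
      object@chromosome, ": ", length(object@witnessSegments),
      " witness segment(s)\n", sep = "")
})

setMethod("show", "GeneCluster", function(object) {
  cat(class(object), " {", paste(object@families, collapse = ","), "} over ",
      paste(chromosomeCover(object), collapse = ", "),
      "; witness: ", paste(.fmtGene(object@witness), collapse = " "),
      "\n", sep = "")
})

setMethod("show", "Window", function(object) {
  cat("Window [", object@start, ",", object@end, "] on ", object@chromosome,
      ": ", paste(.fmtGene(cbind(object@genes,
        chromosome = object@chromosome)), collapse = " "), "\n", sep = "")
})
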