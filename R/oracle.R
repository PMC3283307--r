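#' Brute-force delta-synteny computation (independent oracle)
#'
#' Exhaustively enumerates, per chromosome, every subset of assigned genes
#' (bitmask enumeration over the full power set, pruned by the pairwise
#' distance bound evaluated on the subset's extreme positions), derives all
#' delta-subsets, intersects family sets across chromosomes for clusters, and
#' applies the maximality/coverage rule literally as a double loop.  This
#' route shares no traversal structure with [deltaClusters()] /
#' [maximalSyntenies()] (which anchor a sliding enumeration at each leftmost
#' gene), so the two can check each other.
#'
#' @param genomes a [GenomeSet-class]; refused above the guard of 4
#'   chromosomes or 17 assigned genes per chromosome (combinatorial blow-up).
#' @param delta positive integer window parameter.
#' @param focalFamily optional family id restricting the result to family
#'   sets containing it.
#' @return list of [Synteny-class] objects, sorted by family set (with empty
#'   `mergedFrom`: the oracle keeps no provenance).
#' @export
bruteForceSyntenies <- function(genomes, delta, focalFamily = NULL) {
  stopifnot(is(genomes, "GenomeSet"), delta >= 1)
  chrs <- .splitChromosomes(genomes, assignedOnly = TRUE)
  if (length(chrs) > 4L)
    stop("oracle guard: more than 4 chromosomes")
  if (any(vapply(chrs, nrow, 0L) > 17L))
    stop("oracle guard: more than 17 assigned genes on one chromosome")
  perChr <- lapply(chrs, function(chr) {
    chr <- chr[order(chr$position), , drop = FALSE]
    n <- nrow(chr)
    out <- new.env(parent = emptyenv())
    if (n >= 2L) {
      masks <- seq_len(2^n - 1)
      ## positions of lowest/highest set bit; genes sorted by position, so the
      ## subset's span is the position difference of those two genes
      lo <- round(log2(bitwAnd(masks, -masks))) + 1L
      hi <- floor(log2(masks)) + 1L
      ok <- masks[lo != hi & chr$position[hi] - chr$position[lo] < delta]
      for (m in ok) {
        idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
        fams <- unique(chr$family[idx])
        if (length(fams) < 2L) next
        key <- .famKey(fams)
        out[[key]] <- unique(c(if (!is.null(out[[key]])) out[[key]], idx))
      }
    }
    list(chr = chr, map = out)
  })
  keys <- sort(unique(unlist(lapply(perChr, function(e) ls(e$map)))))
  if (!is.null(focalFamily))
    keys <- keys[vapply(keys, function(k) focalFamily %in% .famUnkey(k), TRUE)]
  clusters <- list()
  for (key in keys) {
    hasIt <- vapply(perChr, function(e) !is.null(e$map[[key]]), TRUE)
    if (sum(hasIt) < 2L) next
    wit <- do.call(rbind, lapply(perChr[hasIt], function(e)
      e$chr[sort(e$map[[key]]), .GENOME_COLS, drop = FALSE]))
    clusters[[key]] <- .sortGenes(wit)
  }
  kept <- character()
  for (a in names(clusters)) {
    fa <- .famUnkey(a); ka <- .geneKeys(clusters[[a]])
    absorbed <- FALSE
    for (b in names(clusters)) {
      if (a == b) next
      fb <- .famUnkey(b)
      if (length(fb) > length(fa) && all(fa %in% fb) &&
          all(ka %in% .geneKeys(clusters[[b]])))
        absorbed <- TRUE
    }
    if (!absorbed) kept <- c(kept, a)
  }
  lapply(sort(kept), function(k)
    new("Synteny", families = .famUnkey(k), witness = clusters[[k]],
        mergedFrom = list(), label = NA_character_))
}
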