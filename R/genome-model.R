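## ---- internal helpers -----------------------------------------------------

.chrKey <- function(species, chromosome) paste(species, chromosome, sep = "|")

.geneKeys <- function(df) paste(df$species, df$chromosome, df$position, sep = "\r")

## canonical order for gene tables: species, chromosome, position
.sortGenes <- function(df) {
  df <- df[order(df$species, df$chromosome, df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## drop duplicate (species, chromosome, position) rows, keep first
.uniqueGenes <- function(df) {
  df[!duplicated(.geneKeys(df)), , drop = FALSE]
}

## split a GenomeSet gene table into per-chromosome data.frames (named by key),
## keeping only assigned genes when assignedOnly
.splitChromosomes <- function(x, assignedOnly = FALSE) {
  df <- if (is(x, "GenomeSet")) x@genes else x
  if (assignedOnly) df <- df[df$family != UNASSIGNED, , drop = FALSE]
  if (!nrow(df)) return(list())
  split(df, .chrKey(df$species, df$chromosome))
}

.famKey <- function(families) paste(sort(families), collapse = "\x1f")
.famUnkey <- function(key) strsplit(key, "\x1f", fixed = TRUE)[[1]]

## ---- constructors ---------------------------------------------------------

#' Construct a Chromosome
#'
#' @param species,chromosome identifiers.
#' @param genes `data.frame` with columns `gene_id`, `position`, `family`
#'   (family `"*"` marks an unassigned gene).
#' @return a [Chromosome-class] object with genes sorted by position.
#' @examples
#' Chromosome("s1", "c1",
#'   data.frame(gene_id = c("a", "b"), position = c(2L, 5L),
#'              family = c("f1", "f2")))
#' @export
Chromosome <- function(species, chromosome, genes) {
  genes$position <- as.integer(genes$position)
  genes <- genes[order(genes$position), .GENE_COLS, drop = FALSE]
  rownames(genes) <- NULL
  new("Chromosome", species = as.character(species),
      chromosome = as.character(chromosome), genes = genes)
}

#' Construct a GenomeSet
#'
#' @param x either a gene `data.frame` with columns `species`, `chromosome`,
#'   `gene_id`, `position`, `family`, or a list of [Chromosome-class] objects.
#' @param speciesOrder character vector of species ids ordered by divergence
#'   time, most recently diverged first.  Defaults to the sorted species ids;
#'   the default only matters for weak-bond resolution.
#' @param familyTable optional `data.frame` with columns `family_id`,
#'   `gene_id`: the input homologous-family membership.  When supplied, every
#'   assigned gene must appear in it under its own family, otherwise an error
#'   is raised (fail-fast: no silent family creation).
#' @return a validated [GenomeSet-class].
#' @examples
#' c1 <- parseCompactNotation("f2 f1 * f4 * * f3 f1", "s1", "c1")
#' c2 <- parseCompactNotation("f1 f2 f2 f3 * f4", "s2", "c2")
#' GenomeSet(list(c1, c2))
#' @export
GenomeSet <- function(x, speciesOrder = NULL, familyTable = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    df <- do.call(rbind, lapply(x, function(ch) {
      stopifnot(is(ch, "Chromosome"))
      cbind(species = ch@species, chromosome = ch@chromosome, ch@genes,
            stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(species = character(),
      chromosome = character(), gene_id = character(),
      position = integer(), family = character())
  } else {
    df <- as.data.frame(x)
  }
  df <- df[, .GENOME_COLS, drop = FALSE]
  df$position <- as.integer(df$position)
  for (cl in c("species", "chromosome", "gene_id", "family"))
    df[[cl]] <- as.character(df[[cl]])
  df <- .sortGenes(df)
  if (is.null(speciesOrder)) speciesOrder <- sort(unique(df$species))
  if (!is.null(familyTable)) {
    assigned <- df[df$family != UNASSIGNED, , drop = FALSE]
    ok <- paste(assigned$family, assigned$gene_id) %in%
      paste(familyTable$family_id, familyTable$gene_id)
    if (!all(ok)) {
      bad <- assigned[!ok, , drop = FALSE][1, ]
      stop("gene '", bad$gene_id, "' carries family '", bad$family,
           "' absent from the family table")
    }
  }
  new("GenomeSet", genes = df, speciesOrder = as.character(speciesOrder))
}

#' Parse compact angle-bracket family notation into a Chromosome
#'
#' Tokens are whitespace-separated family labels; `"*"` marks an unassigned
#' gene.  Token k becomes the gene at position k, so unassigned genes occupy
#' positions (and count toward distances) without entering the alphabet.
#'
#' @param text compact notation, e.g. `"f2 f1 * f4 * * f3 f1"`.
#' @param species,chromosome identifiers (default both `"c?"`-style from
#'   `chromosome`).
#' @return a [Chromosome-class]; gene ids are `"<chromosome>:<position>"`.
#' @examples
#' parseCompactNotation("f1 f2 f2 f3 * f4", "s2", "c2")
#' @export
parseCompactNotation <- function(text, species = chromosome, chromosome = "c1") {
  tok <- strsplit(trimws(text), "\\s+")[[1]]
  if (!length(tok) || identical(tok, ""))
    stop("empty compact-notation string")
  genes <- data.frame(
    gene_id = paste0(chromosome, ":", seq_along(tok)),
    position = seq_along(tok), family = tok, stringsAsFactors = FALSE)
  Chromosome(species, chromosome, genes)
}

#' Render a Chromosome back to compact notation
#'
#' Inverse of [parseCompactNotation()]: positions not occupied by any gene are
#' rendered as `"*"` (indistinguishable from unassigned genes, as in the
#' printed notation).
#'
#' @param x a [Chromosome-class].
#' @return a single string of whitespace-separated tokens.
#' @export
renderCompactNotation <- function(x) {
  stopifnot(is(x, "Chromosome"))
  if (!nrow(x@genes)) return("")
  tokens <- rep(UNASSIGNED, max(x@genes$position))
  tokens[x@genes$position] <- x@genes$family
  paste(tokens, collapse = " ")
}

## ---- elementary operations ------------------------------------------------

#' Distance between two genes on one chromosome
#'
#' The distance is the absolute difference of positions.  It is undefined
#' (an error) for genes on different chromosomes.
#'
#' @param gi,gj one-row gene `data.frame`s carrying at least `position`, and
#'   `species`/`chromosome` columns when present.
#' @return a non-negative integer.
#' @export
geneDistance <- function(gi, gj) {
  for (cl in c("species", "chromosome"))
    if (cl %in% names(gi) && cl %in% names(gj) && gi[[cl]][1] != gj[[cl]][1])
      stop("distance undefined: genes on different chromosomes")
  abs(gi$position[1] - gj$position[1])
}

#' Family set induced by a gene set
#'
#' @param genes gene `data.frame` with a `family` column.
#' @return sorted character vector of distinct family labels, the unassigned
#'   sentinel excluded; empty for all-unassigned (or empty) input.
#' @export
inducedFamilies <- function(genes) {
  if (is.null(genes) || !nrow(genes)) return(character())
  sort(unique(genes$family[genes$family != UNASSIGNED]))
}

#' Is a segment contiguous on its chromosome?
#'
#' A segment is contiguous when every position strictly between two member
#' positions is either occupied by a member or corresponds to an unassigned
#' gene (or to no gene at all).
#'
#' @param segment gene `data.frame` (members), rows from one chromosome.
#' @param chromosome the [Chromosome-class] (or its gene `data.frame`)
#'   carrying the segment.
#' @return logical.
#' @export
isContiguous <- function(segment, chromosome) {
  if (!nrow(segment)) return(TRUE)
  chr <- if (is(chromosome, "Chromosome")) chromosome@genes else chromosome
  rng <- range(segment$position)
  between <- chr[chr$position > rng[1] & chr$position < rng[2] &
                   chr$family != UNASSIGNED, , drop = FALSE]
  all(between$position %in% segment$position)
}

#' Is a segment a delta-segment?
#'
#' True when every pair of member genes is separated by a distance smaller
#' than delta; since positions are totally ordered this is equivalent to
#' `max(position) - min(position) < delta`.
#'
#' @param segment gene `data.frame`.
#' @param delta positive integer window parameter.
#' @return logical (`TRUE` for empty or single-gene segments).
#' @export
isDeltaSegment <- function(segment, delta) {
  stopifnot(delta >= 1)
  if (nrow(segment) < 2L) return(TRUE)
  diff(range(segment$position)) < delta
}

## ---- accessors and show methods -------------------------------------------

#' @rdname accessors
setMethod("geneTable", "GenomeSet", function(x) x@genes)

#' @rdname accessors
setMethod("geneTable", "Chromosome", function(x) x@genes)

#' @rdname accessors
setMethod("speciesOrder", "GenomeSet", function(x) x@speciesOrder)

#' @rdname accessors
setMethod("families", "Chromosome", function(x) inducedFamilies(x@genes))

#' @rdname accessors
setMethod("families", "GenomeSet", function(x) inducedFamilies(x@genes))

setMethod("show", "Chromosome", function(object) {
  cat("Chromosome", object@chromosome, "of species", object@species, "--",
      nrow(object@genes), "positioned genes,",
      sum(object@genes$family == UNASSIGNED), "unassigned\n")
  cat("  <", renderCompactNotation(object), ">\n", sep = "")
})

setMethod("show", "GenomeSet", function(object) {
  df <- object@genes
  cat("GenomeSet:", length(unique(df$species)), "species,",
      length(unique(.chrKey(df$species, df$chromosome))), "chromosomes,",
      nrow(df), "genes (", sum(df$family == UNASSIGNED), "unassigned ),",
      length(families(object)), "families\n")
  cat("  species order (most recently diverged first):",
      paste(object@speciesOrder, collapse = " < "), "\n")
})
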