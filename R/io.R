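#' Read a gene-order table
#'
#' The gene table is TSV with header
#' `species  chromosome  gene_id  position  family`; family `"*"` marks an
#' unassigned gene.  Positions need not be consecutive (gaps are allowed).
#'
#' @param path TSV file.
#' @param speciesOrder optional character vector passed to [GenomeSet()].
#' @param familyTable optional family membership `data.frame`
#'   (`family_id`, `gene_id`); unknown family references are an error.
#' @return a validated [GenomeSet-class]; malformed rows, non-integer
#'   positions and duplicated `(species, chromosome, position)` raise errors
#'   naming the offending line.
#' @export
readGeneTable <- function(path, speciesOrder = NULL, familyTable = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  miss <- setdiff(.GENOME_COLS, names(df))
  if (length(miss))
    stop("gene table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(pos) | pos < 1 | as.numeric(df$position) != pos)
  if (length(bad))
    stop("non-integer or non-positive position at line ", bad[1] + 1L,
         " of ", path)
  df$position <- pos
  key <- paste(df$species, df$chromosome, df$position, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (species, chromosome, position) at line ", dup[1] + 1L,
         " of ", path)
  GenomeSet(df, speciesOrder = speciesOrder, familyTable = familyTable)
}

#' Write a gene-order table
#'
#' Rows are emitted in canonical order (species, chromosome, position) so
#' that identical genome sets produce byte-identical files.
#'
#' @param genomes a [GenomeSet-class].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genomes, path) {
  stopifnot(is(genomes, "GenomeSet"))
  utils::write.table(.sortGenes(genomes@genes)[, .GENOME_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a species divergence order
#'
#' Plain text, one species id per line, listed from the most recently
#' diverged species to the earliest diverged; `#` comments and blank lines
#' are ignored.
#'
#' @param path text file.
#' @return character vector of species ids.
#' @export
readSpeciesOrder <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[!startsWith(x, "#") & nzchar(x)]
  if (anyDuplicated(x)) stop("duplicated species in ", path)
  x
}

#' Read a family membership table
#'
#' @param path TSV with header `family_id  gene_id`.
#' @return `data.frame` usable as `familyTable` in [readGeneTable()].
#' @export
readFamilyTable <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  miss <- setdiff(c("family_id", "gene_id"), names(df))
  if (length(miss))
    stop("family table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Derive a gene-order table from GFF3
#'
#' Gene-type features are rank-ordered on (sequence, start) to produce
#' 1-based positions; strand is ignored (the cluster model is unordered and
#' orientation-free).  The family label is taken from a configurable
#' attribute key; features lacking it become unassigned genes.
#'
#' @param path GFF3 file.
#' @param species species id to assign to all features.
#' @param featureType feature type to keep (default `"gene"`).
#' @param familyAttribute attribute key holding the family id
#'   (default `"family"`).
#' @param idAttribute attribute key holding the gene id (default `"ID"`).
#' @param speciesOrder optional, passed to [GenomeSet()].
#' @return a [GenomeSet-class].
#' @export
readGFF3Genes <- function(path, species, featureType = "gene",
                          familyAttribute = "family", idAttribute = "ID",
                          speciesOrder = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 ingestion requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == featureType]
  if (!length(gr)) stop("no '", featureType, "' features in ", path)
  meta <- as.data.frame(gr)
  fam <- if (familyAttribute %in% names(meta))
    as.character(meta[[familyAttribute]]) else rep(NA_character_, nrow(meta))
  fam[is.na(fam) | fam == ""] <- UNASSIGNED
  ids <- if (idAttribute %in% names(meta)) as.character(meta[[idAttribute]])
         else paste0("feature", seq_len(nrow(meta)))
  df <- data.frame(species = species,
                   chromosome = as.character(meta$seqnames),
                   gene_id = ids, start = meta$start, family = fam,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  df$position <- stats::ave(seq_len(nrow(df)), df$chromosome,
                            FUN = seq_along)
  GenomeSet(df[, .GENOME_COLS], speciesOrder = speciesOrder)
}

#' Tabulate zones for output
#'
#' @param zones list of [Zone-class] objects (or a [SynsResult-class]).
#' @return `data.frame` with columns `zone_id`, `label`, `families`
#'   (comma-separated), `species`, `chromosome`, `gene_id`, `position`, one
#'   row per witness gene, canonically sorted.
#' @export
zoneTable <- function(zones) {
  if (is(zones, "SynsResult")) zones <- zones@zones
  if (!length(zones))
    return(data.frame(zone_id = character(), label = character(),
                      families = character(), species = character(),
                      chromosome = character(), gene_id = character(),
                      position = integer()))
  ord <- order(vapply(zones, function(z) .famKey(families(z)), ""))
  zones <- zones[ord]
  do.call(rbind, lapply(seq_along(zones), function(k) {
    w <- witness(zones[[k]])
    data.frame(zone_id = sprintf("zone%03d", k), label = zones[[k]]@label,
               families = paste(families(zones[[k]]), collapse = ","),
               species = w$species, chromosome = w$chromosome,
               gene_id = w$gene_id, position = w$position,
               stringsAsFactors = FALSE)
  }))
}

#' Write the zones TSV
#'
#' @param zones list of [Zone-class] objects or a [SynsResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeZoneTable <- function(zones, path) {
  utils::write.table(zoneTable(zones), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the refined family partition TSV
#'
#' @param partition a [FamilyPartition-class] or [SynsResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePartitionTable <- function(partition, path) {
  tab <- partitionTable(partition)
  utils::write.table(
    tab[, c("family_id", "subgroup_id", "subgroup_type", "gene_id")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a classification table
#'
#' @param path TSV with header `group_id  gene_id`.
#' @param name label used in reports (default: the file name).
#' @return a [Classification-class].
#' @export
readClassification <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, colClasses = "character")
  miss <- setdiff(c("group_id", "gene_id"), names(df))
  if (length(miss))
    stop("classification ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  Classification(df, name = name)
}
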