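#' Agglomerate syntenies into delta-zones
#'
#' Builds a graph on syntenies with an edge whenever two witnesses share at
#' least two genes, and merges each connected component into one delta-zone.
#' Pairs of syntenies in *different* zones that share exactly one witness
#' gene are returned as weak bonds for phylogeny-based resolution; they are
#' never merged at this stage.
#'
#' @param syntenies list of [Synteny-class] objects.
#' @return list with components `zones` (list of [Zone-class]) and
#'   `weakBonds` (list of [WeakBond-class]).
#' @examples
#' ex <- loadExample(5)
#' agglomerateZones(ex$syntenies)$zones
#' @export
agglomerateZones <- function(syntenies) {
  n <- length(syntenies)
  if (!n) return(list(zones = list(), weakBonds = list()))
  ord <- order(vapply(syntenies, function(s) .famKey(s@families), ""))
  syntenies <- syntenies[ord]
  keysets <- lapply(syntenies, function(s) .geneKeys(s@witness))
  overlap <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j) overlap[i, j] <- length(intersect(keysets[[i]], keysets[[j]]))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  strong <- which(overlap >= 2L, arr.ind = TRUE)
  if (nrow(strong))
    g <- igraph::add_edges(g, as.vector(t(strong)))
  comp <- igraph::components(g)$membership
  zones <- lapply(sort(unique(comp)), function(k)
    new("Zone", members = syntenies[comp == k], label = "orthologous"))
  bonds <- list()
  weak <- which(overlap == 1L, arr.ind = TRUE)
  if (nrow(weak)) for (r in seq_len(nrow(weak))) {
    i <- weak[r, 1]; j <- weak[r, 2]
    if (comp[i] == comp[j]) next  # already joined through >= 2-gene links
    shared <- intersect(keysets[[i]], keysets[[j]])
    wit <- syntenies[[i]]@witness
    bonds[[length(bonds) + 1L]] <- new("WeakBond",
      syntenyA = syntenies[[i]], syntenyB = syntenies[[j]],
      witnessGene = wit[.geneKeys(wit) == shared, , drop = FALSE])
  }
  list(zones = zones, weakBonds = bonds)
}

## order two bonded syntenies: larger witness first; ties broken by more
## chromosomes covered, then by lexicographic family-set order
.bondSides <- function(a, b) {
  na <- nrow(a@witness); nb <- nrow(b@witness)
  if (na != nb) return(if (na > nb) list(i = a, j = b) else list(i = b, j = a))
  ca <- length(chromosomeCover(a)); cb <- length(chromosomeCover(b))
  if (ca != cb) return(if (ca > cb) list(i = a, j = b) else list(i = b, j = a))
  if (.famKey(a@families) <= .famKey(b@families))
    list(i = a, j = b) else list(i = b, j = a)
}

.speciesRank <- function(species, order) {
  r <- match(species, order)
  if (anyNA(r))
    stop("species not covered by the species order: ",
         paste(unique(species[is.na(r)]), collapse = ", "))
  r
}

#' Resolve a weak bond using the species divergence order
#'
#' Let `Si` be the larger witness and `Sj` the smaller, and `g` their single
#' shared gene.  Species are ranked by the divergence order (most recently
#' diverged first, so a larger rank means diverged earlier).  When `g` comes
#' from the biggest species present in `Sj` -- equivalently, when no witness
#' of `Sj` comes from a species bigger than `g`'s -- the topology is
#' evolutionarily plausible (case `"AB"`); otherwise it is not (case `"C"`)
#' and no zone across the bond can be justified.  In both cases the split is
#' the same: the synteny of `Si` is the maximal orthologous synteny with
#' witness `Si`, and the synteny of `Sj` becomes paralogous with witness
#' `Sj \ g`, separating the supposed paralogous copy.
#'
#' @param bond a [WeakBond-class] (error if its witness intersection is not
#'   exactly one gene).
#' @param order species divergence order, most recently diverged first (see
#'   [readSpeciesOrder()]).
#' @return list with elements `case` (`"AB"` or `"C"`), `orthologous` and
#'   `paralogous` (the two relabelled [Synteny-class] objects) and
#'   `witnessGene`.
#' @export
resolveWeakBond <- function(bond, order) {
  stopifnot(is(bond, "WeakBond"))
  shared <- intersect(.geneKeys(bond@syntenyA@witness),
                      .geneKeys(bond@syntenyB@witness))
  if (length(shared) != 1L)
    stop("not a weak bond: witness intersection has ", length(shared),
         " genes (exactly 1 required)")
  sides <- .bondSides(bond@syntenyA, bond@syntenyB)
  si <- sides$i; sj <- sides$j
  g <- bond@witnessGene
  rj <- .speciesRank(sj@witness$species, order)
  rg <- .speciesRank(g$species[1], order)
  plausible <- rg == max(rj)
  ortho <- new("Synteny", families = si@families, witness = si@witness,
               mergedFrom = si@mergedFrom, label = "orthologous")
  reduced <- sj@witness[.geneKeys(sj@witness) != shared, , drop = FALSE]
  rownames(reduced) <- NULL
  para <- new("Synteny", families = sj@families, witness = reduced,
              mergedFrom = sj@mergedFrom, label = "paralogous")
  list(case = if (plausible) "AB" else "C",
       orthologous = ortho, paralogous = para, witnessGene = g)
}

#' Finalize the family partition from labelled zones
#'
#' Per homologous family, only the largest orthologous zone (the one holding
#' the most witness genes of that family; ties broken by total witness size,
#' then by lexicographic family set) and the paralogous zones whose witnesses
#' do not intersect the already retained zones remain.  Family members
#' covered by no retained zone become singleton subgroups.
#'
#' @param zones list of labelled [Zone-class] objects.
#' @param genomes the [GenomeSet-class] the zones were computed from.
#' @return a [FamilyPartition-class].
#' @export
finalizePartition <- function(zones, genomes) {
  stopifnot(is(genomes, "GenomeSet"))
  df <- genomes@genes
  rows <- list()
  zfams <- lapply(zones, families)
  zwit <- lapply(zones, witness)
  zkeys <- lapply(zwit, .geneKeys)
  for (f in families(genomes)) {
    membersF <- df[df$family == f, , drop = FALSE]
    withF <- which(vapply(zfams, function(fs) f %in% fs, TRUE))
    fcount <- vapply(withF, function(k) sum(zwit[[k]]$family == f), 0L)
    tcount <- vapply(withF, function(k) nrow(zwit[[k]]), 0L)
    fkey <- vapply(withF, function(k) .famKey(zfams[[k]]), "")
    ord <- withF[order(-fcount, -tcount, fkey)]
    isOrtho <- vapply(ord, function(k) zones[[k]]@label == "orthologous", TRUE)
    kept <- integer(); keptKeys <- character(); taken <- character()
    if (any(isOrtho)) {
      k <- ord[isOrtho][1]
      kept <- k; keptKeys <- zkeys[[k]]
      covered <- zwit[[k]][zwit[[k]]$family == f, , drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(family_id = f,
        subgroup_id = paste0(f, ":ortho1"), subgroup_type = "ortholog",
        covered[, c("gene_id", "species", "chromosome", "position")])
      taken <- .geneKeys(covered)
    }
    ip <- 0L
    for (k in ord[!isOrtho]) {
      if (length(intersect(zkeys[[k]], keptKeys))) next
      ip <- ip + 1L
      keptKeys <- c(keptKeys, zkeys[[k]])
      covered <- zwit[[k]][zwit[[k]]$family == f, , drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(family_id = f,
        subgroup_id = paste0(f, ":para", ip), subgroup_type = "paralog",
        covered[, c("gene_id", "species", "chromosome", "position")])
      taken <- c(taken, .geneKeys(covered))
    }
    left <- membersF[!(.geneKeys(membersF) %in% taken), , drop = FALSE]
    if (nrow(left)) {
      left <- .sortGenes(left)
      rows[[length(rows) + 1L]] <- cbind(family_id = f,
        subgroup_id = paste0(f, ":singleton", seq_len(nrow(left))),
        subgroup_type = "singleton",
        left[, c("gene_id", "species", "chromosome", "position")])
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), subgroup_id = character(),
               subgroup_type = character(), gene_id = character(),
               species = character(), chromosome = character(),
               position = integer())
  tab <- tab[order(tab$family_id, tab$subgroup_id, tab$species,
                   tab$chromosome, tab$position), , drop = FALSE]
  rownames(tab) <- NULL
  new("FamilyPartition", table = tab)
}

#' Run the full synteny-team pipeline
#'
#' Scans the neighbourhoods of family members on every chromosome, computes
#' delta-clusters and maximal delta-syntenies, agglomerates transitively
#' connected syntenies into delta-zones, resolves weak bonds against the
#' species divergence order, and finalizes the refined family partition.
#' The result is deterministic and independent of input ordering.
#'
#' @param genomes a [GenomeSet-class]; its `speciesOrder` is used for
#'   weak-bond resolution.
#' @param delta positive integer window parameter (default 7).
#' @param focalFamilies optional character vector restricting the scan to
#'   clusters containing at least one of these families (default: all).
#' @return a [SynsResult-class].
#' @examples
#' ex <- loadExample(6)
#' res <- synsRun(ex$genomes, delta = 3, focalFamilies = "f8")
#' zones(res)
#' partitionTable(res)
#' @export
synsRun <- function(genomes, delta = 7, focalFamilies = NULL) {
  stopifnot(is(genomes, "GenomeSet"), delta >= 1)
  clusters <- deltaClusters(genomes, delta)
  if (!is.null(focalFamilies))
    clusters <- clusters[vapply(clusters, function(cl)
      any(focalFamilies %in% cl@families), TRUE)]
  syn <- maximalSyntenies(clusters)
  agg <- agglomerateZones(syn)
  zones <- agg$zones
  bonds <- agg$weakBonds
  resolutions <- list()
  if (length(bonds)) {
    ord <- order(vapply(bonds, function(b)
      paste(.famKey(b@syntenyA@families), .famKey(b@syntenyB@families)), ""))
    demoted <- character()  # family keys of syntenies already made paralogous
    for (b in bonds[ord]) {
      res <- resolveWeakBond(b, genomes@speciesOrder)
      resolutions[[length(resolutions) + 1L]] <- res
      jkey <- .famKey(res$paralogous@families)
      if (jkey %in% demoted) next
      demoted <- c(demoted, jkey)
      ## replace the demoted synteny (reduced witness, paralogous label) and
      ## mark the orthologous side inside the zones
      zones <- lapply(zones, function(z) {
        z@members <- lapply(z@members, function(s) {
          k <- .famKey(s@families)
          if (k == jkey && is.na(s@label)) res$paralogous
          else if (k == .famKey(res$orthologous@families) && is.na(s@label))
            res$orthologous
          else s
        })
        z
      })
    }
    zones <- lapply(zones, function(z) {
      labs <- vapply(z@members, function(s) s@label, "")
      z@label <- if (all(!is.na(labs) & labs == "paralogous"))
        "paralogous" else "orthologous"
      z
    })
  }
  ## syntenies after resolution, as found in the zones
  syn <- unlist(lapply(zones, function(z) z@members), recursive = FALSE)
  if (is.null(syn)) syn <- list()
  syn <- syn[order(vapply(syn, function(s) .famKey(s@families), ""))]
  new("SynsResult", delta = as.numeric(delta), syntenies = syn,
      weakBonds = bonds, resolutions = resolutions, zones = zones,
      partition = finalizePartition(zones, genomes))
}

## ---- accessors / show -----------------------------------------------------

#' @rdname accessors
setMethod("members", "Zone", function(x) x@members)

#' @rdname accessors
setMethod("zoneLabel", "Zone", function(x) x@label)

#' @rdname accessors
setMethod("families", "Zone", function(x)
  sort(unique(unlist(lapply(x@members, families)))))

#' @rdname accessors
setMethod("witness", "Zone", function(x)
  .uniqueGenes(.sortGenes(do.call(rbind, lapply(x@members, witness)))))

#' @rdname accessors
setMethod("zones", "SynsResult", function(x) x@zones)

#' @rdname accessors
setMethod("syntenies", "SynsResult", function(x) x@syntenies)

#' @rdname accessors
setMethod("weakBonds", "SynsResult", function(x) x@weakBonds)

#' @rdname accessors
setMethod("partitionTable", "SynsResult", function(x) x@partition@table)

#' @rdname accessors
setMethod("partitionTable", "FamilyPartition", function(x) x@table)

setMethod("show", "Zone", function(object) {
  cat("Zone (", object@label, ") {",
      paste(families(object), collapse = ","), "}: ",
      length(object@members), " synteny(ies), ",
      nrow(witness(object)), " witness genes\n", sep = "")
})

setMethod("show", "WeakBond", function(object) {
  cat("WeakBond between {", paste(object@syntenyA@families, collapse = ","),
      "} and {", paste(object@syntenyB@families, collapse = ","),
      "}; witness gene ", .fmtGene(object@witnessGene), "\n", sep = "")
})

setMethod("show", "FamilyPartition", function(object) {
  tb <- object@table
  cat("FamilyPartition:", length(unique(tb$family_id)), "families,",
      length(unique(tb$subgroup_id)), "subgroups (",
      sum(tb$subgroup_type == "ortholog"), "ortholog /",
      sum(tb$subgroup_type == "paralog"), "paralog /",
      sum(tb$subgroup_type == "singleton"), "singleton gene rows )\n")
})

setMethod("show", "SynsResult", function(object) {
  cat("SynsResult (delta = ", object@delta, "): ",
      length(object@syntenies), " syntenies, ",
      length(object@zones), " zones, ",
      length(object@weakBonds), " weak bonds\n", sep = "")
  for (z in object@zones) show(z)
  show(object@partition)
})
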