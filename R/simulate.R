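#' Simulate genomes with planted conserved gene clusters
#'
#' Generates a multi-species genome set in which a known set of conserved
#' clusters is planted on homologous chromosomes of every species, embedded
#' in a background of species-private singleton families and unassigned
#' genes.  The generator emulates only the positional structure the cluster
#' detection consumes: planted family sets placed with bounded internal gaps,
#' optional tandem paralogous copies, and per-species gene loss.  It models
#' no sequence evolution, rearrangement process or rate structure.
#'
#' Planted genes of one cluster are laid out consecutively with
#' `0..maxInternalGap` empty positions between neighbours, so with the
#' default `maxInternalGap = 2` and cluster size 3 the whole cluster spans at
#' most 7 positions and every gene pair lies within the default window
#' `delta = 7`.  Clusters are separated by at least `clusterSeparation`
#' background positions so that distinct planted clusters never share a
#' window at that delta.
#'
#' @param speciesCount number of species (default 5, a small clade of
#'   related genomes).
#' @param chromosomesPerSpecies chromosomes per species; planted cluster `k`
#'   goes on chromosome `((k-1) %% chromosomesPerSpecies) + 1` of each
#'   species.
#' @param genesPerChromosome background positions per chromosome.
#' @param plantedClusters list of character vectors (family sets); default:
#'   `nPlanted` clusters of `plantedSize` families named `P<k>F<j>`.
#' @param nPlanted,plantedSize used when `plantedClusters` is `NULL`.
#' @param maxInternalGap maximum number of empty positions between adjacent
#'   planted genes (drawn uniformly per adjacency).
#' @param clusterSeparation minimum background positions between planted
#'   blocks (and chromosome ends).
#' @param paralogRate probability that a planted gene gains an extra copy on
#'   the same chromosome.
#' @param paralogDistance `"near"` (tandem copy adjacent to the original) or
#'   `"far"` (copy at least `clusterSeparation` positions away).
#' @param lossRate per-species probability that a planted gene is lost;
#'   scalar or vector of length `speciesCount`.
#' @param backgroundUnassignedFraction fraction of background positions
#'   holding unassigned (`"*"`) genes rather than singleton families.
#' @param seed integer seed; the same spec and seed reproduce the same
#'   tables exactly.  The caller's RNG state is left untouched.
#' @return list with `genomes` (a [GenomeSet-class]; species order is
#'   `sp1 < sp2 < ...`, most recently diverged first) and `truth`
#'   (`data.frame`: `cluster_id`, `family`, `species`, `chromosome`,
#'   `gene_id`, `position`, `is_paralog`).
#' @examples
#' sim <- simulateGenomes(speciesCount = 3, genesPerChromosome = 20,
#'                        nPlanted = 2, seed = 42)
#' sim$genomes
#' @export
simulateGenomes <- function(speciesCount = 5, chromosomesPerSpecies = 1,
                            genesPerChromosome = 100, plantedClusters = NULL,
                            nPlanted = 3, plantedSize = 3,
                            maxInternalGap = 2, clusterSeparation = 15,
                            paralogRate = 0, paralogDistance = c("near", "far"),
                            lossRate = 0,
                            backgroundUnassignedFraction = 0.2, seed = 1) {
  paralogDistance <- match.arg(paralogDistance)
  if (is.null(plantedClusters))
    plantedClusters <- lapply(seq_len(nPlanted), function(k)
      paste0("P", k, "F", seq_len(plantedSize)))
  lossRate <- rep_len(lossRate, speciesCount)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)

  speciesIds <- paste0("sp", seq_len(speciesCount))
  rows <- list(); truthRows <- list()
  for (si in seq_len(speciesCount)) {
    sp <- speciesIds[si]
    for (ci in seq_len(chromosomesPerSpecies)) {
      chrom <- paste0("chr", ci)
      onThis <- which((seq_along(plantedClusters) - 1L) %%
                        chromosomesPerSpecies + 1L == ci)
      ## token layout: background | block | background | block | ... | background
      blocks <- lapply(onThis, function(k) {
        fams <- sample(plantedClusters[[k]])
        keep <- stats::runif(length(fams)) >= lossRate[si]
        fams <- fams[keep]
        tok <- character(); isPar <- logical(); clus <- integer()
        for (f in fams) {
          if (length(tok)) {
            gap <- sample.int(maxInternalGap + 1L, 1L) - 1L
            tok <- c(tok, rep(NA_character_, gap))
            isPar <- c(isPar, rep(NA, gap)); clus <- c(clus, rep(NA, gap))
          }
          tok <- c(tok, f); isPar <- c(isPar, FALSE); clus <- c(clus, k)
          if (paralogRate > 0 && stats::runif(1) < paralogRate &&
              paralogDistance == "near") {
            tok <- c(tok, f); isPar <- c(isPar, TRUE); clus <- c(clus, k)
          }
        }
        list(tok = tok, isPar = isPar, clus = clus)
      })
      blockLen <- sum(vapply(blocks, function(b) length(b$tok), 0L))
      need <- blockLen + (length(blocks) + 1L) * clusterSeparation
      if (need > genesPerChromosome + blockLen)
        stop("infeasible placement: planted clusters need ", need,
             " positions but the chromosome offers ",
             genesPerChromosome + blockLen)
      ## split background positions into length(blocks)+1 stretches of at
      ## least clusterSeparation each
      nbg <- genesPerChromosome
      nstretch <- length(blocks) + 1L
      extra <- nbg - nstretch * clusterSeparation
      cuts <- if (nstretch > 1L)
        sort(sample.int(extra + 1L, nstretch - 1L, replace = TRUE) - 1L)
      else integer()
      stretchLen <- clusterSeparation + diff(c(0L, cuts, extra))
      tokens <- character(); isPar <- logical(); clus <- integer()
      bgUnassigned <- stats::runif(nbg) < backgroundUnassignedFraction
      bgi <- 0L
      takeBg <- function(m) {
        out <- character(m); i <- 0L
        while (i < m) {
          i <- i + 1L; bgi <<- bgi + 1L
          out[i] <- if (bgUnassigned[bgi]) UNASSIGNED else
            paste0("bg_", sp, "_", chrom, "_", bgi)
        }
        out
      }
      for (b in seq_len(nstretch)) {
        bg <- takeBg(stretchLen[b])
        tokens <- c(tokens, bg)
        isPar <- c(isPar, rep(NA, length(bg)))
        clus <- c(clus, rep(NA, length(bg)))
        if (b <= length(blocks)) {
          tokens <- c(tokens, blocks[[b]]$tok)
          isPar <- c(isPar, blocks[[b]]$isPar)
          clus <- c(clus, blocks[[b]]$clus)
        }
      }
      if (paralogRate > 0 && paralogDistance == "far") {
        ## far copies replace background genes away from every block
        for (b in blocks) for (j in which(!b$isPar %in% c(NA, TRUE))) {
          if (stats::runif(1) < paralogRate) {
            cand <- which(startsWith(ifelse(is.na(tokens), "", tokens), "bg_"))
            fpos <- which(tokens == b$tok[j])[1]
            cand <- cand[abs(cand - fpos) >= clusterSeparation]
            if (length(cand)) {
              at <- cand[sample.int(length(cand), 1L)]
              tokens[at] <- b$tok[j]; isPar[at] <- TRUE; clus[at] <- b$clus[j]
            }
          }
        }
      }
      pos <- seq_along(tokens)
      keep <- !is.na(tokens)
      df <- data.frame(species = sp, chromosome = chrom,
        gene_id = paste(sp, chrom, pos[keep], sep = "_"),
        position = pos[keep], family = tokens[keep],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- df
      planted <- keep & !is.na(clus)
      if (any(planted))
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          cluster_id = paste0("P", clus[planted]),
          family = tokens[planted], species = sp, chromosome = chrom,
          gene_id = paste(sp, chrom, pos[planted], sep = "_"),
          position = pos[planted], is_paralog = isPar[planted],
          stringsAsFactors = FALSE)
    }
  }
  genomes <- GenomeSet(do.call(rbind, rows), speciesOrder = speciesIds)
  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(cluster_id = character(), family = character(),
               species = character(), chromosome = character(),
               gene_id = character(), position = integer(),
               is_paralog = logical())
  rownames(truth) <- NULL
  list(genomes = genomes, truth = truth)
}
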