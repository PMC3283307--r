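# shared fixture builders: random genome sets for oracle sweeps, canonical
# signatures for comparing synteny sets structurally

randomGenomeSet <- function(seed, maxChromosomes = 3, maxGenes = 15,
                            nFamilies = 6, unassignedFraction = 0.2) {
  set.seed(seed)
  nchr <- sample(2:maxChromosomes, 1)
  chrs <- lapply(seq_len(nchr), function(i) {
    n <- sample(5:maxGenes, 1)
    fams <- paste0("f", sample.int(nFamilies, n, replace = TRUE))
    fams[stats::runif(n) < unassignedFraction] <- "*"
    parseCompactNotation(paste(fams, collapse = " "),
                         species = paste0("s", i), chromosome = paste0("c", i))
  })
  GenomeSet(chrs)
}

# structural signature of a synteny/cluster list: family set + witness genes
syntenySignature <- function(x) {
  sort(vapply(x, function(s)
    paste(paste(families(s), collapse = ","),
          paste(witness(s)$species, witness(s)$chromosome,
                witness(s)$position, collapse = ";"),
    sep = "|"), ""))
}

familySetSignature <- function(x)
  sort(vapply(x, function(s) paste(families(s), collapse = ","), ""))

# family sets of clusters whose chromosome cover includes both given keys
clusterPairFamilies <- function(clusters, keyA, keyB) {
  hit <- vapply(clusters, function(cl)
    all(c(keyA, keyB) %in% chromosomeCover(cl)), TRUE)
  familySetSignature(clusters[hit])
}

# free-standing synteny over (species = chromosome) position/family pairs
makeSynteny <- function(families, spec, label = NA_character_) {
  df <- do.call(rbind, lapply(names(spec), function(cn) {
    pos <- as.integer(names(spec[[cn]]))
    data.frame(species = cn, chromosome = cn,
               gene_id = paste0(cn, ":", pos), position = pos,
               family = unname(spec[[cn]]), stringsAsFactors = FALSE)
  }))
  df <- df[order(df$species, df$chromosome, df$position), ]
  rownames(df) <- NULL
  new("Synteny", families = sort(families), witness = df, label = label)
}

plantedClustersRecovered <- function(sim, res) {
  zs <- zones(res)
  planted <- split(sim$truth$family, sim$truth$cluster_id)
  length(zs) == length(planted) &&
    all(vapply(zs, function(z) zoneLabel(z) == "orthologous", TRUE)) &&
    setequal(vapply(lapply(zs, families), paste, collapse = ",", ""),
             vapply(planted, function(p)
               paste(sort(unique(p)), collapse = ","), ""))
}
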