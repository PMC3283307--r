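#' Construct a Classification
#'
#' @param groups named list of character vectors of gene ids, or a
#'   `data.frame` with columns `group_id`, `gene_id`.
#' @param name label used in reports.
#' @return a validated [Classification-class]; a gene appearing in more than
#'   one group is an error.
#' @export
Classification <- function(groups, name = "classification") {
  if (is.data.frame(groups))
    groups <- split(as.character(groups$gene_id), as.character(groups$group_id))
  new("Classification", name = name, groups = groups)
}

#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname accessors
setMethod("groups", "Classification", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname accessors
setMethod("universe", "Classification", function(x)
  sort(unique(unlist(x@groups, use.names = FALSE))))

setMethod("show", "Classification", function(object) {
  cat("Classification '", object@name, "': ", length(object@groups),
      " groups over ", length(universe(object)), " genes\n", sep = "")
})

#' Compare two orthologous-group classifications
#'
#' Builds the bipartite overlap graph between the groups of `a` and `b`
#' restricted to the common universe (genes covered by both) and accounts
#' for every connected component:
#' * *identical* -- a 1-to-1 component whose two groups have equal full
#'   member sets;
#' * *split* -- one `a` group overlapping two or more `b` groups;
#' * *merge* -- two or more `a` groups overlapping one `b` group;
#' * *messy* -- any other multi-group component (including 1-to-1 components
#'   whose full member sets differ).
#'
#' `onlyInA`/`onlyInB` count genes covered by exactly one classification;
#' `singletons` counts genes grouped alone by `b` while grouped (in a group
#' of size >= 2) by `a`.  The similarity is the mean, over common-universe
#' genes, of the Jaccard index between the gene's `a` group and `b` group
#' (both restricted to the common universe) -- a declared substitute
#' summary, not an externally defined metric; it is 1 exactly when the two
#' classifications restricted to the common universe are identical
#' partitions.
#'
#' @param a,b [Classification-class] objects (convention: `a` is the other
#'   method, `b` the synteny-based classification, so `splits` counts `a`
#'   groups split apart by `b`).
#' @return a [ComparisonReport-class].
#' @examples
#' a <- Classification(list(g1 = c("x", "y", "z")), "a")
#' b <- Classification(list(h1 = c("x", "y"), h2 = "z"), "b")
#' compareClassifications(a, b)
#' @export
compareClassifications <- function(a, b) {
  stopifnot(is(a, "Classification"), is(b, "Classification"))
  ua <- universe(a); ub <- universe(b)
  common <- intersect(ua, ub)
  gmapA <- rep(names(a@groups), lengths(a@groups))
  names(gmapA) <- unlist(a@groups, use.names = FALSE)
  gmapB <- rep(names(b@groups), lengths(b@groups))
  names(gmapB) <- unlist(b@groups, use.names = FALSE)

  identicalGroups <- 0L; merges <- 0L; splits <- 0L; messy <- 0L
  if (length(common)) {
    pairs <- unique(data.frame(ga = gmapA[common], gb = gmapB[common],
                               stringsAsFactors = FALSE))
    ## connected components of the bipartite group-overlap graph
    vertA <- unique(pairs$ga); vertB <- unique(pairs$gb)
    g <- igraph::graph_from_edgelist(cbind(paste0("A\r", pairs$ga),
                                           paste0("B\r", pairs$gb)),
                                     directed = FALSE)
    comp <- igraph::components(g)$membership
    for (k in unique(comp)) {
      vs <- names(comp)[comp == k]
      nA <- sum(startsWith(vs, "A\r")); nB <- sum(startsWith(vs, "B\r"))
      if (nA == 1L && nB == 1L) {
        ga <- sub("^A\r", "", vs[startsWith(vs, "A\r")])
        gb <- sub("^B\r", "", vs[startsWith(vs, "B\r")])
        if (setequal(a@groups[[ga]], b@groups[[gb]]))
          identicalGroups <- identicalGroups + 1L
        else messy <- messy + 1L
      } else if (nA == 1L && nB >= 2L) splits <- splits + 1L
      else if (nA >= 2L && nB == 1L) merges <- merges + 1L
      else messy <- messy + 1L
    }
  }
  jac <- if (length(common)) {
    restA <- lapply(a@groups, intersect, common)
    restB <- lapply(b@groups, intersect, common)
    mean(vapply(common, function(gene) {
      ga <- restA[[gmapA[[gene]]]]; gb <- restB[[gmapB[[gene]]]]
      length(intersect(ga, gb)) / length(union(ga, gb))
    }, 0))
  } else NA_real_
  singles <- if (length(common)) {
    sizeB <- lengths(b@groups)[gmapB[common]]
    sizeA <- lengths(a@groups)[gmapA[common]]
    sum(sizeB == 1L & sizeA >= 2L)
  } else 0L
  new("ComparisonReport", nameA = a@name, nameB = b@name,
      identicalGroups = identicalGroups, similarity = jac,
      onlyInA = length(setdiff(ua, ub)), onlyInB = length(setdiff(ub, ua)),
      singletons = as.integer(singles), merges = merges, splits = splits,
      messy = messy)
}

setMethod("show", "ComparisonReport", function(object) {
  cat("Comparison of '", object@nameA, "' (A) vs '", object@nameB,
      "' (B)\n", sep = "")
  cat(sprintf("  identical groups : %d\n", object@identicalGroups))
  cat(sprintf("  similarity       : %.3f  (mean per-gene Jaccard over the common universe;\n",
              object@similarity))
  cat("                      a substitute summary, not an externally defined metric)\n")
  cat(sprintf("  only in A / B    : %d / %d genes\n",
              object@onlyInA, object@onlyInB))
  cat(sprintf("  singletons       : %d  (genes grouped alone by B, grouped by A)\n",
              object@singletons))
  cat(sprintf("  merges / splits / messy : %d / %d / %d\n",
              object@merges, object@splits, object@messy))
})

#' Write a comparison report as TSV
#'
#' @param report a [ComparisonReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeComparisonReport <- function(report, path) {
  df <- data.frame(
    a = report@nameA, b = report@nameB,
    identical = report@identicalGroups, similarity = report@similarity,
    only_in_a = report@onlyInA, only_in_b = report@onlyInB,
    singletons = report@singletons, merges = report@merges,
    splits = report@splits, messy = report@messy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
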