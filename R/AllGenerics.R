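#' Accessors for syntenyTeams classes
#'
#' `families()` returns the family set of a cluster, synteny, zone or
#' chromosome alphabet; `witness()` the witnessing gene table; `geneTable()`
#' the underlying gene table; `speciesOrder()` the divergence order;
#' `chromosomeCover()` the `species|chromosome` keys contributing witnesses;
#' `zoneLabel()` the orthologous/paralogous call; `members()` a zone's member
#' syntenies; `mergedFrom()` the clusters absorbed into a synteny;
#' `witnessSegments()` the complete witness list of a delta-subset;
#' `zones()`, `syntenies()`, `weakBonds()` and `partitionTable()` the parts of
#' a [SynsResult-class].
#'
#' @param x an object of the appropriate class.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname accessors
#' @export
setGeneric("witness", function(x) standardGeneric("witness"))

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname accessors
#' @export
setGeneric("speciesOrder", function(x) standardGeneric("speciesOrder"))

#' @rdname accessors
#' @export
setGeneric("chromosomeCover", function(x) standardGeneric("chromosomeCover"))

#' @rdname accessors
#' @export
setGeneric("zoneLabel", function(x) standardGeneric("zoneLabel"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("mergedFrom", function(x) standardGeneric("mergedFrom"))

#' @rdname accessors
#' @export
setGeneric("witnessSegments", function(x) standardGeneric("witnessSegments"))

#' @rdname accessors
#' @export
setGeneric("zones", function(x) standardGeneric("zones"))

#' @rdname accessors
#' @export
setGeneric("syntenies", function(x) standardGeneric("syntenies"))

#' @rdname accessors
#' @export
setGeneric("weakBonds", function(x) standardGeneric("weakBonds"))

#' @rdname accessors
#' @export
setGeneric("partitionTable", function(x) standardGeneric("partitionTable"))
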