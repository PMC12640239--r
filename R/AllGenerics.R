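#' Metabolite names of an object
#'
#' @param x a MetNetBench object carrying an ordered metabolite name set.
#' @return character vector of metabolite names, in canonical order.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "MetabolicNetwork", function(x) x@nodes)
#' @rdname nodeNames
#' @export
setMethod("nodeNames", "AdjacencyMatrix", function(x) rownames(x@adj))
#' @rdname nodeNames
#' @export
setMethod("nodeNames", "SampleMatrix", function(x) colnames(x@values))
#' @rdname nodeNames
#' @export
setMethod("nodeNames", "AssociationMatrix", function(x) rownames(x@entries))
#' @rdname nodeNames
#' @export
setMethod("nodeNames", "BinaryNetwork", function(x) rownames(x@entries))
#' @rdname nodeNames
#' @export
setMethod("nodeNames", "ConsensusNetwork", function(x) rownames(x@frequencies))

#' Reactions of a network
#'
#' @param x a [MetabolicNetwork-class].
#' @return list of [Reaction-class] objects.
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname reactions
#' @export
setMethod("reactions", "MetabolicNetwork", function(x) x@reactions)

#' Efflux node set of a network
#' @param x a [MetabolicNetwork-class].
#' @return character vector of nodes with removal reactions.
#' @export
setGeneric("effluxNodes", function(x) standardGeneric("effluxNodes"))
#' @rdname effluxNodes
#' @export
setMethod("effluxNodes", "MetabolicNetwork", function(x) x@efflux)

#' Association score family
#' @param x an [AssociationMatrix-class].
#' @return \code{"signed_correlation"} or \code{"nonnegative"}.
#' @export
setGeneric("assocFamily", function(x) standardGeneric("assocFamily"))
#' @rdname assocFamily
#' @export
setMethod("assocFamily", "AssociationMatrix", function(x) x@family)

#' Threshold used to binarize a network
#' @param x a [BinaryNetwork-class].
#' @return numeric(1), \code{NA} when the network was given, not thresholded.
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname thresholdUsed
#' @export
setMethod("thresholdUsed", "BinaryNetwork", function(x) x@threshold)

#' Bootstrap edge-frequency matrix
#' @param x a [ConsensusNetwork-class].
#' @return symmetric numeric matrix of per-pair bootstrap frequencies.
#' @export
setGeneric("edgeFrequencies", function(x) standardGeneric("edgeFrequencies"))
#' @rdname edgeFrequencies
#' @export
setMethod("edgeFrequencies", "ConsensusNetwork", function(x) x@frequencies)

#' Reliable-edge network of a consensus
#' @param x a [ConsensusNetwork-class].
#' @return [BinaryNetwork-class] of edges with frequency strictly above the
#'   reliability threshold.
#' @export
setGeneric("reliableNetwork", function(x) standardGeneric("reliableNetwork"))
#' @rdname reliableNetwork
#' @export
setMethod("reliableNetwork", "ConsensusNetwork", function(x) x@reliable)

#' @export
setMethod("as.matrix", "AdjacencyMatrix", function(x, ...) x@adj)
#' @export
setMethod("as.matrix", "SampleMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@entries)
#' @export
setMethod("as.matrix", "BinaryNetwork", function(x, ...) x@entries)

#' @export
setMethod("dim", "SampleMatrix", function(x) dim(x@values))

setMethod("show", "Reaction", function(object) {
    rhs <- if (object@sink) "(sink)" else paste(object@products, collapse = " + ")
    cat(sprintf("Reaction %s [%s]: %s -> %s | %s\n", object@id, object@law,
                paste(object@substrates, collapse = " + "), rhs,
                paste(names(object@params), signif(object@params, 4),
                      sep = "=", collapse = ", ")))
})

setMethod("show", "MetabolicNetwork", function(object) {
    nefx <- sum(vapply(object@reactions, function(r) isTRUE(r@sink), logical(1)))
    cat(sprintf("MetabolicNetwork: %d metabolites, %d reactions (%d efflux)\n",
                length(object@nodes), length(object@reactions), nefx))
    if (length(object@influx))
        cat("  influx at:", paste(names(object@influx), collapse = ", "), "\n")
})

setMethod("show", "AdjacencyMatrix", function(object) {
    cat(sprintf("AdjacencyMatrix: %d nodes, %d edges\n",
                nrow(object@adj), sum(object@adj[upper.tri(object@adj)])))
})

setMethod("show", "SampleMatrix", function(object) {
    cat(sprintf("SampleMatrix: %d samples x %d metabolites\n",
                nrow(object@values), ncol(object@values)))
})

setMethod("show", "AssociationMatrix", function(object) {
    cat(sprintf("AssociationMatrix (%s%s): %d nodes\n", object@family,
                if (is.na(object@method)) "" else paste0(", ", object@method),
                nrow(object@entries)))
})

setMethod("show", "BinaryNetwork", function(object) {
    cat(sprintf("BinaryNetwork: %d nodes, %d edges (threshold %s)\n",
                nrow(object@entries),
                sum(object@entries[upper.tri(object@entries)]),
                if (is.na(object@threshold)) "given"
                else signif(object@threshold, 4)))
})

setMethod("show", "ConsensusNetwork", function(object) {
    cat(sprintf(
        "ConsensusNetwork: %d nodes, %d reliable edges (frequency > %g)\n",
        nrow(object@frequencies),
        sum(object@reliable@entries[upper.tri(object@reliable@entries)]),
        object@reliabilityThreshold))
})
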