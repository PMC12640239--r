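#' @import methods
NULL

#' Reaction: one kinetically parameterized reaction
#'
#' A single reaction of a [MetabolicNetwork-class]. Mass-action reactions
#' carry a rate constant \code{k} and may have several substrates (rate
#' \eqn{v = k \prod_s [S_s]}); Michaelis-Menten reactions carry \code{Vmax}
#' and \code{Km}, are restricted to a single substrate, and follow
#' \eqn{v = V_{max} [S] / (K_m + [S])}. Efflux (removal) reactions are
#' flagged with \code{sink = TRUE} and have no products.
#'
#' @slot id character(1), unique within the parent network.
#' @slot substrates character vector of metabolite names (non-empty).
#' @slot products character vector of metabolite names; empty only when
#'   \code{sink} is \code{TRUE}.
#' @slot law \code{"mass_action"} or \code{"michaelis_menten"}.
#' @slot params named numeric, strictly positive: \code{k} for mass action,
#'   \code{Vmax} and \code{Km} for Michaelis-Menten.
#' @slot sink logical(1), \code{TRUE} for first-order removal reactions.
#' @exportClass Reaction
setClass("Reaction",
    representation(
        id = "character",
        substrates = "character",
        products = "character",
        law = "character",
        params = "numeric",
        sink = "logical"
    ),
    prototype(sink = FALSE)
)

setValidity("Reaction", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "id must be a single non-empty string")
    if (!object@law %in% c("mass_action", "michaelis_menten"))
        msg <- c(msg, "law must be 'mass_action' or 'michaelis_menten'")
    if (length(object@substrates) < 1L)
        msg <- c(msg, "substrates must be non-empty")
    if (length(object@products) < 1L && !isTRUE(object@sink))
        msg <- c(msg, "products empty but sink flag not set")
    if (any(!is.finite(object@params)) || any(object@params <= 0))
        msg <- c(msg, "all kinetic parameters must be strictly positive")
    if (object@law == "mass_action" && !"k" %in% names(object@params))
        msg <- c(msg, "mass_action reaction needs parameter 'k'")
    if (object@law == "michaelis_menten") {
        if (!all(c("Vmax", "Km") %in% names(object@params)))
            msg <- c(msg, "michaelis_menten reaction needs 'Vmax' and 'Km'")
        if (length(object@substrates) != 1L)
            msg <- c(msg, "michaelis_menten reactions take a single substrate")
    }
    if (length(msg)) msg else TRUE
})

#' MetabolicNetwork: nodes plus kinetically parameterized reactions
#'
#' The ground truth of the synthetic-data generator: an ordered set of
#' metabolite names, a list of [Reaction-class] objects, the set of nodes
#' carrying first-order efflux (removal) reactions, and an optional constant
#' influx (source flux, concentration/hour) keeping the system away from the
#' trivial all-zero steady state.
#'
#' @slot nodes character vector of unique metabolite names (column order of
#'   all derived matrices).
#' @slot reactions list of [Reaction-class].
#' @slot efflux character vector: nodes with removal reactions.
#' @slot influx named numeric: constant production rates, names in
#'   \code{nodes}. May be empty (closed system).
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
    representation(
        nodes = "character",
        reactions = "list",
        efflux = "character",
        influx = "numeric"
    ),
    prototype(influx = numeric())
)

setValidity("MetabolicNetwork", function(object) {
    msg <- character()
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node names must be unique")
    ids <- vapply(object@reactions, function(r) r@id, character(1))
    if (anyDuplicated(ids))
        msg <- c(msg, "reaction ids must be unique")
    for (r in object@reactions) {
        if (!is(r, "Reaction")) {
            msg <- c(msg, "reactions must be Reaction objects")
            break
        }
        v <- validObject(r, test = TRUE)
        if (is.character(v)) msg <- c(msg, paste0(r@id, ": ", v))
        bad <- setdiff(c(r@substrates, r@products), object@nodes)
        if (length(bad))
            msg <- c(msg, paste0(r@id, ": unknown metabolite(s) ",
                                 paste(bad, collapse = ", ")))
    }
    if (length(bad <- setdiff(object@efflux, object@nodes)))
        msg <- c(msg, paste0("efflux names not in nodes: ",
                             paste(bad, collapse = ", ")))
    if (length(object@influx)) {
        if (is.null(names(object@influx)) ||
            length(bad <- setdiff(names(object@influx), object@nodes)))
            msg <- c(msg, "influx must be named by known metabolites")
        if (any(object@influx <= 0))
            msg <- c(msg, "influx rates must be strictly positive")
    }
    if (length(msg)) msg else TRUE
})

#' AdjacencyMatrix: binary symmetric reference interactions
#'
#' Ground-truth interaction matrix: entry \eqn{(x, y)} is 1 when some
#' non-efflux reaction links metabolites \eqn{x} and \eqn{y}, 0 otherwise.
#' Symmetric with a zero diagonal.
#'
#' @slot adj binary numeric matrix with identical row/column names.
#' @exportClass AdjacencyMatrix
setClass("AdjacencyMatrix", representation(adj = "matrix"))

setValidity("AdjacencyMatrix", function(object) {
    m <- object@adj
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
        msg <- c(msg, "row and column names must be identical metabolite names")
    if (!all(m %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
    if (!isTRUE(all.equal(m, t(m)))) msg <- c(msg, "matrix must be symmetric")
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
    if (length(msg)) msg else TRUE
})

#' SampleMatrix: samples-by-metabolites steady-state concentrations
#'
#' Rows are simulated (or measured) samples, columns are metabolites in the
#' generating network's node order. All entries are finite and nonnegative.
#'
#' @slot values numeric matrix, samples x metabolites, with column names.
#' @exportClass SampleMatrix
setClass("SampleMatrix", representation(values = "matrix"))

setValidity("SampleMatrix", function(object) {
    m <- object@values
    msg <- character()
    if (is.null(colnames(m))) msg <- c(msg, "columns must carry metabolite names")
    if (any(!is.finite(m))) msg <- c(msg, "all entries must be finite")
    if (any(m < 0)) msg <- c(msg, "concentrations must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' AssociationMatrix: symmetric pairwise association scores
#'
#' The common currency of all network inference algorithms: a symmetric
#' real matrix of pairwise scores with a zero diagonal. The \code{family}
#' records the score semantics: \code{"signed_correlation"} entries lie in
#' \eqn{[-1, 1]}; \code{"nonnegative"} entries (mutual information, CLR,
#' MRNET, PCLRC, tree importance, aspirational) are \eqn{\ge 0}.
#'
#' @slot entries symmetric numeric matrix, zero diagonal, named dims.
#' @slot family \code{"signed_correlation"} or \code{"nonnegative"}.
#' @slot method character(1): the producing algorithm (informational).
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
    representation(entries = "matrix", family = "character",
                   method = "character"),
    prototype(method = NA_character_)
)

setValidity("AssociationMatrix", function(object) {
    m <- object@entries
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "row and column names must be identical")
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
        msg <- c(msg, "matrix must be symmetric")
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
    if (!object@family %in% c("signed_correlation", "nonnegative"))
        msg <- c(msg, "family must be 'signed_correlation' or 'nonnegative'")
    if (identical(object@family, "signed_correlation") &&
        any(abs(m) > 1 + 1e-8))
        msg <- c(msg, "signed_correlation entries must lie in [-1, 1]")
    if (identical(object@family, "nonnegative") && any(m < 0))
        msg <- c(msg, "nonnegative-family entries must be >= 0")
    if (length(msg)) msg else TRUE
})

#' BinaryNetwork: thresholded association matrix
#'
#' @slot entries binary symmetric matrix, zero diagonal, named dims.
#' @slot threshold numeric(1) threshold used, or \code{NA} when the network
#'   was given directly rather than thresholded.
#' @exportClass BinaryNetwork
setClass("BinaryNetwork",
    representation(entries = "matrix", threshold = "numeric"),
    prototype(threshold = NA_real_)
)

setValidity("BinaryNetwork", function(object) {
    m <- object@entries
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "row and column names must be identical")
    if (!all(m %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
    if (!identical(unname(m), unname(t(m)))) msg <- c(msg, "matrix must be symmetric")
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
    if (length(msg)) msg else TRUE
})

#' ConsensusNetwork: bootstrap edge frequencies and reliable edges
#'
#' Result of [bootstrapConsensus()]: per-pair frequency of appearing in the
#' bootstrap networks, and the reliable-edge network (pairs whose frequency
#' strictly exceeds the reliability threshold).
#'
#' @slot frequencies symmetric numeric matrix in \eqn{[0, 1]}, zero diagonal.
#' @slot reliable [BinaryNetwork-class] of reliable edges.
#' @slot reliabilityThreshold numeric(1), strict lower bound on frequency.
#' @slot networks list of per-bootstrap [BinaryNetwork-class] (possibly
#'   empty when not retained).
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
    representation(frequencies = "matrix", reliable = "BinaryNetwork",
                   reliabilityThreshold = "numeric", networks = "list")
)

setValidity("ConsensusNetwork", function(object) {
    f <- object@frequencies
    msg <- character()
    if (any(f < 0 | f > 1)) msg <- c(msg, "frequencies must lie in [0, 1]")
    if (!isTRUE(all.equal(f, t(f)))) msg <- c(msg, "frequencies must be symmetric")
    rel <- object@reliable@entries
    expected <- (f > object@reliabilityThreshold) + 0
    diag(expected) <- 0
    if (!isTRUE(all.equal(unname(rel), unname(expected))))
        msg <- c(msg, "reliable edges must be pairs with frequency strictly above threshold")
    if (length(msg)) msg else TRUE
})
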