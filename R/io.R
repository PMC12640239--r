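# File interchange: adjacency/association CSV (names in first row and
# column), samples CSV (header of metabolite names, optional sample_id
# column), and a versioned network JSON schema.

#' Write / read an adjacency matrix as CSV
#'
#' First row and first column carry the metabolite names; body entries are
#' 0/1, comma-separated.
#'
#' @param adj an [AdjacencyMatrix-class].
#' @param path file path.
#' @return \code{writeAdjacency} returns \code{path} invisibly;
#'   \code{readAdjacency} returns an [AdjacencyMatrix-class].
#' @export
writeAdjacency <- function(adj, path) {
    utils::write.csv(as.data.frame(as.matrix(adj)), path)
    invisible(path)
}

#' @rdname writeAdjacency
#' @export
readAdjacency <- function(path) {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (any(is.na(m)))
        stop("adjacency file contains missing values: ", path, call. = FALSE)
    if (!isTRUE(all.equal(unname(m), unname(t(m)))))
        stop("adjacency matrix in ", path, " is not symmetric", call. = FALSE)
    storage.mode(m) <- "double"
    colnames(m) <- rownames(m)
    new("AdjacencyMatrix", adj = m)
}

#' Write / read a sample matrix as CSV
#'
#' Header row of metabolite names, one row per sample, first column
#' \code{sample_id}.
#'
#' @param samples a [SampleMatrix-class].
#' @param path file path.
#' @return \code{writeSamples} returns \code{path} invisibly;
#'   \code{readSamples} returns a [SampleMatrix-class].
#' @export
writeSamples <- function(samples, path) {
    df <- data.frame(sample_id = seq_len(nrow(as.matrix(samples))),
                     as.matrix(samples), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSamples
#' @export
readSamples <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if ("sample_id" %in% names(df)) df$sample_id <- NULL
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-finite concentration at row ", bad[1, 1], ", column '",
             colnames(m)[bad[1, 2]], "' of ", path, call. = FALSE)
    new("SampleMatrix", values = m)
}

#' Load a deposited reference adjacency and sample table
#'
#' Reads an adjacency CSV and a samples CSV, checks that the metabolite
#' name sets match, and reorders the sample columns to the adjacency's
#' order when they differ (with a message).
#'
#' @param adjacencyPath path to the adjacency CSV.
#' @param samplesPath path to the samples CSV.
#' @return list with elements \code{adjacency} ([AdjacencyMatrix-class])
#'   and \code{samples} ([SampleMatrix-class]) in matching name order.
#' @export
loadReference <- function(adjacencyPath, samplesPath) {
    adj <- readAdjacency(adjacencyPath)
    sm <- readSamples(samplesPath)
    an <- nodeNames(adj); sn <- nodeNames(sm)
    if (!setequal(an, sn))
        stop("metabolite name sets differ between adjacency and samples",
             call. = FALSE)
    if (!identical(an, sn)) {
        message("reordering sample columns to adjacency order")
        sm <- new("SampleMatrix", values = as.matrix(sm)[, an, drop = FALSE])
    }
    list(adjacency = adj, samples = sm)
}

#' Write / read a metabolic network as JSON
#'
#' Documented schema with a \code{format_version} field: \code{nodes},
#' \code{reactions} (id, substrates, products, law, params, sink) and
#' \code{influx}.
#'
#' @param net a [MetabolicNetwork-class].
#' @param path file path.
#' @return \code{writeNetworkJSON} returns \code{path} invisibly;
#'   \code{readNetworkJSON} returns a [MetabolicNetwork-class].
#' @export
writeNetworkJSON <- function(net, path) {
    obj <- list(
        format_version = 1L,
        nodes = net@nodes,
        reactions = lapply(net@reactions, function(r) list(
            id = r@id, substrates = r@substrates, products = r@products,
            law = r@law, params = as.list(r@params), sink = r@sink)),
        influx = as.list(net@influx))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeNetworkJSON
#' @export
readNetworkJSON <- function(path) {
    obj <- jsonlite::read_json(path)
    if (is.null(obj$format_version) || obj$format_version != 1L)
        stop("unsupported network JSON format version", call. = FALSE)
    rxns <- lapply(obj$reactions, function(r)
        reaction(r$id, unlist(r$substrates),
                 if (length(r$products)) unlist(r$products) else character(),
                 r$law, unlist(r$params), sink = isTRUE(r$sink)))
    metabolicNetwork(unlist(obj$nodes), rxns,
                     influx = if (length(obj$influx)) unlist(obj$influx)
                              else numeric())
}
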