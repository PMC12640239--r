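#' Construct a single reaction
#'
#' Convenience constructor for [Reaction-class] objects used when building a
#' [MetabolicNetwork-class] by hand.
#'
#' @param id unique reaction identifier.
#' @param substrates character vector of substrate metabolite names.
#' @param products character vector of product names; omit (default) together
#'   with \code{sink = TRUE} for removal reactions.
#' @param law \code{"mass_action"} or \code{"michaelis_menten"}.
#' @param params named numeric: \code{k}, or \code{Vmax} and \code{Km}.
#' @param sink \code{TRUE} for a first-order removal (efflux) reaction.
#' @return a validated [Reaction-class].
#' @examples
#' reaction("r1", "A", "B", "mass_action", c(k = 2))
#' @export
reaction <- function(id, substrates, products = character(), law, params,
                     sink = FALSE) {
    new("Reaction", id = id, substrates = substrates, products = products,
        law = law, params = params, sink = sink)
}

#' Assemble a metabolic network from parts
#'
#' @param nodes ordered character vector of metabolite names.
#' @param reactions list of [Reaction-class] objects.
#' @param influx optional named numeric of constant source fluxes
#'   (concentration per hour) into named metabolites.
#' @return a validated [MetabolicNetwork-class]. The efflux node set is
#'   derived from the \code{sink}-flagged reactions.
#' @examples
#' net <- metabolicNetwork(
#'   c("A", "B"),
#'   list(reaction("f", "A", "B", "mass_action", c(k = 2)),
#'        reaction("b", "B", "A", "mass_action", c(k = 1))))
#' @export
metabolicNetwork <- function(nodes, reactions, influx = numeric()) {
    efflux <- unique(unlist(lapply(reactions, function(r)
        if (isTRUE(r@sink)) r@substrates else character())))
    new("MetabolicNetwork", nodes = nodes, reactions = reactions,
        efflux = as.character(efflux), influx = influx)
}

#' Generate a random sparse metabolic reaction network
#'
#' Emulates the class of curated kinetic models used as inference ground
#' truths: a sparse, largely tree-like reaction network with a few cycles,
#' mixed mass-action and Michaelis-Menten kinetics, a constant source flux
#' at a designated core (root) metabolite, and first-order removal at every
#' terminal (degree-1) node as well as at every node without an onward
#' reaction (which would otherwise accumulate mass indefinitely). A random
#' spanning tree over \code{nNodes}
#' metabolites is drawn and every edge becomes a reaction oriented away from
#' the root; \code{nExtraEdges} additional reactions (also oriented away
#' from the root, shallow to deep) close cycles.
#'
#' Kinetic parameters are drawn log-uniformly: \code{k}, \code{Vmax} from
#' \eqn{[0.1, 10]}, \code{Km} from \eqn{[0.5, 5]}, efflux rate constants
#' from \eqn{[0.05, 0.5]} and the root influx from \eqn{[0.01, 0.05]}. The
#' influx ceiling keeps the source flux below every reaction's saturable
#' capacity so a positive steady state always exists.
#'
#' @param nNodes number of metabolites (\eqn{\ge 3}).
#' @param nExtraEdges reactions beyond the spanning tree (cycles).
#' @param mmFraction proportion of internal reactions following
#'   Michaelis-Menten kinetics (the rest are mass action).
#' @param seed integer seed; identical seeds give identical networks.
#' @return a [MetabolicNetwork-class] whose undirected projection is
#'   connected with exactly \code{nNodes - 1 + nExtraEdges} internal edges.
#' @examples
#' net <- generateNetwork(10, nExtraEdges = 2, mmFraction = 0.5, seed = 7)
#' net
#' @export
generateNetwork <- function(nNodes, nExtraEdges = 0L, mmFraction = 0.5,
                            seed = 1L) {
    stopifnot(nNodes >= 3, mmFraction >= 0, mmFraction <= 1)
    maxExtra <- nNodes * (nNodes - 1) / 2 - (nNodes - 1)
    if (nExtraEdges > maxExtra)
        stop("nExtraEdges exceeds the complete-graph budget (max ",
             maxExtra, ")", call. = FALSE)
    withSeed(seed, {
        nodes <- sprintf("M%02d", seq_len(nNodes))
        ## random spanning tree rooted at node 1: each node attaches to a
        ## uniformly chosen earlier node (random recursive tree)
        parent <- integer(nNodes)
        for (i in 2:nNodes)
            parent[i] <- if (i == 2) 1L else sample.int(i - 1L, 1L)
        depth <- integer(nNodes)
        for (i in 2:nNodes) depth[i] <- depth[parent[i]] + 1L
        edges <- cbind(parent[-1], 2:nNodes)   # oriented away from root
        ## extra edges among non-adjacent pairs, oriented shallow -> deep
        if (nExtraEdges > 0) {
            all <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
            used <- paste(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2]))
            free <- all[!paste(all[, 1], all[, 2]) %in% used, , drop = FALSE]
            pick <- free[sample.int(nrow(free), nExtraEdges), , drop = FALSE]
            ord <- depth[pick[, 1]] > depth[pick[, 2]]
            pick[ord, ] <- pick[ord, c(2, 1)]
            edges <- rbind(edges, pick)
        }
        nInternal <- nrow(edges)
        laws <- ifelse(stats::runif(nInternal) < mmFraction,
                       "michaelis_menten", "mass_action")
        rxns <- vector("list", nInternal)
        for (e in seq_len(nInternal)) {
            s <- nodes[edges[e, 1]]; p <- nodes[edges[e, 2]]
            rxns[[e]] <- if (laws[e] == "michaelis_menten")
                reaction(sprintf("v%02d", e), s, p, "michaelis_menten",
                         c(Vmax = exp(stats::runif(1, log(0.1), log(10))),
                           Km = exp(stats::runif(1, log(0.5), log(5)))))
            else
                reaction(sprintf("v%02d", e), s, p, "mass_action",
                         c(k = exp(stats::runif(1, log(0.1), log(10)))))
        }
        ## efflux at every terminal (degree-1) node and at every directed
        ## dead end (no onward reaction): without removal those nodes
        ## accumulate mass indefinitely and no steady state exists
        deg <- tabulate(c(edges[, 1], edges[, 2]), nNodes)
        outDeg <- tabulate(edges[, 1], nNodes)
        terminals <- which(deg == 1L | outDeg == 0L)
        for (t in terminals)
            rxns[[length(rxns) + 1L]] <- reaction(
                sprintf("out_%s", nodes[t]), nodes[t], law = "mass_action",
                params = c(k = exp(stats::runif(1, log(0.05), log(0.5)))),
                sink = TRUE)
        influx <- stats::setNames(exp(stats::runif(1, log(0.01), log(0.05))),
                                  nodes[1])
        metabolicNetwork(nodes, rxns, influx = influx)
    })
}

#' Reference adjacency matrix of a network
#'
#' Builds the binary ground-truth interaction matrix: metabolites \eqn{x}
#' and \eqn{y} are connected iff some non-efflux reaction involves both.
#' All participants of a reaction are mutually connected, so a
#' two-substrate reaction \eqn{A + B \to C} induces edges A-C, B-C and A-B.
#' Removal (sink) reactions contribute no edges.
#'
#' @param net a [MetabolicNetwork-class].
#' @return an [AdjacencyMatrix-class] in the network's node order.
#' @examples
#' networkToAdjacency(generateNetwork(5, seed = 1))
#' @export
networkToAdjacency <- function(net) {
    stopifnot(is(net, "MetabolicNetwork"))
    n <- length(net@nodes)
    m <- matrix(0, n, n, dimnames = list(net@nodes, net@nodes))
    for (r in net@reactions) {
        if (isTRUE(r@sink)) next
        members <- match(unique(c(r@substrates, r@products)), net@nodes)
        for (i in members) for (j in members) if (i != j) m[i, j] <- 1
    }
    new("AdjacencyMatrix", adj = m)
}

#' Apply a condition shift (Vmax/Km multipliers) to a network
#'
#' Produces a modified copy of a network in which selected Michaelis-Menten
#' reactions have their \code{Vmax} and \code{Km} multiplied — e.g. an aged
#' (sarcopenia-like) condition obtained by amplifying \code{Vmax} of the two
#' 15-PGDH-catalyzed degradation reactions 1000-fold and \code{Km} 2.5-fold.
#'
#' @param net a [MetabolicNetwork-class].
#' @param shift a data.frame with columns \code{reaction} (id),
#'   \code{vmaxMult}, \code{kmMult}; multipliers strictly positive.
#' @return a new [MetabolicNetwork-class]; the input is not modified.
#' @examples
#' net <- generateNetwork(6, mmFraction = 1, seed = 2)
#' aged <- applyCondition(net,
#'   data.frame(reaction = "v01", vmaxMult = 1000, kmMult = 2.5))
#' @export
applyCondition <- function(net, shift) {
    stopifnot(is(net, "MetabolicNetwork"),
              all(c("reaction", "vmaxMult", "kmMult") %in% names(shift)))
    if (any(shift$vmaxMult <= 0) || any(shift$kmMult <= 0))
        stop("condition-shift multipliers must be strictly positive",
             call. = FALSE)
    ids <- vapply(net@reactions, function(r) r@id, character(1))
    rxns <- net@reactions
    for (i in seq_len(nrow(shift))) {
        j <- match(shift$reaction[i], ids)
        if (is.na(j))
            stop("unknown reaction id: ", shift$reaction[i], call. = FALSE)
        r <- rxns[[j]]
        if (r@law != "michaelis_menten")
            stop("condition shifts target Michaelis-Menten reactions; '",
                 r@id, "' is mass action", call. = FALSE)
        r@params["Vmax"] <- r@params["Vmax"] * shift$vmaxMult[i]
        r@params["Km"] <- r@params["Km"] * shift$kmMult[i]
        rxns[[j]] <- r
    }
    initialize(net, reactions = rxns)
}
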