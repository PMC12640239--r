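# Experiment orchestration: the (method x sample size x repetition)
# evaluation grid and its summary.

#' Run the inference evaluation grid
#'
#' For every combination of method, sample size and repetition: draws
#' \code{n} rows without replacement from the sample pool (a fresh
#' deterministic seed per cell), infers an association matrix, evaluates
#' the pairwise metrics at the F1-optimal threshold and the four
#' centrality MAEs against the reference. Methods whose minimum sample
#' size (see [methodMinSamples()]) exceeds \code{n} are skipped with a
#' message, as are cells that fail (recorded, never aborting the grid).
#'
#' When \code{outDir} is given, results and a manifest are written as CSV
#' and completed cells are skipped on re-runs, making the grid resumable;
#' per-cell seeds are derived by hashing (method, n, repetition) with the
#' master seed, so outputs are independent of execution order.
#'
#' @param samples a [SampleMatrix-class]: the sample pool.
#' @param ref reference [AdjacencyMatrix-class].
#' @param methods character vector of method identifiers
#'   (see [inferAssociation()]).
#' @param sampleSizes integer vector (default \code{c(5, 10, 20, 50, 100,
#'   200)}).
#' @param repetitions repetitions per cell (default 100).
#' @param seed master seed.
#' @param outDir optional output directory for \code{results.csv} and
#'   \code{manifest.csv}.
#' @param ... forwarded to [inferAssociation()].
#' @return tidy data.frame with columns \code{method}, \code{n},
#'   \code{repetition}, \code{seed}, \code{metric}, \code{value},
#'   \code{threshold}.
#' @export
runGrid <- function(samples, ref, methods,
                    sampleSizes = c(5, 10, 20, 50, 100, 200),
                    repetitions = 100L, seed = 1L, outDir = NULL, ...) {
    x <- as.matrix(samples)
    pool <- nrow(x)
    if (max(sampleSizes) > pool)
        stop("sample pool smaller than the largest sample size",
             call. = FALSE)
    manifestPath <- resultsPath <- NULL
    done <- character()
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        manifestPath <- file.path(outDir, "manifest.csv")
        resultsPath <- file.path(outDir, "results.csv")
        if (file.exists(manifestPath))
            done <- utils::read.csv(manifestPath)$cell
    }
    rows <- list()
    failures <- character()
    for (method in methods) for (n in sampleSizes) {
        minN <- methodMinSamples(method)
        if (n < minN) {
            message("skipping ", method, " at n=", n,
                    " (needs at least ", minN, " samples)")
            next
        }
        for (rep in seq_len(repetitions)) {
            cell <- paste(method, n, rep, sep = "|")
            if (cell %in% done) next
            cellSeed <- hashSeed(method, n, rep, seed)
            res <- tryCatch({
                idx <- withSeed(cellSeed, sample.int(pool, n))
                sub <- new("SampleMatrix", values = x[idx, , drop = FALSE])
                assoc <- suppressMessages(
                    inferAssociation(sub, method, seed = cellSeed, ...))
                rbind(pairwiseMetrics(assoc, ref),
                      cbind(centralityMetrics(
                          optimalThreshold(assoc, ref, "F1")$network, ref),
                          threshold = NA_real_))
            }, error = function(e) conditionMessage(e))
            if (is.character(res)) {
                failures <- c(failures, paste0(cell, ": ", res))
                next
            }
            out <- data.frame(method = method, n = n, repetition = rep,
                              seed = cellSeed, res)
            rows[[cell]] <- out
            if (!is.null(outDir)) {
                utils::write.table(out, resultsPath, sep = ",",
                    row.names = FALSE, col.names = !file.exists(resultsPath),
                    append = file.exists(resultsPath))
                utils::write.table(data.frame(cell = cell), manifestPath,
                    sep = ",", row.names = FALSE,
                    col.names = !file.exists(manifestPath),
                    append = file.exists(manifestPath))
            }
        }
    }
    if (length(failures))
        message(length(failures), " cell(s) failed:\n  ",
                paste(failures, collapse = "\n  "))
    res <- if (length(rows)) do.call(rbind, rows)
           else if (!is.null(resultsPath) && file.exists(resultsPath))
               utils::read.csv(resultsPath)
           else data.frame()
    rownames(res) <- NULL
    attr(res, "failures") <- failures
    res
}

#' Summarize grid results with mean and 95\% percentile CI
#'
#' @param results tidy results from [runGrid()] (needs at least 2
#'   repetitions per cell for nondegenerate CIs).
#' @return data.frame with one row per (method, n, metric): \code{mean},
#'   \code{ciLow}, \code{ciHigh} (2.5th/97.5th percentiles over
#'   repetitions). Cells absent from the input are absent from the output.
#' @export
summarizeGrid <- function(results) {
    grp <- split(results,
                 list(results$method, results$n, results$metric),
                 drop = TRUE)
    out <- do.call(rbind, lapply(grp, function(d) {
        ci <- ci95(d$value)
        data.frame(method = d$method[1], n = d$n[1], metric = d$metric[1],
                   mean = mean(d$value), ciLow = ci[1], ciHigh = ci[2])
    }))
    rownames(out) <- NULL
    out[order(out$method, out$n, out$metric), ]
}
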