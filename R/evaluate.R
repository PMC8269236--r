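## Accuracy metrics, small-database-effect quantification, and community
## statistics.

#' Score read/query assignments against ground truth
#'
#' Exact confusion bookkeeping. A true positive is a target-derived query
#' assigned to its true family. A false positive is any query that receives
#' status \code{assigned} although it is decoy-derived, unrelated, or
#' target-derived but assigned to the wrong family. A false negative is a
#' target-derived query not assigned to its true family (absorbed,
#' unassigned, or misassigned). Because published false-positive percentages
#' mix denominators, the per-class table states each rate's denominator
#' explicitly.
#'
#' @param assignments data.frame from \code{\link{assignReads}}.
#' @param truth data.frame with columns \code{query_id}, \code{class}
#'   (\code{target}/\code{decoy}/\code{unrelated}), \code{true_family};
#'   must cover all assignment query ids.
#' @return a \code{\linkS4class{ConfusionSummary}}.
#' @export
scoreAssignments <- function(assignments, truth) {
    unknown <- setdiff(assignments$read_id, truth$query_id)
    if (length(unknown))
        stop("assignments contain query ids missing from truth: ",
             paste(head(unknown, 5L), collapse = ", "))
    i <- match(assignments$read_id, truth$query_id)
    cls <- truth$class[i]
    trueFam <- truth$true_family[i]
    isAssigned <- assignments$status == "assigned"
    correct <- isAssigned & cls == "target" &
        assignments$family_id == trueFam
    correct[is.na(correct)] <- FALSE
    tp <- sum(correct)
    fp <- sum(isAssigned & !correct)
    fn <- sum(cls == "target" & !correct)
    perClass <- do.call(rbind, lapply(c("target", "decoy", "unrelated"),
        function(k) {
            sel <- cls == k
            n <- sum(sel)
            nAssigned <- sum(isAssigned & sel)
            nCorrect <- if (k == "target") sum(correct & sel) else 0L
            rate <- if (k == "target") {
                if (n) (n - nCorrect) / n else 0   # false-negative rate
            } else {
                if (n) nAssigned / n else 0        # false-positive rate
            }
            data.frame(class = k, n = n, n_assigned = nAssigned,
                       n_correct = nCorrect,
                       rate = rate,
                       rate_type = if (k == "target") "FN / class size"
                                   else "FP / class size",
                       stringsAsFactors = FALSE)
        }))
    new("ConfusionSummary",
        counts = list(tp = tp, fp = fp, fn = fn), perClass = perClass)
}

#' Quantify the small-database effect
#'
#' Reads are assigned under the core (decoy-free) database; the core-assigned
#' reads are then re-evaluated under the full database, and the fraction
#' absorbed by homolog decoys is reported. That fraction is the share of
#' apparent target hits that a database without homologs would have called
#' falsely. Both denominators are available: the overall core-assigned count
#' and a per-family breakdown.
#'
#' @param reads named character vector of reads.
#' @param coreDb decoy-free \code{\linkS4class{ReferenceDatabase}}; an error
#'   is raised if it contains decoys.
#' @param fullDb the homolog-inclusive database.
#' @param config a \code{\link{searchConfig}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return a \code{\linkS4class{SmallDbReport}}.
#' @export
smallDbEffect <- function(reads, coreDb, fullDb, config = searchConfig(),
                          scheme = scoringScheme()) {
    stopifnot(is(coreDb, "ReferenceDatabase"),
              is(fullDb, "ReferenceDatabase"))
    if (any(coreDb@seqInfo$kind == "decoy"))
        stop("coreDb must not contain decoy records")
    core <- assignReads(reads, coreDb, config, scheme)
    coreAssigned <- core[core$status == "assigned", , drop = FALSE]
    nCore <- nrow(coreAssigned)
    if (nCore == 0L)
        return(new("SmallDbReport", nCoreAssigned = 0, nAbsorbed = 0,
                   fraction = 0,
                   perFamily = data.frame(family_id = character(),
                                          n_core_assigned = integer(),
                                          n_absorbed = integer(),
                                          fraction = numeric())))
    full <- assignReads(reads[names(reads) %in% coreAssigned$read_id],
                        fullDb, config, scheme)
    absorbed <- full$read_id[full$status == "homolog_absorbed"]
    nAbs <- length(absorbed)
    fams <- coreAssigned$family_id
    perFam <- do.call(rbind, lapply(unique(fams), function(f) {
        ids <- coreAssigned$read_id[fams == f]
        na <- sum(ids %in% absorbed)
        data.frame(family_id = f, n_core_assigned = length(ids),
                   n_absorbed = na, fraction = na / length(ids),
                   stringsAsFactors = FALSE)
    }))
    rownames(perFam) <- NULL
    new("SmallDbReport", nCoreAssigned = nCore, nAbsorbed = nAbs,
        fraction = nAbs / nCore, perFamily = perFam)
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' \eqn{1 - 2 \sum_i \min(p_i, q_i) / (\sum_i p_i + \sum_i q_i)} over the
#' union of the two key sets (absent keys count as zero).
#'
#' @param p,q non-negative named numeric vectors (e.g. family or taxon
#'   abundances). Unnamed vectors of equal length are matched positionally.
#' @return dissimilarity in [0, 1].
#' @examples
#' brayCurtis(c(a = 3, b = 1), c(a = 1, b = 3))  # 0.5
#' @export
brayCurtis <- function(p, q) {
    if (any(p < 0) || any(q < 0)) stop("abundances must be non-negative")
    if (!is.null(names(p)) || !is.null(names(q))) {
        if (is.null(names(p)) || is.null(names(q)))
            stop("both vectors must be named (or both unnamed)")
        keys <- union(names(p), names(q))
        pp <- setNames(numeric(length(keys)), keys)
        qq <- pp
        pp[names(p)] <- p
        qq[names(q)] <- q
        p <- pp; q <- qq
    } else if (length(p) != length(q)) {
        stop("unnamed vectors must have equal length")
    }
    tot <- sum(p) + sum(q)
    if (tot == 0) stop("Bray-Curtis is undefined for two all-zero profiles")
    1 - 2 * sum(pmin(p, q)) / tot
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-D^2/2}, eigendecomposes, and scales eigenvectors by
#' the square root of their eigenvalues. Negative eigenvalues are reported
#' and their axes dropped; no Lingoes/Cailliez correction is applied.
#'
#' @param d symmetric, zero-diagonal, non-negative distance matrix (or
#'   \code{dist}).
#' @param k number of axes requested (capped at the number of positive
#'   eigenvalues).
#' @return an \code{\linkS4class{Ordination}}.
#' @export
pcoaOrdination <- function(d, k = 2L) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("d must be a square distance matrix")
    if (any(d < 0)) stop("distances must be non-negative")
    if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
    if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
    if (k < 1L) stop("k must be >= 1")
    n <- nrow(d)
    ## axis count is reconciled against the positive spectrum below, so the
    ## "only r of the first k eigenvalues are > 0" warning is redundant here
    fit <- suppressWarnings(cmdscale(d, k = min(k, n - 1L), eig = TRUE))
    eig <- fit$eig
    pos <- sum(eig > 1e-12)
    kUse <- min(k, pos)
    pts <- fit$points[, seq_len(kUse), drop = FALSE]
    colnames(pts) <- paste0("Axis", seq_len(kUse))
    if (!is.null(rownames(d))) rownames(pts) <- rownames(d)
    varExp <- if (pos) eig[seq_len(kUse)] / sum(eig[eig > 0]) else numeric()
    new("Ordination", points = pts, eigenvalues = eig,
        varExplained = varExp, nNegative = sum(eig < -1e-12))
}

#' Extract an abundance vector from a profile
#'
#' Convenience accessor turning a \code{\linkS4class{FunctionalProfile}} or
#' a taxonomic profile data.frame into the named abundance vector consumed by
#' \code{\link{brayCurtis}}.
#'
#' @param x a \code{FunctionalProfile} or taxonomic profile data.frame.
#' @return named numeric vector of relative abundances.
#' @export
abundanceVector <- function(x) {
    if (is(x, "FunctionalProfile"))
        return(setNames(x@families$rel_abundance, x@families$family_id))
    if (is.data.frame(x) && all(c("taxon", "rel_abundance") %in% names(x)))
        return(setNames(x$rel_abundance, x$taxon))
    stop("x must be a FunctionalProfile or a taxonomic profile data.frame")
}
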