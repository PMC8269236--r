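## Homolog-aware read assignment and functional / taxonomic profiling.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

.detectAlphabet <- function(x) {
    ch <- unique(strsplit(paste(toupper(x), collapse = ""), "")[[1]])
    if (all(ch %in% c("A", "C", "G", "T", "N"))) "nucleotide" else "protein"
}

#' Assign reads against a reference database
#'
#' Best-hit search of every read over the database's targets and decoys
#' together. A read whose best passing hit is a target is \code{assigned} to
#' that family; one whose best hit is a homolog decoy is
#' \code{homolog_absorbed} (the decoy exists precisely to pull such reads
#' away from target families); a read with no passing hit is
#' \code{unassigned}. Nucleotide reads (auto-detected by alphabet, or forced
#' via \code{alphabet}) are translated in six frames and the best frame's
#' best hit is used.
#'
#' @param reads named character vector or \code{AAStringSet} /
#'   \code{DNAStringSet} of reads; may be empty.
#' @param db a \code{\linkS4class{ReferenceDatabase}} (tier \code{full}, or
#'   \code{core}/\code{seed} explicitly for evaluation).
#' @param config a \code{\link{searchConfig}}; mode \code{"local"} fits
#'   fragment reads, \code{"global"} full-length query proteins. Nucleotide
#'   input switches to translated local search.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @param alphabet \code{"auto"} (default), \code{"protein"}, or
#'   \code{"nucleotide"}.
#' @return data.frame with one row per read: \code{read_id}, \code{status}
#'   (\code{assigned}/\code{homolog_absorbed}/\code{unassigned}),
#'   \code{family_id} (NA unless assigned), \code{ref_id}, \code{score},
#'   \code{identity}, \code{frame}.
#' @export
assignReads <- function(reads, db, config = searchConfig(),
                        scheme = scoringScheme(), alphabet = "auto") {
    stopifnot(is(db, "ReferenceDatabase"))
    if (is(reads, "AAStringSet")) {
        alphabet <- "protein"; reads <- as.character(reads)
    } else if (is(reads, "DNAStringSet")) {
        alphabet <- "nucleotide"; reads <- as.character(reads)
    }
    empty <- data.frame(read_id = character(), status = character(),
                        family_id = character(), ref_id = character(),
                        score = numeric(), identity = numeric(),
                        frame = character(), stringsAsFactors = FALSE)
    if (!length(reads)) return(empty)
    if (is.null(names(reads)) || anyDuplicated(names(reads)))
        stop("reads must have unique names")
    if (alphabet == "auto") alphabet <- .detectAlphabet(reads)
    if (alphabet == "nucleotide" && config$mode != "translated_local")
        config$mode <- "translated_local"
    refs <- db@sequences
    if (!length(refs)) stop("reference database is empty")
    info <- db@seqInfo

    if (config$mode == "translated_local") {
        ## expand reads to their six frames, score all frames at once,
        ## then pick the best frame per read
        frames <- lapply(reads, translateSixFrames)
        frameTab <- do.call(rbind, lapply(seq_along(reads), function(i) {
            f <- frames[[i]]
            data.frame(read = names(reads)[i], frame = names(f),
                       aa = unname(f), stringsAsFactors = FALSE)
        }))
        frameTab <- frameTab[nzchar(frameTab$aa), , drop = FALSE]
        type <- "local"
        queries <- frameTab$aa
        qOwner <- frameTab$read
        qFrame <- frameTab$frame
    } else {
        type <- config$mode
        queries <- unname(reads)
        qOwner <- names(reads)
        qFrame <- rep(NA_character_, length(reads))
    }

    S <- if (length(queries))
        .scoreMatrix(AAStringSet(queries), refs, type, scheme)
    else matrix(numeric(), 0L, length(refs))

    frameOrder <- c("+1", "+2", "+3", "-1", "-2", "-3")
    out <- vector("list", length(reads))
    for (i in seq_along(reads)) {
        rid <- names(reads)[i]
        rows <- which(qOwner == rid)
        best <- NULL
        for (r in rows) {
            h <- .bestFromScores(queries[r], refs, S[r, ], type, config,
                                 scheme)
            if (is.null(h)) next
            h$frame <- qFrame[r]
            better <- is.null(best) || h$score > best$score ||
                (h$score == best$score && h$identity > best$identity) ||
                (h$score == best$score && h$identity == best$identity &&
                 h$ref_id < best$ref_id) ||
                (h$score == best$score && h$identity == best$identity &&
                 h$ref_id == best$ref_id &&
                 match(h$frame, frameOrder) < match(best$frame, frameOrder))
            if (better) best <- h
        }
        if (is.null(best)) {
            out[[i]] <- data.frame(read_id = rid, status = "unassigned",
                                   family_id = NA_character_,
                                   ref_id = NA_character_, score = NA_real_,
                                   identity = NA_real_,
                                   frame = NA_character_,
                                   stringsAsFactors = FALSE)
        } else {
            j <- match(best$ref_id, info$seq_id)
            isTarget <- info$kind[j] == "target"
            out[[i]] <- data.frame(
                read_id = rid,
                status = if (isTarget) "assigned" else "homolog_absorbed",
                family_id = if (isTarget) info$label[j] else NA_character_,
                ref_id = best$ref_id, score = best$score,
                identity = best$identity, frame = best$frame,
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Build a functional profile from read assignments
#'
#' Counts assigned reads per family; relative abundance is the family count
#' divided by the number of assigned reads (not total reads, not gene
#' length). Pathway rollups are emitted in both share modes (replicate and
#' fractional) via \code{\link{rollupCountsByPathway}}.
#'
#' @param assignments data.frame from \code{\link{assignReads}} (one sample).
#' @param registry a \code{\linkS4class{FamilyRegistry}} supplying pathway
#'   membership; families absent from the registry are rejected.
#' @param sampleId sample identifier (default \code{"sample1"}).
#' @return a \code{\linkS4class{FunctionalProfile}}.
#' @export
functionalProfile <- function(assignments, registry, sampleId = "sample1") {
    stopifnot(is(registry, "FamilyRegistry"))
    nReads <- nrow(assignments)
    nAssigned <- sum(assignments$status == "assigned")
    nAbsorbed <- sum(assignments$status == "homolog_absorbed")
    nUnassigned <- sum(assignments$status == "unassigned")
    fams <- assignments$family_id[assignments$status == "assigned"]
    unknown <- setdiff(unique(fams), registry@families$family_id)
    if (length(unknown))
        stop("assigned families not in registry: ",
             paste(unknown, collapse = ", "))
    counts <- table(fams)
    famDf <- data.frame(family_id = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
    zero <- nAssigned == 0L
    famDf$rel_abundance <- if (zero) numeric(nrow(famDf))
                           else famDf$count / nAssigned
    perFam <- setNames(famDf$count, famDf$family_id)
    rep_ <- rollupCountsByPathway(registry, perFam, "replicate")
    fra_ <- rollupCountsByPathway(registry, perFam, "fractional")
    pwDf <- data.frame(pathway_id = names(rep_),
                       count_replicate = as.numeric(rep_),
                       count_fractional = as.numeric(fra_),
                       rel_replicate = if (zero) numeric(length(rep_))
                                       else as.numeric(rep_) / nAssigned,
                       rel_fractional = if (zero) numeric(length(fra_))
                                        else as.numeric(fra_) / nAssigned,
                       stringsAsFactors = FALSE)
    new("FunctionalProfile", sampleId = sampleId, families = famDf,
        pathways = pwDf,
        totals = list(n_reads = nReads, n_assigned = nAssigned,
                      n_absorbed = nAbsorbed, n_unassigned = nUnassigned),
        zeroAssigned = zero)
}

#' Extract the assigned reads
#'
#' Returns exactly the reads with status \code{assigned}, with their original
#' residues, preserving input order (e.g. for downstream taxonomic
#' classification).
#'
#' @param assignments data.frame from \code{\link{assignReads}}.
#' @param reads the read set that was assigned (named character vector or
#'   \code{XStringSet}).
#' @return named character vector of assigned reads.
#' @export
extractAssignedReads <- function(assignments, reads) {
    if (is(reads, "XStringSet")) reads <- as.character(reads)
    ids <- assignments$read_id[assignments$status == "assigned"]
    missing <- setdiff(ids, names(reads))
    if (length(missing))
        stop("assigned read ids missing from reads: ",
             paste(head(missing, 5L), collapse = ", "))
    reads[names(reads) %in% ids]
}

#' Build a taxonomic profile from read assignments
#'
#' Default classifier \code{"besthit_transfer"} transfers the lineage of each
#' assigned read's best-hit reference. References lacking a lineage at the
#' requested rank count as unclassified. An external classification (read id
#' to taxon) can be supplied instead.
#'
#' @param assignments data.frame from \code{\link{assignReads}}.
#' @param db the \code{\linkS4class{ReferenceDatabase}} searched against.
#' @param rank one of domain, phylum, class, order, family, genus, species.
#' @param classifier \code{"besthit_transfer"} (default) or
#'   \code{"external"}.
#' @param externalTaxa named character vector (read id to taxon) when
#'   \code{classifier = "external"}.
#' @return data.frame (\code{taxon}, \code{count}, \code{rel_abundance})
#'   with attributes \code{rank}, \code{classifier}, \code{n_unclassified};
#'   abundances sum to 1 over classified reads.
#' @export
taxonomicProfile <- function(assignments, db, rank = "phylum",
                             classifier = c("besthit_transfer", "external"),
                             externalTaxa = NULL) {
    classifier <- match.arg(classifier)
    if (!rank %in% .RANKS)
        stop("unknown rank '", rank, "'; use one of: ",
             paste(.RANKS, collapse = ", "))
    assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
    if (classifier == "besthit_transfer") {
        stopifnot(is(db, "ReferenceDatabase"))
        i <- match(assigned$ref_id, db@seqInfo$seq_id)
        lineage <- db@seqInfo$taxonomy[i]
        level <- match(rank, .RANKS)
        taxa <- vapply(lineage, function(x) {
            if (is.na(x)) return(NA_character_)
            parts <- strsplit(x, ";", fixed = TRUE)[[1]]
            if (length(parts) < level || !nzchar(parts[level]))
                NA_character_ else parts[level]
        }, character(1), USE.NAMES = FALSE)
    } else {
        if (is.null(externalTaxa))
            stop("externalTaxa required for external classifier")
        taxa <- unname(externalTaxa[assigned$read_id])
    }
    classified <- taxa[!is.na(taxa)]
    if (length(classified)) {
        counts <- table(classified)
        out <- data.frame(taxon = names(counts),
                          count = as.integer(counts),
                          stringsAsFactors = FALSE)
        out$rel_abundance <- out$count / sum(out$count)
        out <- out[order(-out$count, out$taxon), , drop = FALSE]
        rownames(out) <- NULL
    } else {
        out <- data.frame(taxon = character(), count = integer(),
                          rel_abundance = numeric(),
                          stringsAsFactors = FALSE)
    }
    attr(out, "rank") <- rank
    attr(out, "classifier") <- classifier
    attr(out, "n_unclassified") <- sum(is.na(taxa))
    out
}
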