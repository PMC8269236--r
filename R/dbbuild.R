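## Seed -> core -> full database construction: candidate recruitment at a
## global identity cutoff, homolog-group classification (merge / decoy /
## drop), genome-protein routing, and exact deduplication.

#' Create a database build configuration
#'
#' @param minGlobalIdentity global identity cutoff for recruitment and
#'   homolog-group evidence (default 0.30).
#' @param decoyMajorityFraction a homolog group whose member fraction hitting
#'   one target family reaches this value is merged into that family
#'   (default 0.50, the automated surrogate for semimanual orthology-group
#'   inspection; every decision is logged for review).
#' @param minMembersHitting a group not merged becomes a homolog-decoy group
#'   when at least this many members hit any target (default 1); otherwise it
#'   is dropped.
#' @return a list of class \code{"BuildConfig"}.
#' @export
buildConfig <- function(minGlobalIdentity = 0.30,
                        decoyMajorityFraction = 0.50,
                        minMembersHitting = 1L) {
    if (minGlobalIdentity < 0 || minGlobalIdentity > 1 ||
        decoyMajorityFraction < 0 || decoyMajorityFraction > 1)
        stop("fractions must lie in [0, 1]")
    structure(list(minGlobalIdentity = minGlobalIdentity,
                   decoyMajorityFraction = decoyMajorityFraction,
                   minMembersHitting = as.integer(minMembersHitting)),
              class = "BuildConfig")
}

.asAASet <- function(x, what = "sequences") {
    if (is(x, "AAStringSet")) return(x)
    if (is.character(x)) return(AAStringSet(x))
    stop(what, " must be an AAStringSet or named character vector")
}

#' Build the seed tier from curated sequences
#'
#' Stores manually curated reference sequences per declared family. Every
#' record must name a registry family; duplicate sequence ids are rejected.
#'
#' @param sequences named \code{AAStringSet} (or named character vector) of
#'   curated proteins.
#' @param families character vector, parallel to \code{sequences}, of family
#'   ids.
#' @param registry a \code{\linkS4class{FamilyRegistry}}.
#' @param taxonomy optional character vector of semicolon-separated lineages.
#' @return a \code{\linkS4class{ReferenceDatabase}} with tier \code{"seed"}.
#' @export
buildSeed <- function(sequences, families, registry, taxonomy = NULL) {
    stopifnot(is(registry, "FamilyRegistry"))
    seqs <- .asAASet(sequences)
    if (is.null(names(seqs)) || !all(nzchar(names(seqs))))
        stop("curated sequences must be named by seq_id")
    if (anyDuplicated(names(seqs)))
        stop("duplicate seq_id: ",
             paste(unique(names(seqs)[duplicated(names(seqs))]),
                   collapse = ", "))
    if (length(families) != length(seqs))
        stop("families must be parallel to sequences")
    unknown <- setdiff(families, registry@families$family_id)
    if (length(unknown))
        stop("unknown family id(s): ", paste(unknown, collapse = ", "))
    info <- data.frame(seq_id = names(seqs), kind = "target",
                       label = families,
                       taxonomy = if (is.null(taxonomy)) NA_character_
                                  else taxonomy,
                       stringsAsFactors = FALSE)
    .newRefDb(seqs, info, "seed")
}

#' Recruit candidate sequences into the core tier
#'
#' Each candidate is globally aligned against the pooled seed sequences of
#' its nominal family plus all families declared homologous to it. It is
#' recruited to the best-hit seed's family when the best identity reaches the
#' global cutoff. When the top score is tied across seeds of several
#' families, the candidate goes to the family holding the majority of the
#' tied seeds (majority rule); a remaining tie breaks to the
#' lexicographically smallest family id. Candidates below the cutoff are
#' rejected with a reason.
#'
#' @param candidates named \code{AAStringSet} (or named character vector).
#' @param nominalFamilies character vector, parallel to \code{candidates}:
#'   the family each candidate was retrieved for.
#' @param seedDb the seed-tier \code{\linkS4class{ReferenceDatabase}}.
#' @param registry a \code{\linkS4class{FamilyRegistry}}.
#' @param config a \code{\link{buildConfig}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return list with \code{db} (core-tier database containing all seed
#'   records plus the recruits) and \code{report} (one row per candidate:
#'   decision, assigned family, best seed, score, identity, reason).
#' @export
recruitCore <- function(candidates, nominalFamilies, seedDb, registry,
                        config = buildConfig(), scheme = scoringScheme()) {
    stopifnot(is(seedDb, "ReferenceDatabase"), is(registry, "FamilyRegistry"))
    if (!length(seedDb@sequences)) stop("seed database is empty")
    cand <- .asAASet(candidates, "candidates")
    if (is.null(names(cand)) || anyDuplicated(names(cand)))
        stop("candidates must have unique names")
    if (length(nominalFamilies) != length(cand))
        stop("nominalFamilies must be parallel to candidates")
    unknown <- setdiff(nominalFamilies, registry@families$family_id)
    if (length(unknown))
        stop("candidates name unknown families: ",
             paste(unknown, collapse = ", "))
    dup <- intersect(names(cand), seedDb@seqInfo$seq_id)
    if (length(dup))
        stop("candidate ids collide with seed ids: ",
             paste(head(dup, 5L), collapse = ", "))

    info <- seedDb@seqInfo
    report <- vector("list", length(cand))
    recruited <- logical(length(cand))
    assigned <- character(length(cand))
    for (i in seq_along(cand)) {
        fams <- unique(c(nominalFamilies[i],
                         homologFamilies(registry, nominalFamilies[i])))
        pool <- which(info$label %in% fams)
        q <- as.character(cand[[i]])
        row <- list(candidate_id = names(cand)[i],
                    nominal_family = nominalFamilies[i],
                    decision = "rejected", family_id = NA_character_,
                    best_seed = NA_character_, score = NA_real_,
                    identity = NA_real_, reason = NA_character_)
        if (!length(pool)) {
            row$reason <- "no seed sequences for nominal/homolog families"
        } else {
            refs <- seedDb@sequences[pool]
            sc <- .scoreMatrix(AAStringSet(q), refs, "global", scheme)[1L, ]
            top <- max(sc)
            tied <- which(sc == top)
            stats <- lapply(tied, function(j)
                .pairIdentity(q, as.character(refs[[j]]), "global", scheme))
            ident <- vapply(stats, `[[`, numeric(1), "identity")
            best <- max(ident)
            if (best >= config$minGlobalIdentity) {
                tiedFams <- info$label[pool][tied]
                tab <- table(tiedFams)
                winners <- names(tab)[tab == max(tab)]
                famWin <- sort(winners)[1L]
                inFam <- tied[tiedFams == famWin]
                identFam <- ident[tiedFams == famWin]
                o <- order(-identFam, names(refs)[inFam])[1L]
                row$decision <- "recruited"
                row$family_id <- famWin
                row$best_seed <- names(refs)[inFam][o]
                row$score <- top
                row$identity <- identFam[o]
                recruited[i] <- TRUE
                assigned[i] <- famWin
            } else {
                o <- order(-ident)[1L]
                row$best_seed <- names(refs)[tied][o]
                row$score <- top
                row$identity <- best
                row$reason <- sprintf("best identity %.3f below cutoff %.2f",
                                      best, config$minGlobalIdentity)
            }
        }
        report[[i]] <- row
    }
    report <- do.call(rbind, lapply(report, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    rownames(report) <- NULL

    keep <- which(recruited)
    newInfo <- data.frame(seq_id = names(cand)[keep], kind = "target",
                          label = assigned[keep],
                          source_db = "candidate",
                          taxonomy = NA_character_,
                          duplicates = NA_character_,
                          stringsAsFactors = FALSE)
    allInfo <- rbind(info, newInfo)
    allSeqs <- c(seedDb@sequences, cand[keep])
    list(db = .newRefDb(allSeqs, allInfo, "core"), report = report)
}

#' Classify orthology groups and attach homolog decoys (full tier)
#'
#' Each orthology group's members are best-hit searched against the core
#' targets. A group whose member fraction hitting one family (at the global
#' identity cutoff) reaches the majority fraction merges into that target
#' family; a group with at least \code{minMembersHitting} members hitting any
#' target becomes a homolog-decoy group; other groups are dropped. All
#' decisions and their evidence are reported for review.
#'
#' @param coreDb core-tier \code{\linkS4class{ReferenceDatabase}}.
#' @param groups data.frame with columns \code{group_id}, \code{source_db},
#'   \code{seq_id} (group membership).
#' @param groupSeqs named \code{AAStringSet} resolving the member ids.
#' @param config a \code{\link{buildConfig}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return list with \code{db} (full tier: core targets + merged members +
#'   decoy groups) and \code{report} (one row per group: decision, member
#'   count, hit counts, winning family).
#' @export
attachHomologGroups <- function(coreDb, groups, groupSeqs,
                                config = buildConfig(),
                                scheme = scoringScheme()) {
    stopifnot(is(coreDb, "ReferenceDatabase"))
    need <- c("group_id", "source_db", "seq_id")
    if (!all(need %in% names(groups)))
        stop("groups must have columns: ", paste(need, collapse = ", "))
    groupSeqs <- .asAASet(groupSeqs, "groupSeqs")
    missing <- setdiff(groups$seq_id, names(groupSeqs))
    if (length(missing))
        stop("group members without sequences: ",
             paste(head(missing, 5L), collapse = ", "))
    targets <- coreDb@sequences[coreDb@seqInfo$kind == "target"]
    tlabels <- coreDb@seqInfo$label[coreDb@seqInfo$kind == "target"]
    cfg <- searchConfig(mode = "global",
                        minIdentity = config$minGlobalIdentity)

    info <- coreDb@seqInfo
    seqs <- coreDb@sequences
    rows <- list()
    for (g in unique(groups$group_id)) {
        mem <- groups[groups$group_id == g, ]
        src <- mem$source_db[1L]
        if (!nrow(mem)) next
        if (all(!nzchar(mem$seq_id))) {
            warning("empty group ", g, " dropped")
            next
        }
        hitFam <- rep(NA_character_, nrow(mem))
        for (k in seq_len(nrow(mem))) {
            q <- as.character(groupSeqs[[mem$seq_id[k]]])
            sc <- .scoreMatrix(AAStringSet(q), targets, "global",
                               scheme)[1L, ]
            h <- .bestFromScores(q, targets, sc, "global", cfg, scheme)
            if (!is.null(h))
                hitFam[k] <- tlabels[match(h$ref_id, names(targets))]
        }
        nHit <- sum(!is.na(hitFam))
        tab <- sort(table(hitFam), decreasing = TRUE)
        topFam <- if (length(tab)) names(tab)[1L] else NA_character_
        topFrac <- if (length(tab)) tab[[1L]] / nrow(mem) else 0
        decision <-
            if (topFrac >= config$decoyMajorityFraction) "merged"
            else if (nHit >= config$minMembersHitting) "decoy"
            else "dropped"
        rows[[g]] <- data.frame(group_id = g, source_db = src,
                                n_members = nrow(mem), n_hitting = nHit,
                                top_family = topFam,
                                top_fraction = topFrac,
                                decision = decision,
                                stringsAsFactors = FALSE)
        if (decision == "dropped") next
        addInfo <- data.frame(
            seq_id = mem$seq_id,
            kind = if (decision == "merged") "target" else "decoy",
            label = if (decision == "merged") topFam else g,
            source_db = src, taxonomy = NA_character_,
            duplicates = NA_character_, stringsAsFactors = FALSE)
        dup <- intersect(mem$seq_id, info$seq_id)
        if (length(dup))
            stop("group member ids collide with database ids: ",
                 paste(head(dup, 5L), collapse = ", "))
        info <- rbind(info, addInfo)
        seqs <- c(seqs, groupSeqs[mem$seq_id])
    }
    report <- if (length(rows)) do.call(rbind, rows) else
        data.frame(group_id = character(), source_db = character(),
                   n_members = integer(), n_hitting = integer(),
                   top_family = character(), top_fraction = numeric(),
                   decision = character(), stringsAsFactors = FALSE)
    rownames(report) <- NULL
    list(db = .newRefDb(seqs, info, "full"), report = report)
}

#' Route genome proteins into the full database
#'
#' Each incoming protein is best-hit searched against the full database's
#' targets and decoys together. A protein whose best hit is a target is
#' appended to that family; one whose best hit is a decoy is appended to that
#' decoy group; proteins without a passing hit are discarded. Taxonomy is
#' carried onto the stored records.
#'
#' @param fullDb full-tier \code{\linkS4class{ReferenceDatabase}}.
#' @param proteins named \code{AAStringSet} (or named character vector).
#' @param taxonomy optional character vector of lineages, parallel to
#'   \code{proteins}.
#' @param config a \code{\link{buildConfig}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return list with \code{db} (augmented full database) and \code{report}
#'   (one row per protein: routed kind/label or discarded).
#' @export
mergeRefseqLike <- function(fullDb, proteins, taxonomy = NULL,
                            config = buildConfig(),
                            scheme = scoringScheme()) {
    stopifnot(is(fullDb, "ReferenceDatabase"))
    if (fullDb@tier != "full") stop("db must be full tier")
    prot <- .asAASet(proteins, "proteins")
    if (is.null(names(prot)) || anyDuplicated(names(prot)))
        stop("proteins must have unique names")
    if (!is.null(taxonomy) && length(taxonomy) != length(prot))
        stop("taxonomy must be parallel to proteins")
    cfg <- searchConfig(mode = "global",
                        minIdentity = config$minGlobalIdentity)
    info <- fullDb@seqInfo
    seqs <- fullDb@sequences
    rows <- vector("list", length(prot))
    addIdx <- logical(length(prot))
    addKind <- character(length(prot))
    addLabel <- character(length(prot))
    for (i in seq_along(prot)) {
        q <- as.character(prot[[i]])
        sc <- .scoreMatrix(AAStringSet(q), fullDb@sequences, "global",
                           scheme)[1L, ]
        h <- .bestFromScores(q, fullDb@sequences, sc, "global", cfg, scheme)
        if (is.null(h)) {
            rows[[i]] <- data.frame(seq_id = names(prot)[i],
                                    decision = "discarded",
                                    kind = NA_character_,
                                    label = NA_character_,
                                    identity = NA_real_,
                                    stringsAsFactors = FALSE)
        } else {
            j <- match(h$ref_id, info$seq_id)
            addIdx[i] <- TRUE
            addKind[i] <- info$kind[j]
            addLabel[i] <- info$label[j]
            rows[[i]] <- data.frame(seq_id = names(prot)[i],
                                    decision = "routed",
                                    kind = info$kind[j],
                                    label = info$label[j],
                                    identity = h$identity,
                                    stringsAsFactors = FALSE)
        }
    }
    keep <- which(addIdx)
    if (length(keep)) {
        dup <- intersect(names(prot)[keep], info$seq_id)
        if (length(dup))
            stop("protein ids collide with database ids: ",
                 paste(head(dup, 5L), collapse = ", "))
        addInfo <- data.frame(
            seq_id = names(prot)[keep], kind = addKind[keep],
            label = addLabel[keep], source_db = "genome",
            taxonomy = if (is.null(taxonomy)) NA_character_
                       else taxonomy[keep],
            duplicates = NA_character_, stringsAsFactors = FALSE)
        info <- rbind(info, addInfo)
        seqs <- c(seqs, prot[keep])
    }
    routeReport <- do.call(rbind, rows)
    rownames(routeReport) <- NULL
    list(db = .newRefDb(seqs, info, "full"), report = routeReport)
}

#' Exact full-length deduplication
#'
#' Collapses records with byte-identical residue strings within the same
#' family or decoy group to the earliest-inserted representative, which
#' accumulates the duplicate ids. Identical sequences appearing in different
#' families or groups are kept (and flagged in the report) rather than
#' silently collapsed across labels. Idempotent.
#'
#' @param db a \code{\linkS4class{ReferenceDatabase}}.
#' @return list with \code{db} (deduplicated) and \code{report}
#'   (\code{representative}, \code{duplicate} rows, plus any cross-label
#'   identical pairs flagged with \code{cross_label = TRUE}).
#' @export
dedupExact <- function(db) {
    stopifnot(is(db, "ReferenceDatabase"))
    info <- db@seqInfo
    resid <- as.character(db@sequences)
    key <- paste(info$kind, info$label, resid, sep = "\r")
    first <- !duplicated(key)
    repOf <- info$seq_id[match(key, key)]  # earliest occurrence per key
    dupRows <- which(!first)
    report <- data.frame(representative = repOf[dupRows],
                         duplicate = info$seq_id[dupRows],
                         cross_label = logical(length(dupRows)),
                         stringsAsFactors = FALSE)
    ## flag identical residue strings under different labels
    xkey <- resid
    xdup <- duplicated(xkey) | duplicated(xkey, fromLast = TRUE)
    if (any(xdup)) {
        for (s in unique(xkey[xdup])) {
            idx <- which(xkey == s)
            labs <- unique(paste(info$kind[idx], info$label[idx]))
            if (length(labs) > 1L) {
                rep1 <- info$seq_id[idx[1L]]
                others <- info$seq_id[idx[-1L]]
                keep <- !(paste(info$kind[idx[-1L]], info$label[idx[-1L]]) ==
                          paste(info$kind[idx[1L]], info$label[idx[1L]]))
                if (any(keep))
                    report <- rbind(report,
                        data.frame(representative = rep1,
                                   duplicate = others[keep],
                                   cross_label = TRUE,
                                   stringsAsFactors = FALSE))
            }
        }
    }
    newInfo <- info[first, , drop = FALSE]
    if (nrow(report)) {
        within <- report[!report$cross_label, , drop = FALSE]
        if (nrow(within)) {
            agg <- tapply(within$duplicate, within$representative,
                          paste, collapse = ";")
            i <- match(names(agg), newInfo$seq_id)
            old <- newInfo$duplicates[i]
            newInfo$duplicates[i] <- ifelse(is.na(old), as.character(agg),
                                            paste(old, agg, sep = ";"))
        }
    }
    rownames(newInfo) <- NULL
    list(db = .newRefDb(db@sequences[first], newInfo, db@tier),
         report = report)
}
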