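## Protein alignment and best-hit search. The dynamic programming engine is
## Biostrings::pairwiseAlignment (BLOSUM62, affine gaps); this module fixes
## the conventions the rest of the pipeline depends on: identity denominator,
## deterministic tie-breaking, and the best-hit contract.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Create a scoring scheme
#'
#' @param matrixName substitution matrix name; any matrix shipped with
#'   Biostrings (default \code{"BLOSUM62"}).
#' @param gapOpen gap opening penalty (default 11). A gap of length k costs
#'   \code{gapOpen + k * gapExtend}.
#' @param gapExtend gap extension penalty (default 1).
#' @return a \code{\linkS4class{ScoringScheme}}.
#' @export
scoringScheme <- function(matrixName = "BLOSUM62", gapOpen = 11,
                          gapExtend = 1) {
    e <- new.env()
    utils::data(list = matrixName, package = "Biostrings", envir = e)
    m <- get(matrixName, envir = e)
    new("ScoringScheme", matrixName = matrixName, matrix = m,
        gapOpen = gapOpen, gapExtend = gapExtend)
}

#' Create a search configuration
#'
#' Captures the best-hit search contract: single best hit per query, a
#' minimum identity of 0.30 (the global-identity recruitment cutoff used
#' throughout database construction and profiling), an optional minimum
#' score, and an e-value ceiling of 1e-4 honored only by external search
#' adapters (the built-in search uses score and identity; at desk-scale
#' database sizes e-values are uninformative).
#'
#' @param mode alignment mode: \code{"global"}, \code{"local"}, or
#'   \code{"translated_local"} (six-frame translation of nucleotide queries,
#'   best frame wins).
#' @param minIdentity minimum alignment identity in [0, 1] (default 0.30).
#' @param minScore minimum alignment score. Default 0 for global mode; 50
#'   for local and translated modes, the approximate raw score at which a
#'   desk-scale protein search reaches an e-value near 1e-4 under gapped
#'   Karlin-Altschul statistics, so that short spurious local matches (whose
#'   identity over a tiny span can be high) do not pass as hits.
#' @param evalue e-value ceiling for external adapters (default 1e-4).
#' @return a list of class \code{"SearchConfig"}.
#' @export
searchConfig <- function(mode = c("local", "global", "translated_local"),
                         minIdentity = 0.30, minScore = NULL,
                         evalue = 1e-4) {
    mode <- match.arg(mode)
    if (is.null(minScore)) minScore <- if (mode == "global") 0 else 50
    if (minIdentity < 0 || minIdentity > 1)
        stop("minIdentity must lie in [0, 1]")
    if (minScore < 0) stop("minScore must be >= 0")
    if (evalue < 0) stop("evalue must be >= 0")
    structure(list(mode = mode, minIdentity = minIdentity,
                   minScore = minScore, maxHits = 1L, evalue = evalue),
              class = "SearchConfig")
}

.checkProtein <- function(x, what = "sequence") {
    if (!is.character(x) || length(x) != 1L || !nzchar(x))
        stop(what, " must be a non-empty amino-acid string")
    ch <- strsplit(toupper(x), "")[[1]]
    bad <- which(!ch %in% .AA_ALPHABET)
    if (length(bad))
        stop(what, " has non-alphabet residue '", ch[bad[1L]],
             "' at position ", bad[1L])
    paste(ch, collapse = "")
}

.alignmentStats <- function(aq, ar) {
    qc <- strsplit(aq, "")[[1]]
    rc <- strsplit(ar, "")[[1]]
    ident <- sum(qc == rc & qc != "-")
    list(nColumns = length(qc), nIdentical = ident,
         identity = if (length(qc)) ident / length(qc) else 0)
}

#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch alignment under affine gap penalties with end
#' gaps penalized. Identity is the number of identical residue pairs divided
#' by the total number of alignment columns, including gap and end-gap
#' columns (one documented convention, applied everywhere).
#'
#' @param a,b non-empty amino-acid strings (standard 20 residues + X).
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return a list of class \code{"Alignment"}: \code{alignedQuery},
#'   \code{alignedRef} (gap character \code{-}), \code{score},
#'   \code{nColumns}, \code{nIdentical}, \code{identity}, \code{coverage}
#'   (always 1 for global alignments).
#' @examples
#' alignGlobal("MKV", "MQV")$identity  # 2/3
#' @export
alignGlobal <- function(a, b, scheme = scoringScheme()) {
    a <- .checkProtein(a, "query")
    b <- .checkProtein(b, "reference")
    p <- pairwiseAlignment(AAString(a), AAString(b),
                           substitutionMatrix = scheme@matrix,
                           gapOpening = scheme@gapOpen,
                           gapExtension = scheme@gapExtend, type = "global")
    aq <- as.character(alignedPattern(p))
    ar <- as.character(alignedSubject(p))
    st <- .alignmentStats(aq, ar)
    structure(list(alignedQuery = aq, alignedRef = ar, score = score(p),
                   nColumns = st$nColumns, nIdentical = st$nIdentical,
                   identity = st$identity, coverage = 1),
              class = "Alignment")
}

#' Local pairwise protein alignment
#'
#' Optimal Smith-Waterman alignment. Identity is computed over the local
#' alignment columns only; coverage is the aligned query span divided by the
#' query length. When no residue pair scores positive the alignment is empty
#' with score 0.
#'
#' @inheritParams alignGlobal
#' @return a list of class \code{"Alignment"} (see \code{\link{alignGlobal}}).
#' @export
alignLocal <- function(a, b, scheme = scoringScheme()) {
    a <- .checkProtein(a, "query")
    b <- .checkProtein(b, "reference")
    p <- pairwiseAlignment(AAString(a), AAString(b),
                           substitutionMatrix = scheme@matrix,
                           gapOpening = scheme@gapOpen,
                           gapExtension = scheme@gapExtend, type = "local")
    if (score(p) <= 0 && nchar(p) == 0L)
        return(structure(list(alignedQuery = "", alignedRef = "",
                              score = 0, nColumns = 0L, nIdentical = 0L,
                              identity = 0, coverage = 0),
                         class = "Alignment"))
    aq <- as.character(alignedPattern(p))
    ar <- as.character(alignedSubject(p))
    st <- .alignmentStats(aq, ar)
    span <- Biostrings::width(pattern(p))
    structure(list(alignedQuery = aq, alignedRef = ar, score = score(p),
                   nColumns = st$nColumns, nIdentical = st$nIdentical,
                   identity = st$identity,
                   coverage = span / nchar(a)),
              class = "Alignment")
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates all three forward and three reverse-complement frames under
#' the standard genetic code. Stop codons are emitted as \code{*}, codons
#' containing N as \code{X}; trailing partial codons are dropped.
#'
#' @param x nucleotide string over A, C, G, T, N (case-insensitive).
#' @return named character vector of 6 amino-acid strings
#'   (\code{"+1" "+2" "+3" "-1" "-2" "-3"}).
#' @examples
#' translateSixFrames("ATGAAAGTT")[["+1"]]  # "MKV"
#' @export
translateSixFrames <- function(x) {
    if (!is.character(x) || length(x) != 1L)
        stop("x must be a single nucleotide string")
    xs <- toupper(x)
    ch <- strsplit(xs, "")[[1]]
    bad <- which(!ch %in% c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop("non-nucleotide character '", ch[bad[1L]], "' at position ",
             bad[1L])
    fwd <- DNAString(xs)
    rev <- reverseComplement(fwd)
    one <- function(s, off) {
        L <- length(s) - off
        n <- L - (L %% 3L)
        if (n < 3L) return("")
        as.character(translate(subseq(s, start = off + 1L,
                                      width = n),
                               if.fuzzy.codon = "X"))
    }
    out <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
             one(rev, 0L), one(rev, 1L), one(rev, 2L))
    names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
    out
}

## Score matrix: queries x refs, one vectorized scoreOnly call per reference
## (much cheaper than one call per query for large read sets).
.scoreMatrix <- function(queries, refs, type, scheme) {
    S <- matrix(NA_real_, nrow = length(queries), ncol = length(refs))
    for (j in seq_along(refs)) {
        S[, j] <- pairwiseAlignment(queries, refs[[j]],
                                    substitutionMatrix = scheme@matrix,
                                    gapOpening = scheme@gapOpen,
                                    gapExtension = scheme@gapExtend,
                                    type = type, scoreOnly = TRUE)
    }
    colnames(S) <- names(refs)
    S
}

## Identity and coverage for one query/ref pair without materializing the
## aligned strings (nmatch/nchar are cheap; aligned strings are not).
## Global alignment columns include end gaps, reconstructed from the ranges.
.pairIdentity <- function(query, ref, type, scheme) {
    p <- pairwiseAlignment(AAString(query), AAString(ref),
                           substitutionMatrix = scheme@matrix,
                           gapOpening = scheme@gapOpen,
                           gapExtension = scheme@gapExtend, type = type)
    ncols <- nchar(p)
    qr <- pattern(p)
    sr <- subject(p)
    span <- Biostrings::width(qr)
    if (type == "global") {
        ncols <- ncols +
            (Biostrings::start(qr) - 1L) +
            (nchar(query) - Biostrings::end(qr)) +
            (Biostrings::start(sr) - 1L) +
            (nchar(ref) - Biostrings::end(sr))
        cov <- 1
    } else {
        cov <- span / nchar(query)
    }
    if (ncols == 0L)
        return(list(identity = 0, coverage = 0, score = max(0, score(p))))
    list(identity = nmatch(p) / ncols, coverage = cov, score = score(p))
}

## Deterministic best hit of one query against a reference set, given the
## precomputed score vector. Walks score tiers downward; within a tier,
## identity is computed only for the tied references, the identity filter is
## applied, and remaining ties break by higher identity then smallest ref id.
.bestFromScores <- function(query, refs, scores, type, config, scheme) {
    ok <- which(scores >= config$minScore)
    if (!length(ok)) return(NULL)
    for (s in sort(unique(scores[ok]), decreasing = TRUE)) {
        idx <- ok[scores[ok] == s]
        ids <- names(refs)[idx]
        stats <- lapply(idx, function(j)
            .pairIdentity(query, as.character(refs[[j]]), type, scheme))
        identity <- vapply(stats, `[[`, numeric(1), "identity")
        pass <- identity >= config$minIdentity
        if (any(pass)) {
            ids <- ids[pass]; identity <- identity[pass]
            cov <- vapply(stats, `[[`, numeric(1), "coverage")[pass]
            o <- order(-identity, ids)[1L]
            return(list(ref_id = ids[o], score = s, identity = identity[o],
                        coverage = cov[o]))
        }
    }
    NULL
}

#' Best-hit search of a query against a reference database
#'
#' Returns the single highest-scoring reference passing the identity (and
#' score) thresholds. Ties on score break by higher identity, then by
#' lexicographically smallest reference id, so the result is independent of
#' database record order. In translated mode the best frame's best hit is
#' returned (frames tie-break in the order +1, +2, +3, -1, -2, -3). Absence
#' of a passing hit is a value (NULL), not an error.
#'
#' @param query a single amino-acid string (or nucleotide string in
#'   translated mode).
#' @param db a \code{\linkS4class{ReferenceDatabase}} or a named
#'   \code{AAStringSet}.
#' @param config a \code{\link{searchConfig}}.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @return one-row data.frame (\code{ref_id}, \code{kind}, \code{label},
#'   \code{score}, \code{identity}, \code{coverage}, \code{frame}) or NULL.
#' @export
bestHit <- function(query, db, config = searchConfig(),
                    scheme = scoringScheme()) {
    refs <- if (is(db, "ReferenceDatabase")) db@sequences else db
    if (!length(refs)) stop("reference database is empty")
    if (is.null(names(refs)) || anyDuplicated(names(refs)))
        stop("references must have unique names")
    if (config$mode == "translated_local") {
        frames <- translateSixFrames(query)
        best <- NULL
        for (fr in names(frames)) {
            q <- frames[[fr]]
            if (nchar(q) == 0L) next
            sc <- .scoreMatrix(AAStringSet(q), refs, "local", scheme)[1L, ]
            h <- .bestFromScores(q, refs, sc, "local", config, scheme)
            if (!is.null(h)) {
                h$frame <- fr
                if (is.null(best) || h$score > best$score ||
                    (h$score == best$score && h$identity > best$identity) ||
                    (h$score == best$score && h$identity == best$identity &&
                     h$ref_id < best$ref_id))
                    best <- h
            }
        }
        h <- best
    } else {
        type <- config$mode
        q <- .checkProtein(query, "query")
        sc <- .scoreMatrix(AAStringSet(q), refs, type, scheme)[1L, ]
        h <- .bestFromScores(q, refs, sc, type, config, scheme)
        if (!is.null(h)) h$frame <- NA_character_
    }
    if (is.null(h)) return(NULL)
    if (is(db, "ReferenceDatabase")) {
        i <- match(h$ref_id, db@seqInfo$seq_id)
        kind <- db@seqInfo$kind[i]
        label <- db@seqInfo$label[i]
    } else {
        kind <- NA_character_; label <- NA_character_
    }
    data.frame(ref_id = h$ref_id, kind = kind, label = label,
               score = h$score, identity = h$identity,
               coverage = h$coverage, frame = h$frame,
               stringsAsFactors = FALSE)
}

#' Parse a 12-column tabular hit file
#'
#' Reads the tab-separated best-hit format used for adapter interchange
#' (query, reference, percent identity, alignment length, mismatches, gap
#' opens, query start/end, reference start/end, e-value, bit score).
#'
#' @param path path to the tabular file.
#' @return data.frame of hits with \code{identity} rescaled to [0, 1] and
#'   \code{score} taken from the bit score column; zero rows for an empty
#'   file.
#' @export
readHitTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(query_id = character(), ref_id = character(),
                          identity = numeric(), length = integer(),
                          mismatches = integer(), gapopens = integer(),
                          qstart = integer(), qend = integer(),
                          sstart = integer(), send = integer(),
                          evalue = numeric(), score = numeric(),
                          stringsAsFactors = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 12L)
    if (length(bad))
        stop("malformed hit table line ", bad[1L], ": expected 12 columns, ",
             "got ", lengths(parts)[bad[1L]])
    m <- do.call(rbind, parts)
    num <- function(j) suppressWarnings(as.numeric(m[, j]))
    out <- data.frame(query_id = m[, 1L], ref_id = m[, 2L],
                      identity = num(3L) / 100, length = as.integer(num(4L)),
                      mismatches = as.integer(num(5L)),
                      gapopens = as.integer(num(6L)),
                      qstart = as.integer(num(7L)), qend = as.integer(num(8L)),
                      sstart = as.integer(num(9L)), send = as.integer(num(10L)),
                      evalue = num(11L), score = num(12L),
                      stringsAsFactors = FALSE)
    badnum <- which(!stats::complete.cases(out[c("identity", "evalue",
                                                 "score")]))
    if (length(badnum))
        stop("malformed hit table line ", badnum[1L],
             ": non-numeric identity/evalue/score")
    out
}

#' Run an external best-hit search engine
#'
#' Thin adapter around a BLAST+-style protein search. The engine is run with
#' a one-best-hit contract (tabular 12-column output), and hits are filtered
#' to the configured e-value ceiling and identity threshold so the results
#' are interchangeable with the built-in search at the hit level.
#'
#' @param queryFasta path to the query protein FASTA.
#' @param dbFasta path to the reference protein FASTA.
#' @param config a \code{\link{searchConfig}}.
#' @param engine search engine executable (default \code{"blastp"}; the
#'   formatter \code{makeblastdb} must be on the path as well).
#' @return data.frame of best hits per query (possibly zero rows), as from
#'   \code{\link{readHitTable}}.
#' @export
externalSearchAdapter <- function(queryFasta, dbFasta,
                                  config = searchConfig(),
                                  engine = "blastp") {
    if (Sys.which(engine) == "" || Sys.which("makeblastdb") == "")
        stop("external search engine '", engine,
             "' (or makeblastdb) is not available on the path")
    nq <- length(readLines(queryFasta))
    out <- tempfile(fileext = ".tsv")
    if (nq == 0L) {
        file.create(out)
        return(readHitTable(out))
    }
    dbdir <- tempfile("blastdb")
    dir.create(dbdir)
    dbpath <- file.path(dbdir, "ref")
    rc <- system2("makeblastdb",
                  c("-in", shQuote(dbFasta), "-dbtype", "prot",
                    "-out", shQuote(dbpath)),
                  stdout = FALSE, stderr = FALSE)
    if (rc != 0L) stop("makeblastdb failed with status ", rc)
    rc <- system2(engine,
                  c("-query", shQuote(queryFasta), "-db", shQuote(dbpath),
                    "-outfmt", "6", "-max_target_seqs", "1",
                    "-evalue", format(config$evalue, scientific = TRUE),
                    "-out", shQuote(out)),
                  stdout = FALSE, stderr = FALSE)
    if (rc != 0L) stop(engine, " failed with status ", rc)
    hits <- readHitTable(out)
    hits <- hits[hits$evalue <= config$evalue &
                 hits$identity >= config$minIdentity, , drop = FALSE]
    hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Convert a hit table into read assignments
#'
#' Maps externally produced best hits onto the three-way assignment contract
#' (assigned / homolog_absorbed / unassigned) using the reference database's
#' target/decoy labels, so external and built-in searches are interchangeable
#' downstream.
#'
#' @param hits data.frame with columns \code{query_id}, \code{ref_id},
#'   \code{score}, \code{identity} (one row per query).
#' @param readIds character vector of all query ids searched (reads without
#'   a hit become unassigned).
#' @param db the \code{\linkS4class{ReferenceDatabase}} searched against.
#' @return assignment data.frame as from \code{\link{assignReads}}.
#' @export
assignmentsFromHits <- function(hits, readIds, db) {
    stopifnot(is(db, "ReferenceDatabase"))
    unknown <- setdiff(hits$ref_id, db@seqInfo$seq_id)
    if (length(unknown))
        stop("hits name references absent from the database: ",
             paste(head(unknown, 5L), collapse = ", "))
    out <- data.frame(read_id = readIds, status = "unassigned",
                      family_id = NA_character_, ref_id = NA_character_,
                      score = NA_real_, identity = NA_real_,
                      frame = NA_character_, stringsAsFactors = FALSE)
    i <- match(hits$query_id, out$read_id)
    if (anyNA(i))
        stop("hits name queries absent from readIds: ",
             paste(head(hits$query_id[is.na(i)], 5L), collapse = ", "))
    j <- match(hits$ref_id, db@seqInfo$seq_id)
    kind <- db@seqInfo$kind[j]
    out$status[i] <- ifelse(kind == "target", "assigned", "homolog_absorbed")
    out$family_id[i] <- ifelse(kind == "target", db@seqInfo$label[j],
                               NA_character_)
    out$ref_id[i] <- hits$ref_id
    out$score[i] <- hits$score
    out$identity[i] <- hits$identity
    out
}
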