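## Family/pathway registry and the database-summary arithmetic.

.SOURCE_DBS <- c("arCOG", "COG", "eggNOG", "KEGG")

#' Load a gene family / pathway registry
#'
#' Reads a family registry TSV (family id, annotation, semicolon-separated
#' pathway ids, semicolon-separated homolog family ids) and, optionally, a
#' per-(family, pathway) counts fixture TSV mirroring a published database
#' summary table. Shared families (members of several pathways) are stored
#' once with a pathway-membership set; the fixture is validated so that the
#' repeated rows printed for a shared family carry identical counts.
#'
#' Called with no arguments, loads the packaged registry of 60 cobalamin
#' (vitamin B12) biosynthesis gene (sub)families organized into five pathway
#' processes, with the published core/full sequence counts and per-source
#' homolog-group counts attached.
#'
#' @param registryTsv path to the registry TSV; default: packaged cobalamin
#'   registry.
#' @param fixtureTsv path to the counts fixture TSV, or NA to attach none;
#'   default: packaged cobalamin counts.
#' @param pathwayOrder optional character vector fixing the pathway order;
#'   defaults to order of first appearance.
#' @return a \code{\linkS4class{FamilyRegistry}}.
#' @examples
#' reg <- loadRegistry()
#' length(familyIds(reg))        # 60
#' pathwayMembers(reg, "precorrin2")
#' @export
loadRegistry <- function(registryTsv = NULL, fixtureTsv = NULL,
                         pathwayOrder = NULL) {
    if (is.null(registryTsv))
        registryTsv <- system.file("extdata", "cobalamin_families.tsv",
                                   package = "FamPath", mustWork = TRUE)
    if (is.null(fixtureTsv))
        fixtureTsv <- system.file("extdata", "cobalamin_family_counts.tsv",
                                  package = "FamPath", mustWork = TRUE)
    fam <- read.delim(registryTsv, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("family_id", "annotation", "pathways")
    if (!all(need %in% names(fam)))
        stop("registry TSV must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(fam$family_id))
        stop("duplicated family_id rows: ",
             paste(unique(fam$family_id[duplicated(fam$family_id)]),
                   collapse = ", "))
    splitSemi <- function(x) {
        out <- strsplit(x, ";", fixed = TRUE)
        lapply(out, function(v) v[nzchar(v)])
    }
    memberships <- splitSemi(fam$pathways)
    if (any(lengths(memberships) == 0L))
        stop("every family must belong to at least one pathway; offenders: ",
             paste(fam$family_id[lengths(memberships) == 0L], collapse = ", "))
    pwids <- unique(unlist(memberships))
    if (!is.null(pathwayOrder)) {
        if (!setequal(pathwayOrder, pwids))
            stop("pathwayOrder must name exactly the pathways in the TSV")
        pwids <- pathwayOrder
    }
    pathways <- lapply(pwids, function(p)
        fam$family_id[vapply(memberships, function(m) p %in% m, logical(1))])
    names(pathways) <- pwids

    homologs <- list()
    if ("homolog_family_ids" %in% names(fam)) {
        h <- splitSemi(fam$homolog_family_ids)
        names(h) <- fam$family_id
        homologs <- h[lengths(h) > 0L]
        unknown <- setdiff(unlist(homologs), fam$family_id)
        if (length(unknown))
            stop("homolog ids not in registry: ",
                 paste(unknown, collapse = ", "))
    }

    counts <- data.frame()
    if (!is.na(fixtureTsv)) {
        counts <- read.delim(fixtureTsv, stringsAsFactors = FALSE)
        need <- c("pathway_id", "family_id", "core_count", "full_count",
                  .SOURCE_DBS)
        if (!all(need %in% names(counts)))
            stop("fixture TSV must have columns: ",
                 paste(need, collapse = ", "))
        numcols <- c("core_count", "full_count", .SOURCE_DBS)
        for (cc in numcols) counts[[cc]] <- as.integer(counts[[cc]])
        bad <- !counts$family_id %in% fam$family_id
        if (any(bad))
            stop("fixture rows name unknown families: ",
                 paste(unique(counts$family_id[bad]), collapse = ", "))
        key <- paste(counts$pathway_id, counts$family_id)
        if (anyDuplicated(key))
            stop("duplicate fixture row(s): ",
                 paste(unique(key[duplicated(key)]), collapse = "; "))
        ## a family shared by k pathways is printed k times; rows must agree
        for (f in unique(counts$family_id)) {
            rows <- counts[counts$family_id == f, numcols, drop = FALSE]
            if (nrow(rows) > 1L && nrow(unique(rows)) != 1L)
                stop("conflicting duplicate counts for shared family '", f,
                     "' across pathways")
        }
        neg <- counts[numcols] < 0
        if (any(neg, na.rm = TRUE))
            stop("fixture counts must be non-negative")
    }

    new("FamilyRegistry",
        families = fam[c("family_id", "annotation")],
        pathways = pathways, homologs = homologs, counts = counts)
}

#' Deduplicated sequence-count total over distinct families
#'
#' Sums a fixture column over the distinct families of the registry, counting
#' each shared family once (its printed per-pathway rows are identical by
#' validation). On the packaged cobalamin registry this reproduces the
#' published deduplicated totals: 168,630 core and 287,731 full sequences,
#' versus plain column sums of 178,322 and 324,044 that double-count shared
#' families.
#'
#' @param registry a \code{\linkS4class{FamilyRegistry}} with counts attached.
#' @param field \code{"core_count"} or \code{"full_count"}.
#' @return integer total.
#' @examples
#' uniqueFamilyTotal(loadRegistry(), "core_count")  # 168630
#' @export
uniqueFamilyTotal <- function(registry, field = c("core_count",
                                                  "full_count")) {
    stopifnot(is(registry, "FamilyRegistry"))
    field <- match.arg(field)
    counts <- registry@counts
    if (!nrow(counts)) stop("registry has no counts fixture attached")
    first <- counts[!duplicated(counts$family_id), ]
    sum(first[[field]])
}

#' Homolog-group total for one pathway
#'
#' Sums the four per-source homolog-group counts (arCOG, COG, eggNOG, KEGG)
#' over a pathway's families as printed, treating NA (count not available)
#' as zero. On the packaged registry the five pathways give 8,652 / 2,910 /
#' 2,256 / 1,691 / 7,303.
#'
#' @param registry a \code{\linkS4class{FamilyRegistry}} with counts.
#' @param pathway pathway id.
#' @return integer total.
#' @export
pathwayHomologGroupTotal <- function(registry, pathway) {
    stopifnot(is(registry, "FamilyRegistry"))
    if (!pathway %in% names(registry@pathways))
        stop("unknown pathway: ", pathway)
    counts <- registry@counts
    if (!nrow(counts)) stop("registry has no counts fixture attached")
    rows <- counts[counts$pathway_id == pathway, .SOURCE_DBS, drop = FALSE]
    sum(vapply(rows, function(col) sum(col, na.rm = TRUE), numeric(1)))
}

#' Per-source homolog-group totals
#'
#' Totals of the homolog-group counts per source database, either over
#' distinct families (each shared family counted once; the reading behind
#' the published 650 + 770 + 17,546 + 2,188 = 21,154) or by straight
#' summation of the printed rows (which double-counts shared families).
#'
#' @param registry a \code{\linkS4class{FamilyRegistry}} with counts.
#' @param deduplicate count each shared family once (default TRUE).
#' @return named integer vector over sources (arCOG, COG, eggNOG, KEGG).
#' @export
homologGroupTotals <- function(registry, deduplicate = TRUE) {
    stopifnot(is(registry, "FamilyRegistry"))
    counts <- registry@counts
    if (!nrow(counts)) stop("registry has no counts fixture attached")
    if (deduplicate) counts <- counts[!duplicated(counts$family_id), ]
    vapply(counts[.SOURCE_DBS], function(col) sum(col, na.rm = TRUE),
           numeric(1))
}

#' Roll per-family counts up to pathways
#'
#' Aggregates per-family observations (e.g. read counts) to pathway totals.
#' In \code{"replicate"} mode a family shared by k pathways contributes its
#' full count to each of them (so pathway totals can exceed the family total);
#' in \code{"fractional"} mode its count is split equally, conserving total
#' mass exactly.
#'
#' @param registry a \code{\linkS4class{FamilyRegistry}}.
#' @param perFamilyCounts named numeric vector keyed by family id.
#' @param shareMode \code{"replicate"} or \code{"fractional"}.
#' @return named numeric vector over all registry pathways (zero where no
#'   member family was observed).
#' @examples
#' reg <- loadRegistry()
#' rollupCountsByPathway(reg, c(cobA = 10), "replicate")
#' @export
rollupCountsByPathway <- function(registry, perFamilyCounts,
                                  shareMode = c("replicate", "fractional")) {
    stopifnot(is(registry, "FamilyRegistry"))
    shareMode <- match.arg(shareMode)
    fams <- names(perFamilyCounts)
    if (is.null(fams) && length(perFamilyCounts))
        stop("perFamilyCounts must be named by family id")
    unknown <- setdiff(fams, registry@families$family_id)
    if (length(unknown))
        stop("unknown family id(s): ", paste(unknown, collapse = ", "))
    nPathwaysOf <- table(unlist(registry@pathways))
    out <- setNames(numeric(length(registry@pathways)),
                    names(registry@pathways))
    for (p in names(registry@pathways)) {
        members <- intersect(registry@pathways[[p]], fams)
        if (!length(members)) next
        v <- perFamilyCounts[members]
        if (shareMode == "fractional")
            v <- v / as.numeric(nPathwaysOf[members])
        out[[p]] <- sum(v)
    }
    out
}
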