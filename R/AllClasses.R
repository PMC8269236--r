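## Central S4 classes. Tabular results (hits, read assignments, reports)
## are plain data.frames with documented columns; the classes below carry
## multi-part state that benefits from validity checking.

#' @importClassesFrom Biostrings AAStringSet
NULL

#' FamilyRegistry: gene families, pathways, and packaged counts
#'
#' Holds the curated gene (sub)families, their free-text annotations, the
#' pathway membership sets (families may belong to several pathways), the
#' declared homology relation between families, and (optionally) a
#' per-(family, pathway) counts fixture transcribing published database
#' summaries.
#'
#' @slot families data.frame with columns \code{family_id}, \code{annotation}.
#' @slot pathways named list; each element is the ordered character vector of
#'   member family ids for one pathway.
#' @slot homologs named list; \code{homologs[[f]]} is the character vector of
#'   family ids declared homologous to family \code{f} (symmetric).
#' @slot counts data.frame with columns \code{pathway_id}, \code{family_id},
#'   \code{core_count}, \code{full_count}, \code{arCOG}, \code{COG},
#'   \code{eggNOG}, \code{KEGG}; zero rows when no fixture is attached.
#'   Homolog-group columns may be NA (count not available).
#'
#' @seealso \code{\link{loadRegistry}}, \code{\link{uniqueFamilyTotal}},
#'   \code{\link{rollupCountsByPathway}}
#' @exportClass FamilyRegistry
setClass("FamilyRegistry", representation(
    families = "data.frame",
    pathways = "list",
    homologs = "list",
    counts = "data.frame"
))

setValidity("FamilyRegistry", function(object) {
    msg <- character()
    fam <- object@families
    if (!all(c("family_id", "annotation") %in% names(fam)))
        msg <- c(msg, "families must have columns family_id, annotation")
    else {
        if (anyDuplicated(fam$family_id))
            msg <- c(msg, "duplicated family_id in registry")
        unknown <- setdiff(unlist(object@pathways), fam$family_id)
        if (length(unknown))
            msg <- c(msg, paste0("pathway members not in registry: ",
                                 paste(unknown, collapse = ", ")))
        for (f in names(object@homologs)) {
            for (g in object@homologs[[f]]) {
                if (!f %in% object@homologs[[g]])
                    msg <- c(msg, paste0("homology not symmetric: ", f,
                                         " -> ", g))
            }
        }
        if (!all(names(object@homologs) %in% fam$family_id))
            msg <- c(msg, "homolog keys must be registry families")
    }
    if (nrow(object@counts)) {
        need <- c("pathway_id", "family_id", "core_count", "full_count",
                  "arCOG", "COG", "eggNOG", "KEGG")
        if (!all(need %in% names(object@counts)))
            msg <- c(msg, "counts fixture lacks required columns")
        else if (!all(object@counts$pathway_id %in% names(object@pathways)))
            msg <- c(msg, "counts fixture names unknown pathway")
    }
    if (length(msg)) msg else TRUE
})

#' ReferenceDatabase: tiered protein reference store
#'
#' A tier-tagged container separating target-family sequences from
#' homolog-decoy groups. Decoy records are only admitted at the \code{full}
#' tier; \code{seed} and \code{core} tiers hold targets only.
#'
#' @slot tier one of \code{"seed"}, \code{"core"}, \code{"full"}.
#' @slot sequences \code{AAStringSet} of all records, named by \code{seq_id}.
#' @slot seqInfo data.frame aligned with \code{sequences}: columns
#'   \code{seq_id}, \code{kind} (\code{"target"} or \code{"decoy"}),
#'   \code{label} (family id for targets, group id for decoys),
#'   \code{source_db}, \code{taxonomy} (semicolon-separated 7-rank lineage or
#'   NA), \code{duplicates} (semicolon-separated ids collapsed into this
#'   record by exact deduplication, or NA).
#'
#' @seealso \code{\link{buildSeed}}, \code{\link{assignReads}},
#'   \code{\link{writeReferenceFasta}}
#' @exportClass ReferenceDatabase
setClass("ReferenceDatabase", representation(
    tier = "character",
    sequences = "AAStringSet",
    seqInfo = "data.frame"
))

setValidity("ReferenceDatabase", function(object) {
    msg <- character()
    if (!(length(object@tier) == 1L &&
          object@tier %in% c("seed", "core", "full")))
        msg <- c(msg, "tier must be one of seed, core, full")
    info <- object@seqInfo
    need <- c("seq_id", "kind", "label", "source_db", "taxonomy", "duplicates")
    if (!all(need %in% names(info)))
        msg <- c(msg, paste0("seqInfo must have columns: ",
                             paste(need, collapse = ", ")))
    else {
        if (nrow(info) != length(object@sequences))
            msg <- c(msg, "seqInfo rows must match sequences")
        if (anyDuplicated(info$seq_id))
            msg <- c(msg, "seq ids must be globally unique")
        if (length(object@sequences) &&
            !identical(names(object@sequences), info$seq_id))
            msg <- c(msg, "sequence names must equal seqInfo$seq_id")
        if (!all(info$kind %in% c("target", "decoy")))
            msg <- c(msg, "kind must be target or decoy")
        if (length(object@tier) == 1L && object@tier != "full" &&
            any(info$kind == "decoy"))
            msg <- c(msg, "decoy records are only allowed in the full tier")
    }
    if (length(msg)) msg else TRUE
})

#' ScoringScheme: substitution matrix and affine gap penalties
#'
#' @slot matrixName name of the substitution matrix (e.g. "BLOSUM62").
#' @slot matrix numeric substitution matrix, symmetric over its alphabet.
#' @slot gapOpen positive gap opening penalty; a gap of length k costs
#'   \code{gapOpen + k * gapExtend}.
#' @slot gapExtend positive per-residue gap extension penalty.
#' @exportClass ScoringScheme
setClass("ScoringScheme", representation(
    matrixName = "character",
    matrix = "matrix",
    gapOpen = "numeric",
    gapExtend = "numeric"
))

setValidity("ScoringScheme", function(object) {
    msg <- character()
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
        msg <- c(msg, "gap penalties must be > 0")
    m <- object@matrix
    if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "substitution matrix must be symmetric")
    if (length(msg)) msg else TRUE
})

#' FunctionalProfile: per-sample functional gene-family abundances
#'
#' @slot sampleId sample identifier.
#' @slot families data.frame: \code{family_id}, \code{count},
#'   \code{rel_abundance} (count / number of assigned reads).
#' @slot pathways data.frame: \code{pathway_id}, \code{count_replicate}
#'   (shared families contribute their full count to every member pathway),
#'   \code{count_fractional} (count split equally across member pathways),
#'   and the matching relative abundances.
#' @slot totals named list: \code{n_reads}, \code{n_assigned},
#'   \code{n_absorbed}, \code{n_unassigned}.
#' @slot zeroAssigned logical flag; TRUE when no read was assigned and the
#'   relative abundances are reported as zero by convention.
#' @exportClass FunctionalProfile
setClass("FunctionalProfile", representation(
    sampleId = "character",
    families = "data.frame",
    pathways = "data.frame",
    totals = "list",
    zeroAssigned = "logical"
))

setValidity("FunctionalProfile", function(object) {
    msg <- character()
    tot <- object@totals
    need <- c("n_reads", "n_assigned", "n_absorbed", "n_unassigned")
    if (!all(need %in% names(tot)))
        msg <- c(msg, "totals must name n_reads, n_assigned, n_absorbed, n_unassigned")
    else if (tot$n_assigned + tot$n_absorbed + tot$n_unassigned != tot$n_reads)
        msg <- c(msg, "assigned + absorbed + unassigned must equal n_reads")
    if (!object@zeroAssigned && nrow(object@families) &&
        abs(sum(object@families$rel_abundance) - 1) > 1e-8)
        msg <- c(msg, "family relative abundances must sum to 1")
    if (length(msg)) msg else TRUE
})

#' ConfusionSummary: assignment accuracy bookkeeping
#'
#' @slot counts named list: \code{tp} (target-derived queries assigned to
#'   their true family), \code{fp} (queries assigned although decoy-derived,
#'   unrelated, or assigned to the wrong family), \code{fn} (target-derived
#'   queries not assigned to their true family).
#' @slot perClass data.frame with one row per truth class
#'   (\code{target}, \code{decoy}, \code{unrelated}): class size, number
#'   assigned, number correct, and the class-specific rate with its
#'   denominator stated.
#' @exportClass ConfusionSummary
setClass("ConfusionSummary", representation(
    counts = "list",
    perClass = "data.frame"
))

#' SmallDbReport: decoy-absorption quantification
#'
#' @slot nCoreAssigned reads assigned under the core (decoy-free) database.
#' @slot nAbsorbed of those, reads absorbed by homolog decoys under the full
#'   database.
#' @slot fraction \code{nAbsorbed / nCoreAssigned} (0 when nothing was
#'   core-assigned).
#' @slot perFamily data.frame: per core-assigned family, number of reads and
#'   number absorbed under the full database (the alternative denominator).
#' @exportClass SmallDbReport
setClass("SmallDbReport", representation(
    nCoreAssigned = "numeric",
    nAbsorbed = "numeric",
    fraction = "numeric",
    perFamily = "data.frame"
))

setValidity("SmallDbReport", function(object) {
    if (object@fraction < 0 || object@fraction > 1)
        "fraction must lie in [0, 1]" else TRUE
})

#' Ordination: principal coordinates embedding
#'
#' @slot points numeric matrix (samples x axes), column-centered, axes
#'   ordered by decreasing eigenvalue.
#' @slot eigenvalues all eigenvalues of the double-centered matrix,
#'   decreasing; negative values are retained here for inspection but get no
#'   axis.
#' @slot varExplained proportion of the positive-eigenvalue sum carried by
#'   each returned axis.
#' @slot nNegative number of negative eigenvalues (no correction applied).
#' @exportClass Ordination
setClass("Ordination", representation(
    points = "matrix",
    eigenvalues = "numeric",
    varExplained = "numeric",
    nNegative = "numeric"
))
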