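## Accessor generics and show methods.

#' @rdname FamilyRegistry-class
#' @param object,x a \code{FamilyRegistry}
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname FamilyRegistry-class
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname FamilyRegistry-class
#' @param pathway a pathway id
#' @export
setGeneric("pathwayMembers", function(x, pathway)
    standardGeneric("pathwayMembers"))

#' @rdname FamilyRegistry-class
#' @param family a family id
#' @export
setGeneric("homologFamilies", function(x, family)
    standardGeneric("homologFamilies"))

#' @rdname FamilyRegistry-class
#' @export
setGeneric("sharedFamilies", function(x) standardGeneric("sharedFamilies"))

#' @rdname FamilyRegistry-class
#' @export
setGeneric("familyCounts", function(x) standardGeneric("familyCounts"))

#' @rdname ReferenceDatabase-class
#' @param x a \code{ReferenceDatabase}
#' @export
setGeneric("dbTier", function(x) standardGeneric("dbTier"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("refInfo", function(x) standardGeneric("refInfo"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("targetSeqs", function(x) standardGeneric("targetSeqs"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("decoySeqs", function(x) standardGeneric("decoySeqs"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("familiesPresent", function(x) standardGeneric("familiesPresent"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("decoyGroups", function(x) standardGeneric("decoyGroups"))

#' @rdname FunctionalProfile-class
#' @param x a \code{FunctionalProfile}
#' @export
setGeneric("familyAbundance", function(x) standardGeneric("familyAbundance"))

#' @rdname FunctionalProfile-class
#' @export
setGeneric("pathwayAbundance", function(x) standardGeneric("pathwayAbundance"))

#' @rdname FunctionalProfile-class
#' @export
setGeneric("profileTotals", function(x) standardGeneric("profileTotals"))

setMethod("familyIds", "FamilyRegistry", function(x) x@families$family_id)
setMethod("pathwayIds", "FamilyRegistry", function(x) names(x@pathways))
setMethod("pathwayMembers", "FamilyRegistry", function(x, pathway) {
    if (!pathway %in% names(x@pathways))
        stop("unknown pathway: ", pathway)
    x@pathways[[pathway]]
})
setMethod("homologFamilies", "FamilyRegistry", function(x, family) {
    if (!family %in% x@families$family_id)
        stop("unknown family: ", family)
    h <- x@homologs[[family]]
    if (is.null(h)) character() else h
})
setMethod("sharedFamilies", "FamilyRegistry", function(x) {
    tab <- table(unlist(x@pathways))
    sort(names(tab)[tab > 1L])
})
setMethod("familyCounts", "FamilyRegistry", function(x) x@counts)

setMethod("show", "FamilyRegistry", function(object) {
    cat("FamilyRegistry with", nrow(object@families), "gene (sub)families in",
        length(object@pathways), "pathways\n")
    for (p in names(object@pathways))
        cat("  ", p, ": ", length(object@pathways[[p]]), " families\n",
            sep = "")
    sh <- sharedFamilies(object)
    if (length(sh))
        cat("  shared families:", paste(sh, collapse = ", "), "\n")
    if (nrow(object@counts))
        cat("  counts fixture attached (", nrow(object@counts),
            " rows)\n", sep = "")
})

setMethod("dbTier", "ReferenceDatabase", function(x) x@tier)
setMethod("refInfo", "ReferenceDatabase", function(x) x@seqInfo)
setMethod("targetSeqs", "ReferenceDatabase", function(x)
    x@sequences[x@seqInfo$kind == "target"])
setMethod("decoySeqs", "ReferenceDatabase", function(x)
    x@sequences[x@seqInfo$kind == "decoy"])
setMethod("familiesPresent", "ReferenceDatabase", function(x)
    sort(unique(x@seqInfo$label[x@seqInfo$kind == "target"])))
setMethod("decoyGroups", "ReferenceDatabase", function(x)
    sort(unique(x@seqInfo$label[x@seqInfo$kind == "decoy"])))

setMethod("show", "ReferenceDatabase", function(object) {
    info <- object@seqInfo
    cat("ReferenceDatabase [tier: ", object@tier, "]\n", sep = "")
    cat("  targets: ", sum(info$kind == "target"), " sequences in ",
        length(unique(info$label[info$kind == "target"])), " families\n",
        sep = "")
    if (any(info$kind == "decoy"))
        cat("  decoys:  ", sum(info$kind == "decoy"), " sequences in ",
            length(unique(info$label[info$kind == "decoy"])),
            " homolog groups\n", sep = "")
    if (any(!is.na(info$taxonomy)))
        cat("  taxonomy present for ", sum(!is.na(info$taxonomy)),
            " records\n", sep = "")
})

setMethod("show", "ScoringScheme", function(object) {
    cat("ScoringScheme: ", object@matrixName, ", gap open ", object@gapOpen,
        ", gap extend ", object@gapExtend, "\n", sep = "")
})

setMethod("familyAbundance", "FunctionalProfile", function(x) x@families)
setMethod("pathwayAbundance", "FunctionalProfile", function(x) x@pathways)
setMethod("profileTotals", "FunctionalProfile", function(x) x@totals)

setMethod("show", "FunctionalProfile", function(object) {
    t <- object@totals
    cat("FunctionalProfile for sample '", object@sampleId, "'\n", sep = "")
    cat("  reads: ", t$n_reads, " (assigned ", t$n_assigned, ", absorbed ",
        t$n_absorbed, ", unassigned ", t$n_unassigned, ")\n", sep = "")
    if (nrow(object@families)) {
        top <- head(object@families[order(-object@families$count), ], 3L)
        cat("  top families: ",
            paste0(top$family_id, " (", top$count, ")", collapse = ", "),
            "\n", sep = "")
    }
})

setMethod("show", "ConfusionSummary", function(object) {
    cat("ConfusionSummary: TP ", object@counts$tp, ", FP ", object@counts$fp,
        ", FN ", object@counts$fn, "\n", sep = "")
    print(object@perClass, row.names = FALSE)
})

setMethod("show", "SmallDbReport", function(object) {
    cat("SmallDbReport: ", object@nAbsorbed, "/", object@nCoreAssigned,
        " core-assigned reads absorbed by decoys (fraction ",
        signif(object@fraction, 4), ")\n", sep = "")
})

setMethod("show", "Ordination", function(object) {
    cat("Ordination: ", nrow(object@points), " samples on ",
        ncol(object@points), " axes\n", sep = "")
    cat("  variance explained:",
        paste(signif(object@varExplained, 3), collapse = ", "), "\n")
    if (object@nNegative > 0)
        cat("  ", object@nNegative,
            " negative eigenvalues (no correction applied)\n", sep = "")
})
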