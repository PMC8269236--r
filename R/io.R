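## Reference FASTA I/O using the package header convention:
##   >{seq_id} fam={family_id|group_id} kind={target|decoy} tax={lineage}

.newRefDb <- function(sequences, info, tier) {
    info <- as.data.frame(info, stringsAsFactors = FALSE)
    for (col in c("source_db", "taxonomy", "duplicates"))
        if (is.null(info[[col]])) info[[col]] <- NA_character_
    info <- info[c("seq_id", "kind", "label", "source_db", "taxonomy",
                   "duplicates")]
    rownames(info) <- NULL
    names(sequences) <- info$seq_id
    new("ReferenceDatabase", tier = tier, sequences = sequences,
        seqInfo = info)
}

#' Write a reference database to FASTA
#'
#' Headers follow the convention
#' \code{>seq_id fam=<label> kind=<target|decoy> tax=<lineage>}; the
#' \code{tax=} field is omitted for records without taxonomy.
#'
#' @param db a \code{\linkS4class{ReferenceDatabase}}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceFasta <- function(db, path) {
    stopifnot(is(db, "ReferenceDatabase"))
    info <- db@seqInfo
    hdr <- paste0(info$seq_id, " fam=", info$label, " kind=", info$kind,
                  ifelse(is.na(info$taxonomy), "",
                         paste0(" tax=", info$taxonomy)))
    seqs <- db@sequences
    names(seqs) <- hdr
    writeXStringSet(seqs, path)
    invisible(path)
}

#' Read a reference database from FASTA
#'
#' Parses the header convention written by \code{\link{writeReferenceFasta}}.
#'
#' @param path FASTA path.
#' @param tier tier tag for the reconstructed database.
#' @return a \code{\linkS4class{ReferenceDatabase}}.
#' @export
readReferenceFasta <- function(path, tier = "full") {
    seqs <- readAAStringSet(path)
    hdr <- names(seqs)
    field <- function(key) {
        m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
        out <- rep(NA_character_, length(hdr))
        has <- grepl(paste0(key, "="), hdr, fixed = TRUE)
        out[has] <- sub(paste0(key, "="), "",
                        regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr)))
        out
    }
    ids <- sub(" .*$", "", hdr)
    info <- data.frame(seq_id = ids, kind = field("kind"),
                       label = field("fam"), source_db = NA_character_,
                       taxonomy = field("tax"), duplicates = NA_character_,
                       stringsAsFactors = FALSE)
    if (anyNA(info$kind) || anyNA(info$label))
        stop("FASTA headers must carry fam= and kind= fields")
    .newRefDb(seqs, info, tier)
}

#' Write an assignment table or profile to TSV
#'
#' @param x a data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
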