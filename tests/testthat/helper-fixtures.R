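# Shared fixture builders. All sequence fixtures are generated in code under
# fixed seeds; nothing binary is stored.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
          "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomProtein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# substitute exactly k positions, never back to the original residue
mutateK <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
    paste(ch, collapse = "")
}

# 3-family toy registry: famX/famY declared homologous, two pathways with
# famY shared between them
toyRegistry <- function() {
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c(
        "family_id\tannotation\tpathways\thomolog_family_ids",
        "famX\tenzyme X\talpha\tfamY",
        "famY\tenzyme Y\talpha;beta\tfamX",
        "famZ\tenzyme Z\tbeta\t"), tmp)
    loadRegistry(tmp, NA)
}

# registry TSV with a conflicting duplicated fixture row, for error paths
conflictingFixture <- function() {
    reg <- tempfile(fileext = ".tsv")
    writeLines(c(
        "family_id\tannotation\tpathways",
        "famX\tenzyme X\talpha;beta"), reg)
    fix <- tempfile(fileext = ".tsv")
    writeLines(c(
        paste("pathway_id", "family_id", "core_count", "full_count",
              "arCOG", "COG", "eggNOG", "KEGG", sep = "\t"),
        "alpha\tfamX\t10\t20\t1\t1\t1\t1",
        "beta\tfamX\t11\t20\t1\t1\t1\t1"), fix)
    list(registry = reg, fixture = fix)
}

# small hand-built full-tier database: two families (2 seqs each, planted
# lineages) and one decoy group, from a fixed seed
toyFullDb <- function(seed = 101) {
    set.seed(seed)
    ancX <- randomProtein(150)
    ancZ <- randomProtein(150)
    seqs <- c(famX_1 = ancX, famX_2 = mutateK(ancX, 8),
              famZ_1 = ancZ, famZ_2 = mutateK(ancZ, 8),
              dec_1 = mutateK(ancX, 75), dec_2 = mutateK(ancX, 70))
    info <- data.frame(
        seq_id = names(seqs),
        kind = c("target", "target", "target", "target", "decoy", "decoy"),
        label = c("famX", "famX", "famZ", "famZ", "grpA", "grpA"),
        source_db = NA_character_,
        taxonomy = c(rep("Bacteria;Proteobacteria;c1;o1;f1;g1;s1", 2),
                     rep("Bacteria;Firmicutes;c2;o2;f2;g2;s2", 2),
                     NA, NA),
        duplicates = NA_character_, stringsAsFactors = FALSE)
    FamPath:::.newRefDb(Biostrings::AAStringSet(seqs), info, "full")
}

# strip decoys out of a full db, yielding the matching core db
coreOf <- function(fullDb) {
    info <- refInfo(fullDb)
    keep <- info$kind == "target"
    FamPath:::.newRefDb(fullDb@sequences[keep], info[keep, ], "core")
}
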