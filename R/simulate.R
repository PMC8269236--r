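## Seeded synthetic data: reference families with controlled member
## identities, homolog decoys derived from the family ancestors (so they
## genuinely attract hits), unrelated background proteins, full-length
## evaluation query sets, and fragmented reads with provenance.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
           "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.PHYLA <- c("Proteobacteria", "Firmicutes", "Actinobacteria",
            "Bacteroidetes", "Cyanobacteria")

## evaluate expr with the RNG seeded, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Create a simulation configuration
#'
#' Defaults describe a desk-scale study: 10 families of 8 members mutated to
#' 0.90-0.99 identity to their family ancestor, 10 homolog-decoy groups
#' derived from the same ancestors at 0.40-0.60 identity (so decoys attract
#' hits, reproducing the small-database mechanism, while staying separable
#' from true members), 20 unrelated background proteins, and fragment reads
#' of 40-70 residues.
#'
#' @param seed RNG seed; all generator output is deterministic given it.
#' @param nFamilies,membersPerFamily family structure.
#' @param lengthRange protein length range (residues).
#' @param memberIdentity member-to-ancestor identity range.
#' @param decoyIdentity decoy-to-ancestor identity range; must lie below the
#'   member range (a warning is issued otherwise).
#' @param nDecoyGroups,decoysPerGroup decoy structure.
#' @param nUnrelated unrelated sequences drawn i.i.d. from the background.
#' @param readLength read length range (residues) for fragmentation.
#' @param readsPerSample reads per simulated sample.
#' @param proportions optional named community proportions per family for
#'   \code{\link{fragmentReads}} (default: uniform over families).
#' @param nPathways synthetic pathways the families are split across.
#' @param background residue sampling weights over the standard 20 amino
#'   acids (default uniform).
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, nFamilies = 10L,
                             membersPerFamily = 8L,
                             lengthRange = c(180L, 240L),
                             memberIdentity = c(0.90, 0.99),
                             decoyIdentity = c(0.40, 0.60),
                             nDecoyGroups = 10L, decoysPerGroup = 3L,
                             nUnrelated = 20L, readLength = c(40L, 70L),
                             readsPerSample = 1000L, proportions = NULL,
                             nPathways = 2L, background = NULL) {
    chkRange <- function(r, nm) {
        if (length(r) != 2L || any(r <= 0) || any(r > 1) || r[1] > r[2])
            stop(nm, " must be an increasing range within (0, 1]")
    }
    chkRange(memberIdentity, "memberIdentity")
    chkRange(decoyIdentity, "decoyIdentity")
    if (memberIdentity[1] <= decoyIdentity[2])
        warning("member identity range overlaps decoy range; ",
                "separability properties are not guaranteed")
    if (memberIdentity[2] < 1 &&
        round((1 - memberIdentity[2]) * lengthRange[1]) < 1)
        stop("member identity ", memberIdentity[2],
             " is not resolvable by point substitution at length ",
             lengthRange[1])
    if (is.null(background)) background <- rep(1 / 20, 20L)
    if (length(background) != 20L || any(background < 0))
        stop("background must be 20 non-negative weights")
    structure(list(seed = as.integer(seed), nFamilies = as.integer(nFamilies),
                   membersPerFamily = as.integer(membersPerFamily),
                   lengthRange = as.integer(lengthRange),
                   memberIdentity = memberIdentity,
                   decoyIdentity = decoyIdentity,
                   nDecoyGroups = as.integer(nDecoyGroups),
                   decoysPerGroup = as.integer(decoysPerGroup),
                   nUnrelated = as.integer(nUnrelated),
                   readLength = as.integer(readLength),
                   readsPerSample = as.integer(readsPerSample),
                   proportions = proportions,
                   nPathways = as.integer(nPathways),
                   background = background / sum(background)),
              class = "SimulationConfig")
}

.randomProtein <- function(len, background) {
    paste(sample(.AA20, len, replace = TRUE, prob = background),
          collapse = "")
}

## substitute exactly round((1 - identity) * L) positions, never to the
## original residue, so the realized identity to the source is controlled
.mutateTo <- function(seq, identity, background) {
    ch <- strsplit(seq, "")[[1]]
    k <- round((1 - identity) * length(ch))
    if (k == 0L) return(seq)
    pos <- sample(length(ch), k)
    for (p in pos) {
        alt <- setdiff(.AA20, ch[p])
        ch[p] <- sample(alt, 1L,
                        prob = background[match(alt, .AA20)])
    }
    paste(ch, collapse = "")
}

.lineageFor <- function(i, what = "Fam") {
    phylum <- .PHYLA[((i - 1L) %% length(.PHYLA)) + 1L]
    paste("Bacteria", phylum, paste0("Class_", what, i),
          paste0("Order_", what, i), paste0("Family_", what, i),
          paste0("Genus_", what, i),
          paste0("Genus_", what, i, " species_", i), sep = ";")
}

#' Simulate a full reference database with ground truth
#'
#' Per family, one random ancestor is drawn and members are produced by
#' point substitution down to a sampled member identity. Decoy groups derive
#' from the family ancestors at the (lower) decoy identity, unrelated
#' proteins are i.i.d. background draws, and every family carries a planted
#' 7-rank lineage shared by its members. Output is deterministic given the
#' config seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{db} (full-tier
#'   \code{\linkS4class{ReferenceDatabase}} of targets + decoys),
#'   \code{registry} (synthetic \code{\linkS4class{FamilyRegistry}}),
#'   \code{unrelated} (named character vector), \code{truth} (data.frame:
#'   \code{seq_id}, \code{class} target/decoy/unrelated, \code{label},
#'   \code{source_seq_id}, \code{identity_to_source}), \code{config}.
#' @export
simulateReferenceSet <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed, {
        famIds <- sprintf("fam%02d", seq_len(config$nFamilies))
        ancestors <- setNames(vapply(famIds, function(f)
            .randomProtein(sample(config$lengthRange[1]:
                                  config$lengthRange[2], 1L),
                           config$background), ""), famIds)
        seqs <- character(); info <- list(); truth <- list()
        for (i in seq_along(famIds)) {
            f <- famIds[i]
            base <- .lineageFor(i)
            for (m in seq_len(config$membersPerFamily)) {
                ## members share the family lineage down to genus but carry
                ## distinct species, so taxonomic profiles can vary across
                ## replicates while family proportions stay fixed
                parts <- strsplit(base, ";", fixed = TRUE)[[1]]
                parts[7] <- paste0(parts[6], " species_", i, "_", m)
                lin <- paste(parts, collapse = ";")
                id <- runif(1L, config$memberIdentity[1],
                            config$memberIdentity[2])
                sid <- sprintf("%s_m%02d", f, m)
                seqs[sid] <- .mutateTo(ancestors[[f]], id,
                                       config$background)
                info[[sid]] <- data.frame(
                    seq_id = sid, kind = "target", label = f,
                    source_db = "simulated", taxonomy = lin,
                    duplicates = NA_character_, stringsAsFactors = FALSE)
                truth[[sid]] <- data.frame(
                    seq_id = sid, class = "target", label = f,
                    source_seq_id = paste0(f, "_ancestor"),
                    identity_to_source = id, stringsAsFactors = FALSE)
            }
        }
        for (g in seq_len(config$nDecoyGroups)) {
            gid <- sprintf("decoy%02d", g)
            srcFam <- famIds[((g - 1L) %% length(famIds)) + 1L]
            lin <- .lineageFor(g, "Homolog")
            for (m in seq_len(config$decoysPerGroup)) {
                id <- runif(1L, config$decoyIdentity[1],
                            config$decoyIdentity[2])
                sid <- sprintf("%s_m%02d", gid, m)
                seqs[sid] <- .mutateTo(ancestors[[srcFam]], id,
                                       config$background)
                info[[sid]] <- data.frame(
                    seq_id = sid, kind = "decoy", label = gid,
                    source_db = "simulated", taxonomy = lin,
                    duplicates = NA_character_, stringsAsFactors = FALSE)
                truth[[sid]] <- data.frame(
                    seq_id = sid, class = "decoy", label = gid,
                    source_seq_id = paste0(srcFam, "_ancestor"),
                    identity_to_source = id, stringsAsFactors = FALSE)
            }
        }
        unrelated <- character()
        for (u in seq_len(config$nUnrelated)) {
            sid <- sprintf("unrel%03d", u)
            unrelated[sid] <- .randomProtein(
                sample(config$lengthRange[1]:config$lengthRange[2], 1L),
                config$background)
            truth[[sid]] <- data.frame(
                seq_id = sid, class = "unrelated", label = NA_character_,
                source_seq_id = NA_character_,
                identity_to_source = NA_real_, stringsAsFactors = FALSE)
        }
        db <- .newRefDb(AAStringSet(seqs), do.call(rbind, info), "full")
        pwy <- sprintf("pwy%d", seq_len(config$nPathways))
        fam <- data.frame(family_id = famIds,
                          annotation = paste("simulated family", famIds),
                          stringsAsFactors = FALSE)
        pathways <- split(famIds,
                          pwy[((seq_along(famIds) - 1L) %%
                               config$nPathways) + 1L])
        registry <- new("FamilyRegistry", families = fam,
                        pathways = pathways[pwy[pwy %in% names(pathways)]],
                        homologs = list(), counts = data.frame())
        list(db = db, registry = registry, unrelated = unrelated,
             truth = do.call(rbind, unname(truth)), config = config)
    })
}

#' Generate an artificial evaluation query set
#'
#' Draws full-length query proteins in the published evaluation design:
#' a fixed count of target-derived queries (mutated copies of target
#' members), homolog-derived queries (mutated copies of decoy members), and
#' unrelated background proteins, with truth labels attached. The default
#' composition is 143 / 57 / 70 (270 queries).
#'
#' @param sim result of \code{\link{simulateReferenceSet}}.
#' @param counts integer triple: target-derived, decoy-derived, unrelated.
#' @param identity identity range for the mutated copies relative to their
#'   source record (default: the member identity range of the simulation).
#' @param seed RNG seed (default: simulation seed + 1).
#' @return list: \code{queries} (named character vector), \code{truth}
#'   (data.frame: \code{query_id}, \code{class}, \code{true_family},
#'   \code{source_seq_id}).
#' @export
makeArtificialEvalSet <- function(sim, counts = c(143L, 57L, 70L),
                                  identity = NULL, seed = NULL) {
    if (length(counts) != 3L || any(counts < 0))
        stop("counts must be three non-negative integers")
    config <- sim$config
    if (is.null(identity)) identity <- config$memberIdentity
    if (is.null(seed)) seed <- config$seed + 1L
    info <- sim$db@seqInfo
    targets <- info$seq_id[info$kind == "target"]
    decoys <- info$seq_id[info$kind == "decoy"]
    if (counts[1] > 0 && !length(targets))
        stop("no target members available to draw from")
    if (counts[2] > 0 && !length(decoys))
        stop("no decoy members available to draw from")
    .withSeed(seed, {
        queries <- character(); truth <- list()
        draw <- function(pool, n) pool[sample.int(length(pool), n,
                                                  replace = TRUE)]
        src <- draw(targets, counts[1])
        for (i in seq_len(counts[1])) {
            qid <- sprintf("q_target_%03d", i)
            id <- runif(1L, identity[1], identity[2])
            queries[qid] <- .mutateTo(
                as.character(sim$db@sequences[[src[i]]]), id,
                config$background)
            truth[[qid]] <- data.frame(
                query_id = qid, class = "target",
                true_family = info$label[match(src[i], info$seq_id)],
                source_seq_id = src[i], stringsAsFactors = FALSE)
        }
        src <- draw(decoys, counts[2])
        for (i in seq_len(counts[2])) {
            qid <- sprintf("q_decoy_%03d", i)
            id <- runif(1L, identity[1], identity[2])
            queries[qid] <- .mutateTo(
                as.character(sim$db@sequences[[src[i]]]), id,
                config$background)
            truth[[qid]] <- data.frame(
                query_id = qid, class = "decoy", true_family = NA_character_,
                source_seq_id = src[i], stringsAsFactors = FALSE)
        }
        for (i in seq_len(counts[3])) {
            qid <- sprintf("q_unrel_%03d", i)
            queries[qid] <- .randomProtein(
                sample(config$lengthRange[1]:config$lengthRange[2], 1L),
                config$background)
            truth[[qid]] <- data.frame(
                query_id = qid, class = "unrelated",
                true_family = NA_character_, source_seq_id = NA_character_,
                stringsAsFactors = FALSE)
        }
        list(queries = queries, truth = do.call(rbind, unname(truth)))
    })
}

#' Fragment reference sequences into reads
#'
#' Samples reads by community proportion over families (and, if named in the
#' proportions, decoy groups), with uniform start positions and lengths in
#' the configured range; reads longer than their source are clipped with a
#' warning. Optionally reverse-translates the peptide reads to nucleotides
#' by uniform codon choice for translated-search testing. Provenance is
#' recorded per read.
#'
#' @param sim result of \code{\link{simulateReferenceSet}} (or a list with
#'   \code{db} and \code{config}).
#' @param proportions named proportions over family/group labels present in
#'   the database; must sum to 1. Default: the config proportions, else
#'   uniform over families.
#' @param n number of reads (default: config \code{readsPerSample}).
#' @param nucleotide reverse-translate reads to DNA (default FALSE).
#' @param seed RNG seed (default: simulation seed + 2).
#' @return list: \code{reads} (named character vector), \code{provenance}
#'   (data.frame: \code{read_id}, \code{source_seq_id}, \code{kind},
#'   \code{label}, \code{start}, \code{length}).
#' @export
fragmentReads <- function(sim, proportions = NULL, n = NULL,
                          nucleotide = FALSE, seed = NULL) {
    db <- sim$db
    config <- sim$config
    info <- db@seqInfo
    if (is.null(n)) n <- config$readsPerSample
    if (is.null(proportions)) proportions <- config$proportions
    if (is.null(proportions)) {
        fams <- unique(info$label[info$kind == "target"])
        proportions <- setNames(rep(1 / length(fams), length(fams)), fams)
    }
    if (abs(sum(proportions) - 1) > 1e-8)
        stop("proportions must sum to 1")
    unknown <- setdiff(names(proportions), info$label)
    if (length(unknown))
        stop("proportions name labels absent from the database: ",
             paste(unknown, collapse = ", "))
    if (is.null(seed)) seed <- config$seed + 2L
    codonsOf <- NULL
    if (nucleotide) {
        gc <- Biostrings::GENETIC_CODE
        codonsOf <- split(names(gc), unname(gc))
    }
    .withSeed(seed, {
        labels <- sample(names(proportions), n, replace = TRUE,
                         prob = proportions)
        reads <- character(n); prov <- vector("list", n)
        clipped <- 0L
        for (i in seq_len(n)) {
            pool <- info$seq_id[info$label == labels[i]]
            sid <- pool[sample.int(length(pool), 1L)]
            src <- as.character(db@sequences[[sid]])
            len <- sample(config$readLength[1]:config$readLength[2], 1L)
            if (len > nchar(src)) { len <- nchar(src); clipped <- clipped + 1L }
            start <- sample.int(nchar(src) - len + 1L, 1L)
            pep <- substr(src, start, start + len - 1L)
            rid <- sprintf("read%06d", i)
            if (nucleotide) {
                ch <- strsplit(pep, "")[[1]]
                reads[i] <- paste(vapply(ch, function(a) {
                    cods <- codonsOf[[a]]
                    cods[sample.int(length(cods), 1L)]
                }, ""), collapse = "")
            } else reads[i] <- pep
            names(reads)[i] <- rid
            prov[[i]] <- data.frame(
                read_id = rid, source_seq_id = sid,
                kind = info$kind[match(sid, info$seq_id)],
                label = labels[i], start = start, length = len,
                stringsAsFactors = FALSE)
        }
        if (clipped > 0L)
            warning(clipped, " read(s) clipped to their source length")
        list(reads = reads, provenance = do.call(rbind, prov))
    })
}
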