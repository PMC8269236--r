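test_that("buildSeed stores curated records per family and rejects bad input", {
    reg <- toyRegistry()
    set.seed(201)
    seqs <- c(s1 = randomProtein(100), s2 = randomProtein(100),
              s3 = randomProtein(100), s4 = randomProtein(100),
              s5 = randomProtein(100), s6 = randomProtein(100),
              s7 = randomProtein(100), s8 = randomProtein(100))
    fams <- c("famX", "famX", "famX", "famY", "famY", "famZ", "famZ", "famZ")
    db <- buildSeed(seqs, fams, reg)
    expect_s4_class(db, "ReferenceDatabase")
    expect_equal(dbTier(db), "seed")
    expect_equal(familiesPresent(db), c("famX", "famY", "famZ"))
    expect_equal(as.integer(table(refInfo(db)$label)[c("famX", "famY",
                                                       "famZ")]),
                 c(3L, 2L, 3L))
    expect_error(buildSeed(seqs, rep("ghost", 8), reg), "ghost")
    expect_error(buildSeed(c(seqs, s1 = randomProtein(50)),
                           c(fams, "famX"), reg), "duplicate seq_id")
})

test_that("simulated 60-family seed matches its registry bookkeeping", {
    cfg <- simulationConfig(seed = 202, nFamilies = 60, membersPerFamily = 1,
                            nDecoyGroups = 0, nUnrelated = 0,
                            lengthRange = c(60L, 80L))
    sim <- simulateReferenceSet(cfg)
    expect_length(familiesPresent(sim$db), 60L)
    expect_length(familyIds(sim$registry), 60L)
})

test_that("recruitment assigns by best hit, applies the cutoff, and reports", {
    reg <- toyRegistry()
    set.seed(203)
    ancX <- randomProtein(120)
    ancZ <- randomProtein(120)
    seedDb <- buildSeed(c(sX1 = ancX, sX2 = mutateK(ancX, 6),
                          sZ1 = ancZ),
                        c("famX", "famX", "famZ"), reg)
    cand <- c(nearX = mutateK(ancX, 6),     # ~95% to a famX seed
              noise = randomProtein(120),   # ~<25% anywhere
              nearZ = mutateK(ancZ, 12))
    res <- recruitCore(cand, c("famX", "famX", "famZ"), seedDb, reg)
    rep <- res$report
    expect_equal(rep$decision,
                 c("recruited", "rejected", "recruited"))
    expect_equal(rep$family_id[1], "famX")
    expect_equal(rep$family_id[3], "famZ")
    expect_match(rep$reason[2], "below cutoff")
    # partition: recruited + rejected = input count
    expect_equal(sum(rep$decision == "recruited") +
                 sum(rep$decision == "rejected"), length(cand))
    # tier monotonicity: all seed ids survive into the core
    expect_true(all(refInfo(seedDb)$seq_id %in% refInfo(res$db)$seq_id))
    expect_equal(dbTier(res$db), "core")
})

test_that("score ties across families resolve by seed majority", {
    reg <- toyRegistry()
    set.seed(204)
    shared <- randomProtein(100)
    other <- randomProtein(100)
    # the identical sequence sits twice in famX, once in famY (homologs),
    # so a candidate equal to it ties across all three seeds
    seedDb <- buildSeed(c(x1 = shared, x2 = shared, y1 = shared,
                          z1 = other),
                        c("famX", "famX", "famY", "famZ"), reg)
    res <- recruitCore(c(cand = shared), "famY", seedDb, reg)
    expect_equal(res$report$decision, "recruited")
    expect_equal(res$report$family_id, "famX")  # 2 of 3 tied seeds
})

test_that("recruitment recovers planted truth when tiers are separable", {
    cfg <- simulationConfig(seed = 205, nFamilies = 3, membersPerFamily = 2,
                            nDecoyGroups = 0, nUnrelated = 0)
    sim <- simulateReferenceSet(cfg)
    info <- refInfo(sim$db)
    seedDb <- FamPath:::.newRefDb(sim$db@sequences, info, "seed")
    set.seed(205)
    # candidates: light mutations of known members
    src <- sample(info$seq_id, 6, replace = TRUE)
    cand <- setNames(vapply(src, function(s)
        mutateK(as.character(sim$db@sequences[[s]]), 5), ""),
        paste0("c", seq_along(src)))
    truthFam <- info$label[match(src, info$seq_id)]
    res <- recruitCore(cand, truthFam, seedDb, sim$registry)
    expect_true(all(res$report$decision == "recruited"))
    expect_equal(res$report$family_id, truthFam)
})

test_that("homolog groups merge, become decoys, or drop by planted fraction", {
    reg <- toyRegistry()
    set.seed(206)
    anc <- randomProtein(150)
    core <- buildSeed(c(t1 = anc, t2 = mutateK(anc, 7)),
                      c("famX", "famX"), reg)
    core@tier <- "core"
    mkMember <- function(hit) if (hit) mutateK(anc, 60) else randomProtein(150)
    fractions <- c(g0 = 0, g2 = 0.2, g6 = 0.6, g10 = 1.0)
    groups <- list(); seqs <- character()
    for (g in names(fractions)) {
        hits <- round(fractions[[g]] * 10)
        ids <- sprintf("%s_m%02d", g, 1:10)
        groups[[g]] <- data.frame(group_id = g, source_db = "COG",
                                  seq_id = ids)
        for (k in 1:10) seqs[ids[k]] <- mkMember(k <= hits)
    }
    res <- attachHomologGroups(core, do.call(rbind, groups), seqs)
    decisions <- setNames(res$report$decision, res$report$group_id)
    expect_equal(unname(decisions[c("g0", "g2", "g6", "g10")]),
                 c("dropped", "decoy", "merged", "merged"))
    expect_equal(dbTier(res$db), "full")
    # merged members are targets of famX; decoy members keep their group id
    info <- refInfo(res$db)
    expect_true(all(info$label[grepl("^g6_", info$seq_id)] == "famX"))
    expect_true(all(info$kind[grepl("^g2_", info$seq_id)] == "decoy"))
    expect_false(any(grepl("^g0_", info$seq_id)))
})

test_that("genome proteins route to targets or decoys by best hit", {
    db <- toyFullDb()
    set.seed(207)
    pX <- mutateK(as.character(db@sequences[["famX_1"]]), 3)
    pD <- mutateK(as.character(db@sequences[["dec_1"]]), 3)
    pN <- randomProtein(150)
    res <- mergeRefseqLike(db, c(pX = pX, pD = pD, pN = pN),
                           taxonomy = c("Bacteria;Proteobacteria;c;o;f;g;s",
                                        NA, NA))
    rep <- res$report
    expect_equal(rep$decision, c("routed", "routed", "discarded"))
    expect_equal(rep$kind[1:2], c("target", "decoy"))
    expect_equal(rep$label[1:2], c("famX", "grpA"))
    info <- refInfo(res$db)
    expect_equal(info$taxonomy[info$seq_id == "pX"],
                 "Bacteria;Proteobacteria;c;o;f;g;s")
    # routing matches planted labels on separable simulator output
    cfg <- simulationConfig(seed = 207, nFamilies = 3, membersPerFamily = 3,
                            nDecoyGroups = 2, nUnrelated = 0)
    sim <- simulateReferenceSet(cfg)
    sinfo <- refInfo(sim$db)
    picks <- c(sample(which(sinfo$kind == "target"), 3),
               sample(which(sinfo$kind == "decoy"), 2))
    prot <- setNames(vapply(picks, function(i)
        mutateK(as.character(sim$db@sequences[[i]]), 4), ""),
        paste0("p", seq_along(picks)))
    res2 <- mergeRefseqLike(sim$db, prot)
    expect_equal(res2$report$kind, sinfo$kind[picks])
    expect_equal(res2$report$label, sinfo$label[picks])
})

test_that("exact dedup collapses within labels, flags across, idempotent", {
    set.seed(208)
    s <- randomProtein(80)
    seqs <- c(a1 = s, a2 = s, a3 = s, b1 = randomProtein(80), x1 = s)
    info <- data.frame(seq_id = names(seqs), kind = "target",
                       label = c("famA", "famA", "famA", "famA", "famB"),
                       source_db = NA, taxonomy = NA, duplicates = NA,
                       stringsAsFactors = FALSE)
    db <- FamPath:::.newRefDb(Biostrings::AAStringSet(seqs), info, "core")
    res <- dedupExact(db)
    kept <- refInfo(res$db)
    # 3-fold duplicate within famA collapses to 2 removals; famB copy stays
    expect_equal(nrow(kept), 3L)
    expect_equal(kept$seq_id, c("a1", "b1", "x1"))
    expect_equal(kept$duplicates[kept$seq_id == "a1"], "a2;a3")
    within <- res$report[!res$report$cross_label, ]
    expect_equal(sort(within$duplicate), c("a2", "a3"))
    expect_true(any(res$report$cross_label &
                    res$report$duplicate == "x1"))
    # idempotence
    again <- dedupExact(res$db)
    expect_equal(nrow(again$report[!again$report$cross_label, ]), 0L)
    expect_equal(refInfo(again$db)$seq_id, kept$seq_id)
    # size reduction is exactly sum(k - 1) over planted k-fold duplicates
    expect_equal(nrow(info) - nrow(kept), 2L)
    # all-unique database passes through unchanged
    db2 <- toyFullDb()
    res2 <- dedupExact(db2)
    expect_equal(refInfo(res2$db)$seq_id, refInfo(db2)$seq_id)
})

test_that("tiers stay monotone through a full build", {
    reg <- toyRegistry()
    set.seed(209)
    ancX <- randomProtein(130); ancZ <- randomProtein(130)
    seedDb <- buildSeed(c(sX = ancX, sZ = ancZ), c("famX", "famZ"), reg)
    core <- recruitCore(c(c1 = mutateK(ancX, 10), c2 = mutateK(ancZ, 12)),
                        c("famX", "famZ"), seedDb, reg)$db
    groups <- data.frame(group_id = "h1", source_db = "KEGG",
                         seq_id = c("h1a", "h1b"))
    gseq <- c(h1a = mutateK(ancX, 70), h1b = mutateK(ancX, 72))
    full <- attachHomologGroups(core, groups, gseq)$db
    seedIds <- refInfo(seedDb)$seq_id
    coreIds <- refInfo(core)$seq_id[refInfo(core)$kind == "target"]
    fullIds <- refInfo(full)$seq_id[refInfo(full)$kind == "target"]
    expect_true(all(seedIds %in% coreIds))
    expect_true(all(coreIds %in% fullIds))
})
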