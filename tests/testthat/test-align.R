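test_that("global alignment handles identity, substitution, and errors", {
    a <- alignGlobal("MKV", "MKV")
    expect_equal(a$identity, 1)
    expect_equal(a$nColumns, 3L)
    b <- alignGlobal("MKV", "MQV")
    expect_equal(b$identity, 2 / 3)
    # end gaps enter the identity denominator
    d <- alignGlobal("MKV", "MKVAA")
    expect_equal(d$nColumns, 5L)
    expect_equal(d$identity, 3 / 5)
    expect_error(alignGlobal("", "MKV"), "non-empty")
    expect_error(alignGlobal("MKJV", "MKV"), "position 3")
})

test_that("local alignment reports span identity, coverage, and empties", {
    l <- alignLocal("KVL", "XXMKVLQQ")
    expect_equal(l$identity, 1)
    expect_equal(l$coverage, 1)
    # no positive-scoring residue pair: empty alignment, score 0
    e <- alignLocal("WWW", "PPP")
    expect_equal(e$score, 0)
    expect_equal(e$nColumns, 0L)
})

test_that("alignment scores equal independent dynamic-programming oracles", {
    sch <- scoringScheme()
    set.seed(401)
    for (trial in 1:60) {
        a <- randomProtein(sample(1:8, 1))
        b <- randomProtein(sample(1:8, 1))
        expect_equal(alignGlobal(a, b, sch)$score,
                     oracleGlobalScore(a, b, blosum62),
                     info = paste("global", a, b))
        expect_equal(alignLocal(a, b, sch)$score,
                     oracleLocalScore(a, b, blosum62),
                     info = paste("local", a, b))
    }
})

test_that("the DP oracles themselves match true path enumeration (tiny n)", {
    set.seed(402)
    for (trial in 1:10) {
        a <- randomProtein(sample(1:3, 1))
        b <- randomProtein(sample(1:3, 1))
        expect_equal(oracleGlobalScore(a, b, blosum62),
                     oracleEnumGlobalScore(a, b, blosum62),
                     info = paste("enum global", a, b))
        expect_equal(oracleLocalScore(a, b, blosum62),
                     oracleEnumLocalScore(a, b, blosum62),
                     info = paste("enum local", a, b))
    }
})

test_that("global score and identity are symmetric in their arguments", {
    set.seed(403)
    for (trial in 1:10) {
        a <- randomProtein(sample(3:12, 1))
        b <- randomProtein(sample(3:12, 1))
        f <- alignGlobal(a, b)
        r <- alignGlobal(b, a)
        expect_equal(f$score, r$score)
        expect_equal(f$identity, r$identity)
    }
})

test_that("six-frame translation follows the standard code and strands", {
    fr <- translateSixFrames("ATGAAAGTT")
    expect_equal(fr[["+1"]], "MKV")
    # reverse complement carries the peptide to frame -1
    rc <- translateSixFrames("AACTTTCAT")
    expect_equal(rc[["-1"]], "MKV")
    # N-containing codons become X, stops become *
    expect_equal(translateSixFrames("TAAAAN")[["+1"]], "*X")
    expect_error(translateSixFrames("ATGU"), "position 4")
    # frame lengths obey floor((L - offset) / 3) in all six frames
    set.seed(404)
    for (trial in 1:10) {
        L <- sample(3:40, 1)
        s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
        fr <- translateSixFrames(s)
        for (off in 0:2) {
            expect_equal(nchar(fr[[c("+1", "+2", "+3")[off + 1]]]),
                         (L - off) %/% 3)
            expect_equal(nchar(fr[[c("-1", "-2", "-3")[off + 1]]]),
                         (L - off) %/% 3)
        }
    }
})

test_that("bestHit applies thresholds and matches an exhaustive argmax", {
    db <- toyFullDb()
    info <- refInfo(db)
    sch <- scoringScheme()
    cfgG <- searchConfig(mode = "global")
    # query identical to a reference finds it at identity 1
    h <- bestHit(as.character(db@sequences[["famX_1"]]), db, cfgG)
    expect_equal(h$ref_id, "famX_1")
    expect_equal(h$identity, 1)
    expect_equal(h$kind, "target")
    # identity below the cutoff yields no hit even when the score passes
    set.seed(405)
    far <- mutateK(as.character(db@sequences[["famX_1"]]), 115)  # ~23% id
    strict <- searchConfig(mode = "global", minIdentity = 0.30)
    loose <- searchConfig(mode = "global", minIdentity = 0)
    hLoose <- bestHit(far, db, loose)
    if (!is.null(hLoose) && hLoose$identity < 0.30)
        expect_null(bestHit(far, db, strict))
    # exhaustive oracle over per-reference global scores with tie-breaks
    set.seed(406)
    for (trial in 1:8) {
        q <- mutateK(as.character(db@sequences[[sample(6, 1)]]),
                     sample(0:20, 1))
        h <- bestHit(q, db, cfgG, sch)
        scores <- vapply(seq_along(db@sequences), function(j)
            oracleGlobalScore(q, as.character(db@sequences[[j]]),
                              blosum62), numeric(1))
        names(scores) <- names(db@sequences)
        idents <- vapply(names(scores), function(r)
            alignGlobal(q, as.character(db@sequences[[r]]), sch)$identity,
            numeric(1))
        pass <- scores >= 0 & idents >= 0.30
        if (!any(pass)) {
            expect_null(h)
        } else {
            top <- max(scores[pass])
            cands <- names(scores)[pass & scores == top]
            cands <- cands[order(-idents[cands], cands)]
            expect_equal(h$ref_id, cands[1])
            expect_equal(h$score, top)
        }
    }
})

test_that("bestHit is deterministic under database permutation", {
    db <- toyFullDb()
    set.seed(407)
    q <- mutateK(as.character(db@sequences[["famZ_2"]]), 10)
    h1 <- bestHit(q, db, searchConfig(mode = "global"))
    perm <- sample(length(db@sequences))
    db2 <- FamPath:::.newRefDb(db@sequences[perm],
                               refInfo(db)[perm, ], "full")
    h2 <- bestHit(q, db2, searchConfig(mode = "global"))
    expect_identical(h1, h2)
})

test_that("members outscore decoys whenever identity tiers are separable", {
    set.seed(408)
    cfg <- simulationConfig(seed = 408, nFamilies = 4, membersPerFamily = 3,
                            nDecoyGroups = 3, nUnrelated = 0)
    sim <- simulateReferenceSet(cfg)
    info <- refInfo(sim$db)
    cfgG <- searchConfig(mode = "global")
    members <- info$seq_id[info$kind == "target"]
    for (m in sample(members, 5)) {
        h <- bestHit(as.character(sim$db@sequences[[m]]), sim$db, cfgG)
        expect_equal(h$kind, "target")
        expect_equal(h$label, info$label[match(m, info$seq_id)])
    }
})

test_that("hit tables parse, reject malformed lines, and round-trip", {
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c(
        "q1\tr1\t97.5\t100\t2\t0\t1\t100\t1\t100\t1e-50\t180",
        "q2\tr2\t45.0\t80\t40\t2\t1\t80\t5\t84\t1e-09\t60",
        "q3\tr1\t31.2\t64\t40\t1\t1\t64\t1\t60\t2e-05\t41"), tmp)
    hits <- readHitTable(tmp)
    expect_equal(nrow(hits), 3L)
    expect_equal(hits$identity, c(0.975, 0.45, 0.312))
    expect_equal(hits$score, c(180, 60, 41))
    bad <- tempfile(fileext = ".tsv")
    writeLines(c("q1\tr1\t97.5", "only\tthree\tcols"), bad)
    expect_error(readHitTable(bad), "line 1")
    empty <- tempfile(fileext = ".tsv")
    file.create(empty)
    expect_equal(nrow(readHitTable(empty)), 0L)
})

test_that("external hits and built-in search agree downstream", {
    db <- toyFullDb()
    set.seed(409)
    reads <- c(r1 = substr(as.character(db@sequences[["famX_1"]]), 10, 69),
               r2 = substr(as.character(db@sequences[["famZ_1"]]), 20, 79),
               r3 = substr(as.character(db@sequences[["dec_1"]]), 30, 89),
               r4 = randomProtein(60))
    builtin <- assignReads(reads, db, searchConfig(mode = "local"))
    # adapter stub: emit the built-in results as a hit table
    hit <- builtin[builtin$status != "unassigned", ]
    stub <- data.frame(query_id = hit$read_id, ref_id = hit$ref_id,
                       score = hit$score, identity = hit$identity,
                       stringsAsFactors = FALSE)
    viaStub <- assignmentsFromHits(stub, names(reads), db)
    expect_equal(viaStub$status, builtin$status)
    expect_equal(viaStub$family_id, builtin$family_id)
    expect_equal(viaStub$ref_id, builtin$ref_id)
})

test_that("the BLAST+ adapter honors the best-hit contract", {
    db <- toyFullDb()
    qf <- tempfile(fileext = ".fasta")
    dbf <- tempfile(fileext = ".fasta")
    set.seed(410)
    queries <- c(qx = as.character(db@sequences[["famX_2"]]),
                 qz = as.character(db@sequences[["famZ_1"]]),
                 qr = randomProtein(120))
    writeLines(paste0(">", names(queries), "\n", queries), qf)
    writeReferenceFasta(db, dbf)
    hits <- externalSearchAdapter(qf, dbf, searchConfig())
    expect_lte(nrow(hits), 3L)
    expect_false(anyDuplicated(hits$query_id) > 0)
    expect_true(all(hits$evalue <= 1e-4))
    expect_true(all(hits$identity >= 0.30))
    expect_equal(hits$ref_id[hits$query_id == "qx"], "famX_2")
    # empty query file gives an empty hit list
    emptyq <- tempfile(fileext = ".fasta")
    file.create(emptyq)
    expect_equal(nrow(externalSearchAdapter(emptyq, dbf, searchConfig())),
                 0L)
    expect_error(externalSearchAdapter(qf, dbf, engine = "no_such_engine"),
                 "not available")
})
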