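b62 <- loadSubstitutionMatrix("BLOSUM62")
bgStd <- standardProteinBackground()

test_that("the two-hit filter groups matches by reference and diagonal", {
    m <- data.frame(queryPos = c(0L, 5L, 3L, 7L),
                    refId = c(1L, 1L, 1L, 2L),
                    refPos = c(1L, 6L, 10L, 8L))
    # two matches on diagonal +1 of ref 1 survive; the others are isolated
    f <- doubleHitFilter(m, minHits = 2)
    expect_identical(nrow(f), 1L)
    expect_identical(f$refId, 1L)
    expect_identical(f$diagonal, 1L)
    expect_identical(f$queryPos, 0L)       # representative = lowest queryPos
    expect_identical(f$nHits, 2L)

    # minHits = 1 keeps every diagonal group
    f1 <- doubleHitFilter(m, minHits = 1)
    expect_identical(nrow(f1), 3L)

    expect_identical(nrow(doubleHitFilter(m[0, ], 2)), 0L)
})

test_that("two k-mer matches on one diagonal arise from a shared 3-mer pair", {
    nt <- nucleotideAlphabet()
    tab <- buildKmerTable(list(r0 = encodeSequence("TACGT", nt)), k = 2)
    m <- matchKmers(tab, encodeSequence("ACG", nt))
    expect_identical(m$queryPos, c(0L, 1L))
    expect_identical(m$refPos, c(1L, 2L))
    f <- doubleHitFilter(m, minHits = 2)
    expect_identical(f$diagonal, 1L)
    expect_identical(f$nHits, 2L)
})

test_that("a database containing the query yields a perfect rank-1 hit", {
    db <- setNames(lapply(1:15, function(i)
        randomSequence(proteinAlphabet(), 150, bgStd, seed = 100 + i)),
        paste0("r", 1:15))
    query <- db[["r7"]]
    cfg <- searchConfig(evalueSamples = 200)
    hits <- runSearch(query, db, b62, cfg)
    expect_identical(hits$refName[1], "r7")
    expect_identical(hits$rank[1], 1L)
    expect_equal(hits$identityPct[1], 100.0)
    expect_equal(hits$coveragePct[1], 100.0)
    expect_true(all(diff(hits$evalue) >= 0))

    # max_evalue = 0 empties the result
    cfg0 <- searchConfig(evalueSamples = 200, maxEvalue = 0)
    expect_identical(nrow(runSearch(query, db, b62, cfg0)), 0L)

    expect_error(runSearch(encodeSequence("", proteinAlphabet()), db, b62,
                           cfg), "empty")
})

test_that("a planted 85%-identity homolog is found at rank 1", {
    query <- randomSequence(proteinAlphabet(), 200, bgStd, seed = 4242)
    est <- evalueEstimator(b62, -11, -1, bgStd, lenQ = 200, lenDb = 200,
                           nSamples = 300, seed = 1)
    for (seed in 1:3) {
        db <- setNames(lapply(1:60, function(i)
            randomSequence(proteinAlphabet(), 200, bgStd,
                           seed = seed * 1000 + i)), paste0("r", 1:60))
        db[["planted"]] <- mutateSequence(query, substitutionRate = 0.15,
                                          background = bgStd,
                                          seed = seed)$sequence
        hits <- runSearch(query, db, b62, searchConfig(), estimator = est)
        expect_identical(hits$refName[1], "planted")
    }
})

test_that("raising any stage threshold never enlarges the hit set", {
    query <- randomSequence(proteinAlphabet(), 150, bgStd, seed = 31)
    db <- setNames(lapply(1:40, function(i)
        randomSequence(proteinAlphabet(), 150, bgStd, seed = 7000 + i)),
        paste0("r", 1:40))
    for (i in 1:5)
        db[[paste0("hom", i)]] <- mutateSequence(
            query, substitutionRate = 0.10 * i, background = bgStd,
            seed = 50 + i)$sequence
    est <- evalueEstimator(b62, -11, -1, bgStd, lenQ = 150, lenDb = 150,
                           nSamples = 300, seed = 1)
    table <- buildKmerTable(db, k = 6)

    hitSet <- function(cfg) {
        h <- runSearch(query, db, b62, cfg, table = table, estimator = est)
        sort(h$refName)
    }
    base <- searchConfig()
    sets <- list(
        minHits = lapply(c(1, 2, 3), function(v)
            hitSet(searchConfig(minHits = v))),
        ungapped = lapply(c(10, 20, 40), function(v)
            hitSet(searchConfig(ungappedThreshold = v))),
        maxE = lapply(c(10, 1e-3, 1e-30), function(v)
            hitSet(searchConfig(maxEvalue = v))))
    for (grid in sets)
        for (g in seq_len(length(grid) - 1))
            expect_true(all(grid[[g + 1]] %in% grid[[g]]))

    # determinism: identical config and seed give byte-identical reports
    h1 <- reportHits(runSearch(query, db, b62, base, table = table))
    h2 <- reportHits(runSearch(query, db, b62, base, table = table))
    expect_identical(h1, h2)
})

test_that("hit reports carry the documented columns and formats", {
    recs <- data.frame(
        header = c("sp|P11111|AAA_HUMAN Alpha OS=Homo sapiens GN=AAA",
                   "sp|P22222|BBB_HUMAN Beta OS=Homo sapiens GN=BBB"),
        sequence = c(paste(rep("MKWVTFISLLLLFSSAYS", 6), collapse = ""),
                     paste(rep("GATTACAMKWVTFISLLL", 6), collapse = "")))
    meta <- parseSwissProtHeader(recs$header)
    db <- setNames(lapply(recs$sequence, encodeSequence,
                          alphabet = proteinAlphabet()), meta$entryName)
    hits <- runSearch(db[[1]], db, b62,
                      searchConfig(evalueSamples = 100, maxEvalue = 1e3),
                      meta = meta)
    rep1 <- reportHits(hits)
    expect_identical(rep1[1], "rank\tgene\taccession\tevalue\tidentity\tcoverage")
    expect_true(all(lengths(strsplit(rep1, "\t")) == 6))
    first <- strsplit(rep1[2], "\t")[[1]]
    expect_identical(first[1:3], c("1", "AAA", "P11111"))
    expect_identical(first[5:6], c("100.0", "100.0"))
    expect_match(first[4], "^[0-9]\\.[0-9]e[+-][0-9]+$")

    # empty hits give a header-only report; file writing round-trips
    empty <- reportHits(hits[0, ])
    expect_identical(empty, rep1[1])
    f <- tempfile()
    reportHits(hits, file = f)
    expect_identical(readLines(f), rep1)
})
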