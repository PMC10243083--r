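test_that("k-mer codes follow d = sum q^i c_i and decode exactly", {
    expect_identical(kmerCode(c(0, 0, 0), 4), 0)
    expect_identical(kmerCode(c(3, 3, 3), 4), 63)           # q^k - 1
    expect_identical(kmerCode(symbolCodes(
        encodeSequence("ACG", nucleotideAlphabet())), 4), 36)
    expect_identical(kmerDecode(36, 3, 4), c(0L, 1L, 2L))
    expect_identical(kmerDecode(0, 3, 4), c(0L, 0L, 0L))
    # exhaustive round-trip over all 3-mers, q = 4
    for (d in 0:63)
        expect_identical(kmerCode(kmerDecode(d, 3, 4), 4), as.numeric(d))
    expect_error(kmerCode(c(0, 4), 4), "\\[0, q\\)")
    expect_error(kmerDecode(64, 3, 4), "out of range")
})

test_that("table construction indexes every unmasked k-mer", {
    nt <- nucleotideAlphabet()
    tab <- buildKmerTable(list(r0 = encodeSequence("ACGT", nt)), k = 2)
    expect_identical(tab@codes, c(4, 9, 14))     # AC, CG, GT
    expect_identical(tab@positions, 0:2)
    expect_identical(kmerCount(tab), 3L)
    expect_identical(kmerLookup(tab, 9)$position, 1L)

    # sequence shorter than the span yields an empty table
    short <- buildKmerTable(list(encodeSequence("AC", nt)), k = 3)
    expect_identical(kmerCount(short), 0L)

    # masking position 1 kills the k-mers at starts 0 and 1
    masked <- buildKmerTable(list(encodeSequence("ACGT", nt)), k = 2,
                             masks = list(c(FALSE, TRUE, FALSE, FALSE)))
    expect_identical(masked@codes, 14)           # only GT survives
    expect_identical(masked@positions, 2L)

    # entry count conservation: sum over sequences of unmasked k-mer counts
    seqs <- lapply(1:5, function(i) randomSeq(nt, 10 + i, seed = 400 + i))
    t5 <- buildKmerTable(seqs, k = 3)
    expect_identical(kmerCount(t5), sum(vapply(seqs, length, 0L) - 3L + 1L))
})

test_that("exact matching equals the quadratic brute-force scan (property)", {
    nt <- nucleotideAlphabet()
    p <- proteinAlphabet()
    cases <- expand.grid(k = c(2L, 3L, 4L), alph = c("nt", "aa"),
                         rep = 1:6, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(cases))) {
        alph <- if (cases$alph[r] == "nt") nt else p
        k <- cases$k[r]
        seed <- 7000 + r
        db <- list(a = randomSeq(alph, 40 + r, seed),
                   b = randomSeq(alph, 60, seed + 1))
        query <- randomSeq(alph, 30, seed + 2)
        tab <- buildKmerTable(db, k = k)
        got <- matchKmers(tab, query)
        want <- bruteKmerMatches(db, query, contiguousPattern(k))
        expect_equal(got, want, ignore_attr = TRUE)
    }
})

test_that("spaced patterns match brute force applying the mask positions", {
    nt <- nucleotideAlphabet()
    pat <- spacedPattern("1101")
    expect_identical(patternK(pat), 3L)
    expect_identical(patternSpan(pat), 4L)
    expect_error(spacedPattern("0110"), "informative")
    for (r in 1:5) {
        db <- list(x = randomSeq(nt, 50, 880 + r))
        query <- randomSeq(nt, 25, 890 + r)
        tab <- buildKmerTable(db, pattern = pat)
        expect_equal(matchKmers(tab, query),
                     bruteKmerMatches(db, query, pat), ignore_attr = TRUE)
    }
})

test_that("thresholded matching enumerates similar k-mers correctly", {
    nt <- nucleotideAlphabet()
    sm <- uniformSubstitutionMatrix(nt, 2, -1)
    for (r in 1:5) {
        db <- list(x = randomSeq(nt, 40, 660 + r),
                   y = randomSeq(nt, 30, 670 + r))
        query <- randomSeq(nt, 20, 680 + r)
        tab <- buildKmerTable(db, k = 3)
        for (thr in c(6, 3, 0)) {
            expect_equal(matchKmers(tab, query, sm, thr),
                         bruteKmerMatches(db, query, contiguousPattern(3),
                                          scoreMatrix(sm), thr),
                         ignore_attr = TRUE)
        }
    }
    # threshold at the per-position maximum row sums = exact matching
    # (diagonal-dominant matrix: only the k-mer itself attains the maximum)
    db <- list(x = randomSeq(nt, 50, 991))
    query <- randomSeq(nt, 20, 992)
    tab <- buildKmerTable(db, k = 3)
    expect_equal(matchKmers(tab, query, sm, threshold = 6),
                 matchKmers(tab, query), ignore_attr = TRUE)
    # threshold -Inf: every table entry matches every query k-mer position
    m <- matchKmers(tab, query, sm, threshold = -Inf)
    expect_identical(nrow(m), (20L - 3L + 1L) * kmerCount(tab))
})

test_that("matching requires compatible alphabets and relaxed mode a matrix", {
    nt <- nucleotideAlphabet()
    tab <- buildKmerTable(list(randomSeq(nt, 20, 31)), k = 2)
    expect_error(matchKmers(tab, randomProteinSeq(10, 32)), "alphabet")
    expect_error(matchKmers(tab, randomSeq(nt, 10, 33), threshold = 3),
                 "matrix")
})

test_that("merging tables over disjoint references equals a one-pass build", {
    nt <- nucleotideAlphabet()
    seqs <- setNames(lapply(1:4, function(i) randomSeq(nt, 30, 50 + i)),
                     paste0("s", 1:4))
    whole <- buildKmerTable(seqs, k = 3)
    part1 <- buildKmerTable(seqs[1:2], k = 3)
    part2 <- buildKmerTable(seqs[3:4], k = 3)
    merged <- mergeKmerTables(list(part1, part2))
    expect_identical(merged@codes, whole@codes)
    expect_identical(merged@offsets, whole@offsets)
    expect_identical(merged@refIds, whole@refIds)
    expect_identical(merged@positions, whole@positions)

    # merge with an empty table is the identity
    emptyTab <- buildKmerTable(list(z = encodeSequence("AC", nt)), k = 3)
    expect_identical(mergeKmerTables(list(whole, emptyTab))@positions,
                     whole@positions)

    expect_error(mergeKmerTables(list(part1, part1)), "disjoint")
    expect_error(mergeKmerTables(list(part1,
                                      buildKmerTable(seqs[3:4], k = 2))),
                 "differ")
})

test_that("serialization round-trips tables and rejects corrupt payloads", {
    nt <- nucleotideAlphabet()
    tab <- buildKmerTable(list(r0 = encodeSequence("ACGT", nt)), k = 2)
    bytes <- serializeKmerTable(tab)
    back <- deserializeKmerTable(bytes)
    for (slot in c("codes", "offsets", "refIds", "positions", "refNames",
                   "refLengths", "mask"))
        expect_identical(methods::slot(back, slot), methods::slot(tab, slot))
    expect_identical(alphabetSymbols(back@alphabet),
                     alphabetSymbols(tab@alphabet))

    emptyTab <- buildKmerTable(list(z = encodeSequence("AC", nt)), k = 3)
    expect_identical(kmerCount(deserializeKmerTable(
        serializeKmerTable(emptyTab))), 0L)

    expect_error(deserializeKmerTable(bytes[1:20]), "truncated")
    corrupt <- bytes
    corrupt[1:4] <- as.raw(0)
    expect_error(deserializeKmerTable(corrupt), "magic")
})

test_that("oversized code spaces are a configuration error", {
    p <- proteinAlphabet()
    expect_error(buildKmerTable(list(randomProteinSeq(30, 1)), k = 12),
                 "2\\^53")
})
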