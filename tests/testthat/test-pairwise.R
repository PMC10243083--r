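b62 <- loadSubstitutionMatrix("BLOSUM62")
nt <- nucleotideAlphabet()
ntm <- uniformSubstitutionMatrix(nt, 2, -2)

test_that("rigorous alignment matches the exhaustive enumeration oracle", {
    for (r in 1:8) {
        s1 <- randomSeq(nt, withSeed20(100 + r, sample(1:6, 1)), 200 + r)
        s2 <- randomSeq(nt, withSeed20(110 + r, sample(1:6, 1)), 210 + r)
        for (tp in c(TRUE, FALSE)) {
            a <- alignOptimal(s1, s2, ntm, -3, -1, mode = "global",
                              terminalPenalty = tp)[[1]]
            want <- bruteGlobalScore(symbolCodes(s1), symbolCodes(s2),
                                     scoreMatrix(ntm), -3, -1, termpen = tp)
            expect_equal(alignmentScore(a), want)
            expect_equal(scoreFromTrace(a, ntm, -3, -1,
                                        terminalPenalty = tp), want)
            expectValidTrace(a)
        }
    }
    # local against the exhaustive substring oracle (small lengths)
    for (r in 1:5) {
        s1 <- randomSeq(nt, 4, 300 + r)
        s2 <- randomSeq(nt, 4, 310 + r)
        a <- alignOptimal(s1, s2, ntm, -3, -1, mode = "local")[[1]]
        expect_equal(alignmentScore(a),
                     bruteLocalScore(symbolCodes(s1), symbolCodes(s2),
                                     scoreMatrix(ntm), -3, -1))
        expectValidTrace(a)
    }
})

test_that("rigorous scores agree with an independent aligner on proteins", {
    for (r in 1:20) {
        s1 <- randomProteinSeq(withSeed20(500 + r, sample(10:60, 1)), 520 + r)
        s2 <- randomProteinSeq(withSeed20(540 + r, sample(10:60, 1)), 560 + r)
        for (local in c(FALSE, TRUE)) {
            a <- alignOptimal(s1, s2, b62, -11, -1,
                              mode = if (local) "local" else "global")[[1]]
            expect_equal(alignmentScore(a),
                         biostringsScore(s1, s2, b62, -11, -1, local))
        }
    }
})

test_that("degenerate aligner inputs behave as specified", {
    # identical sequences align gap-free at the diagonal sum
    s <- randomProteinSeq(25, 1)
    a <- alignOptimal(s, s, b62, -11, -1)[[1]]
    expect_identical(sum(alignmentTrace(a) < 0), 0L)
    expect_equal(alignmentScore(a),
                 sum(diag(scoreMatrix(b62))[symbolCodes(s) + 1]))
    expect_equal(getIdentity(a), 1.0)

    # local alignment with all-negative scores is empty with score 0
    neg <- uniformSubstitutionMatrix(nt, -1, -2)
    a0 <- alignOptimal(randomSeq(nt, 8, 2), randomSeq(nt, 8, 3), neg,
                       -3, -1, mode = "local")[[1]]
    expect_identical(nrow(alignmentTrace(a0)), 0L)
    expect_equal(alignmentScore(a0), 0)

    # empty sequence in global mode: valid all-gap alignment
    e <- encodeSequence("", nt)
    s2 <- encodeSequence("ACG", nt)
    ae <- alignOptimal(e, s2, ntm, -3, -1)[[1]]
    expect_identical(renderAlignment(ae), c("---", "ACG"))
    expect_equal(alignmentScore(ae), -3 + 2 * -1)

    # alphabet mismatch
    expect_error(alignOptimal(randomProteinSeq(5, 4), s2, ntm, -3, -1),
                 "alphabet")
})

test_that("score is symmetric under argument swap for symmetric matrices", {
    for (r in 1:10) {
        s1 <- randomProteinSeq(20, 600 + r)
        s2 <- randomProteinSeq(30, 620 + r)
        for (mode in c("global", "local")) {
            expect_equal(
                alignmentScore(alignOptimal(s1, s2, b62, -11, -1, mode)[[1]]),
                alignmentScore(alignOptimal(s2, s1, b62, -11, -1, mode)[[1]]))
        }
    }
})

test_that("banded alignment with a full band equals the rigorous aligner", {
    for (r in 1:50) {
        n1 <- withSeed20(700 + r, sample(5:60, 1))
        n2 <- withSeed20(720 + r, sample(5:60, 1))
        s1p <- randomProteinSeq(n1, 740 + r)
        s2p <- randomProteinSeq(n2, 760 + r)
        s1n <- randomSeq(nt, n1, 780 + r)
        s2n <- randomSeq(nt, n2, 800 + r)
        full <- c(-n1, n2)
        for (mode in c("global", "local")) {
            expect_equal(
                alignmentScore(alignBanded(s1p, s2p, b62, -11, -1,
                                           band = full, mode = mode)[[1]]),
                alignmentScore(alignOptimal(s1p, s2p, b62, -11, -1,
                                            mode = mode)[[1]]))
            expect_equal(
                alignmentScore(alignBanded(s1n, s2n, ntm, -3, -1,
                                           band = full, mode = mode)[[1]]),
                alignmentScore(alignOptimal(s1n, s2n, ntm, -3, -1,
                                            mode = mode)[[1]]))
        }
    }
})

test_that("banded scores never exceed rigorous scores; diagonal band sums the diagonal", {
    for (r in 1:50) {
        s1 <- randomProteinSeq(30, 900 + r)
        s2 <- randomProteinSeq(35, 950 + r)
        dlo <- withSeed20(1000 + r, sample(-25:0, 1))
        dhi <- dlo + withSeed20(1050 + r, sample(5:40, 1))
        a <- alignBanded(s1, s2, b62, -11, -1, band = c(dlo, dhi),
                         mode = "local")[[1]]
        expect_lte(alignmentScore(a),
                   alignmentScore(alignOptimal(s1, s2, b62, -11, -1,
                                               mode = "local")[[1]]))
        expectValidTrace(a)
        if (nrow(alignmentTrace(a))) {
            dgs <- alignmentTrace(a)[, 2] - alignmentTrace(a)[, 1]
            dgs <- dgs[alignmentTrace(a)[, 1] >= 0 &
                       alignmentTrace(a)[, 2] >= 0]
            expect_true(all(dgs >= dlo & dgs <= dhi))
        }
    }

    # band (0, 0) in global mode with linear gaps = plain diagonal sum
    s1 <- randomSeq(nt, 12, 5)
    s2 <- randomSeq(nt, 12, 6)
    a <- alignBanded(s1, s2, ntm, -3, NULL, band = c(0, 0))[[1]]
    expect_equal(alignmentScore(a),
                 sum(scoreMatrix(ntm)[cbind(symbolCodes(s1) + 1,
                                            symbolCodes(s2) + 1)]))

    expect_error(alignBanded(s1, s2, ntm, -3, -1, band = c(5, 10)),
                 "contain")
    expect_error(alignBanded(s1, s2, ntm, -3, -1, band = c(30, 40),
                             mode = "local"), "intersect")
})

test_that("ungapped X-drop extension obeys the stopping rule and its oracle", {
    # hand-simulated stopping: third column drops 3 > X = 1
    s1 <- encodeSequence("AATT", nt)
    s2 <- encodeSequence("AAGG", nt)
    m13 <- uniformSubstitutionMatrix(nt, 1, -3)
    a <- alignLocalUngapped(s1, s2, m13, seed = c(0, 0), xDrop = 1)
    expect_equal(alignmentScore(a), 2)
    expect_identical(alignmentTrace(a), cbind(0:1, 0:1))

    # perfect diagonal
    aaaa <- encodeSequence("AAAA", nt)
    m1 <- uniformSubstitutionMatrix(nt, 1, -1)
    ap <- alignLocalUngapped(aaaa, aaaa, m1, seed = c(0, 0), xDrop = 5)
    expect_equal(alignmentScore(ap), 4)
    expect_identical(nrow(alignmentTrace(ap)), 4L)

    # X = Inf equals the quadratic diagonal-segment oracle
    for (r in 1:30) {
        s1 <- randomProteinSeq(40, 1100 + r)
        s2 <- randomProteinSeq(40, 1150 + r)
        seed <- withSeed20(1200 + r, c(sample(0:39, 1), sample(0:39, 1)))
        a <- alignLocalUngapped(s1, s2, b62, seed = seed, xDrop = Inf)
        expect_equal(alignmentScore(a),
                     bruteDiagonalSegment(s1, s2, b62, seed))
        expect_identical(sum(alignmentTrace(a) < 0), 0L)   # no gaps
        expectValidTrace(a)
    }
    expect_error(alignLocalUngapped(s1, s2, b62, seed = c(50, 0)), "range")
})

test_that("gapped X-drop extension reaches the rigorous local score at X = Inf", {
    # constructed cases where the optimal local alignment crosses the seed
    for (r in 1:15) {
        core <- randomProteinSeq(20, 1300 + r)
        left1 <- randomProteinSeq(8, 1350 + r)
        right2 <- randomProteinSeq(8, 1400 + r)
        s1 <- Sequence(c(symbolCodes(left1), symbolCodes(core)),
                       proteinAlphabet())
        s2 <- Sequence(c(symbolCodes(core), symbolCodes(right2)),
                       proteinAlphabet())
        # seed inside the shared core
        seed <- c(8 + 5, 5)
        a <- alignLocalGapped(s1, s2, b62, -11, -1, seed = seed, xDrop = Inf)
        rig <- alignOptimal(s1, s2, b62, -11, -1, mode = "local")[[1]]
        expect_equal(alignmentScore(a), alignmentScore(rig))
        expect_equal(scoreFromTrace(a, b62, -11, -1), alignmentScore(a))
        expectValidTrace(a)
    }

    # a perfect match gives the same result for any X
    s <- randomProteinSeq(30, 1500)
    for (x in c(1, 5, Inf)) {
        a <- alignLocalGapped(s, s, b62, -11, -1, seed = c(10, 10), xDrop = x)
        expect_equal(alignmentScore(a),
                     sum(diag(scoreMatrix(b62))[symbolCodes(s) + 1]))
    }

    # tiny X confines the alignment near the seed and bounds the score
    for (r in 1:10) {
        s1 <- randomProteinSeq(50, 1600 + r)
        s2 <- randomProteinSeq(50, 1650 + r)
        sd <- withSeed20(1700 + r, c(sample(0:49, 1), sample(0:49, 1)))
        aT <- alignLocalGapped(s1, s2, b62, -11, -1, seed = sd, xDrop = 1)
        rig <- alignmentScore(alignOptimal(s1, s2, b62, -11, -1,
                                           mode = "local")[[1]])
        expect_lte(alignmentScore(aT), rig)
    }
})

test_that("identity and coverage metrics follow their definitions", {
    a <- Alignment(list(encodeSequence("ACG", nt), encodeSequence("AG", nt)),
                   rbind(c(0, 0), c(1, -1), c(2, 1)))
    expect_equal(getIdentity(a, "all"), 2 / 3)
    expect_equal(getIdentity(a, "shortest"), 2 / 2)
    expect_equal(getIdentity(a, "not_terminal"), 2 / 3)

    s <- randomProteinSeq(14, 9)
    sub <- Sequence(symbolCodes(s)[4:10], proteinAlphabet())
    al <- Alignment(list(s, sub), cbind(3:9, 0:6))
    expect_equal(getCoverage(al, 1, 14), 7 / 14)
    expect_equal(getCoverage(al, 2), 1.0)

    # self-alignment scores 1 everywhere; shortest >= all always
    self <- alignOptimal(s, s, b62, -11, -1)[[1]]
    for (m in c("all", "not_terminal", "shortest"))
        expect_equal(getIdentity(self, m), 1.0)
    for (r in 1:10) {
        x <- alignOptimal(randomProteinSeq(15, 30 + r),
                          randomProteinSeq(20, 40 + r), b62, -11, -1)[[1]]
        expect_gte(getIdentity(x, "shortest"), getIdentity(x, "all"))
        expect_lte(getCoverage(x, 1), 1)
    }
    expect_error(getIdentity(Alignment(list(s, s, s),
                                       cbind(0:4, 0:4, 0:4))),
                 "2-sequence")
})

test_that("co-optimal alignments are enumerated deterministically and all score equally", {
    s1 <- encodeSequence("AC", nt)
    s2 <- encodeSequence("A", nt)
    res <- alignOptimal(s1, s2, uniformSubstitutionMatrix(nt, 1, -1),
                        -1, -1, mode = "global")
    expect_gte(length(res), 1L)
    for (a in res) {
        expect_equal(scoreFromTrace(a, uniformSubstitutionMatrix(nt, 1, -1),
                                    -1, -1), alignmentScore(a))
        expectValidTrace(a)
    }
    # re-running yields the identical list (determinism)
    res2 <- alignOptimal(s1, s2, uniformSubstitutionMatrix(nt, 1, -1),
                         -1, -1, mode = "global")
    expect_identical(lapply(res, alignmentTrace),
                     lapply(res2, alignmentTrace))
})
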