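nt <- nucleotideAlphabet()

twoSeqProfile <- function() {
    a <- Alignment(list(encodeSequence("ACG", nt),
                        encodeSequence("AG", nt)),
                   rbind(c(0, 0), c(1, -1), c(2, 1)))
    sequenceProfile(a)
}

test_that("profiles count symbols and gaps per column", {
    p <- twoSeqProfile()
    cnt <- positionCounts(p)
    expect_identical(unname(cnt[, "A"]), c(2L, 0L, 0L))
    expect_identical(unname(cnt[, "C"]), c(0L, 1L, 0L))
    expect_identical(unname(cnt[, "G"]), c(0L, 0L, 2L))
    expect_identical(gapCounts(p), c(0L, 1L, 0L))
    # conservation: column sums + gaps = number of sequences
    expect_true(all(rowSums(cnt) + gapCounts(p) == 2L))

    # single ungapped sequence: one-hot rows, no gaps
    s <- encodeSequence("ACGT", nt)
    p1 <- sequenceProfile(Alignment(list(s), matrix(0:3, ncol = 1)))
    expect_true(all(rowSums(positionCounts(p1)) == 1L))
    expect_identical(gapCounts(p1), rep(0L, 4))
})

test_that("count conservation holds for profiles of random alignments", {
    b62 <- loadSubstitutionMatrix("BLOSUM62")
    for (r in 1:10) {
        seqs <- lapply(1:3, function(i) randomProteinSeq(12, 3000 + 10 * r + i))
        msa <- msaAlignment(alignMultiple(seqs, b62, -11, -1))
        p <- sequenceProfile(msa)
        expect_true(all(rowSums(positionCounts(p)) + gapCounts(p) == 3L))
    }
})

test_that("PPM follows the pseudocount formula and rows sum to 1", {
    # counts (A: 2, others 0): c_p = 0 gives P(A) = 1
    s <- encodeSequence("A", nt)
    p <- sequenceProfile(Alignment(list(s, s), rbind(c(0, 0))))
    expect_equal(unname(probabilityMatrix(p, 0)[1, ]), c(1, 0, 0, 0))
    # c_p = 4, k = 4: P(A) = (2+1)/(2+4) = 0.5, others 1/6
    expect_equal(unname(probabilityMatrix(p, 4)[1, ]),
                 c(0.5, 1/6, 1/6, 1/6))

    for (cp in c(0, 1, 4)) {
        pr <- probabilityMatrix(twoSeqProfile(), cp)
        expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-12)
    }

    # all-gap column with zero pseudocount is an error
    g <- new("SequenceProfile",
             counts = matrix(0L, 1, 4,
                             dimnames = list(NULL, c("A","C","G","T"))),
             gaps = 2L, alphabet = nt)
    expect_error(probabilityMatrix(g, 0), "zero pseudocount")
    expect_equal(rowSums(probabilityMatrix(g, 1)), 1)
})

test_that("PWM is the base-2 log-odds of PPM over the background", {
    p <- twoSeqProfile()
    # P(S) = B_S everywhere gives an all-zero PWM
    u <- new("SequenceProfile",
             counts = matrix(1L, 2, 4,
                             dimnames = list(NULL, c("A","C","G","T"))),
             gaps = c(0L, 0L), alphabet = nt)
    expect_true(all(logOddsMatrix(u) == 0))

    # P(A) = 0.5 over B_A = 0.25 gives W(A) = 1
    s <- encodeSequence("A", nt)
    p2 <- sequenceProfile(Alignment(list(s, s), rbind(c(0, 0))))
    expect_equal(unname(logOddsMatrix(p2, 4)[1, "A"]), 1)

    # doubling the background lowers the weight by exactly 1 bit
    bg1 <- c(A = 0.1, C = 0.3, G = 0.3, T = 0.3)
    bg2 <- bg1; bg2["A"] <- 0.2
    w1 <- logOddsMatrix(p2, 4, bg1)
    w2 <- logOddsMatrix(p2, 4, bg2)
    expect_equal(w2[1, "A"], w1[1, "A"] - 1)

    # zero counts with c_p = 0 give -Inf, zero background is an error
    expect_identical(unname(logOddsMatrix(p2, 0)[1, "C"]), -Inf)
    expect_error(logOddsMatrix(p2, 0, c(0, 0.5, 0.25, 0.25)), "positive")
})

test_that("consensus picks maxima, IUPAC codes for nucleotide ties", {
    # A/G tie -> R
    tie <- sequenceProfile(Alignment(
        list(encodeSequence("A", nt), encodeSequence("G", nt)),
        rbind(c(0, 0))))
    expect_identical(as.character(toConsensus(tie)), "R")

    # all four tie -> N
    all4 <- new("SequenceProfile",
                counts = matrix(1L, 1, 4,
                                dimnames = list(NULL, c("A","C","G","T"))),
                gaps = 0L, alphabet = nt)
    expect_identical(as.character(toConsensus(all4)), "N")

    # protein ties resolve to the first symbol in alphabet order
    p <- proteinAlphabet()
    ptie <- sequenceProfile(Alignment(
        list(encodeSequence("C", p), encodeSequence("A", p)),
        rbind(c(0, 0))))
    expect_identical(as.character(toConsensus(ptie)), "A")

    # consensus of a single-sequence profile is the sequence itself
    s <- randomProteinSeq(15, 77)
    p1 <- sequenceProfile(Alignment(list(s), matrix(0:14, ncol = 1)))
    expect_identical(as.character(toConsensus(p1)), decodeSequence(s))
})

test_that("sequence probability and score are consistent", {
    s <- randomSeq(nt, 8, 55)
    p1 <- sequenceProfile(Alignment(list(s), matrix(0:7, ncol = 1)))
    # consensus of a one-sequence profile has probability 1 at c_p = 0
    expect_equal(sequenceProbability(p1, s, 0), 1.0)
    # a zero-count symbol makes the probability 0
    other <- Sequence((symbolCodes(s) + 1L) %% 4L, nt)
    expect_equal(sequenceProbability(p1, other, 0), 0.0)

    # single-sequence profile scored on itself, uniform background over 4:
    # each position contributes log2(1 / 0.25) = 2
    expect_equal(sequenceScore(p1, s, 0), 2 * length(s))

    # identity: probability = 2^score * prod(B) when all probabilities > 0
    for (r in 1:50) {
        seqs <- lapply(1:3, function(i) randomSeq(nt, 6, 4000 + 10 * r + i))
        aln <- Alignment(seqs, cbind(0:5, 0:5, 0:5))
        pr <- sequenceProfile(aln)
        test <- randomSeq(nt, 6, 4500 + r)
        cp <- 2
        bg <- uniformBackground(nt)
        prob <- sequenceProbability(pr, test, cp)
        sc <- sequenceScore(pr, test, cp, bg)
        expect_equal(prob, 2^sc * prod(bg[symbolCodes(test) + 1]),
                     tolerance = 1e-9)
    }

    expect_error(sequenceProbability(p1, randomSeq(nt, 5, 1), 0), "length")
})
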