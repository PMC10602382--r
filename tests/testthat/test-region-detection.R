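test_that("triangular weights are symmetric, normalized and plateaued", {
    w12 <- triangularWeights(12)
    expect_equal(w12, c(1:6, 6:1) / 42)
    w11 <- triangularWeights(11)
    expect_equal(w11, rev(w11))
    expect_equal(sum(w11), 1)
})

test_that("windowed score matches hand arithmetic and bounds", {
    cfg <- detectionConfig()
    expect_equal(windowedScore(strrep("K", 40), cfg), rep(1, 40))
    expect_equal(windowedScore(strrep("G", 40), cfg), rep(0, 40))
    ## full window straddling the charged/uncharged junction: the charged
    ## half carries weights (1..6)/42 = 21/42
    sc <- windowedScore("KKKKKKGGGGGG", cfg)
    expect_equal(sc[6], 0.5)
    s <- paste(sample(c("K", "G"), 100, replace = TRUE), collapse = "")
    expect_true(all(windowedScore(s, cfg) >= 0 &
                    windowedScore(s, cfg) <= 1))
})

test_that("interval calling respects the tolerance automaton", {
    cfg <- detectionConfig(minLen = 30L, tolerance = 10L)
    iv <- detectIntervals(rep(0.9, 50), cfg)
    expect_equal(as.data.frame(iv)[, c("start", "end")],
                 data.frame(start = 1L, end = 50L))
    expect_length(detectIntervals(rep(0.1, 50), cfg), 0)

    ## 40 above / 11 below / 40 above splits; 40/10/40 fuses
    tr11 <- c(rep(1, 40), rep(0, 11), rep(1, 40))
    iv <- detectIntervals(tr11, cfg)
    expect_equal(IRanges::start(iv), c(1L, 52L))
    expect_equal(IRanges::end(iv), c(40L, 91L))
    tr10 <- c(rep(1, 40), rep(0, 10), rep(1, 40))
    iv <- detectIntervals(tr10, cfg)
    expect_equal(IRanges::width(iv), 90L)
})

test_that("interval calling is identical to the brute-force oracle", {
    set.seed(123)
    cfg <- detectionConfig(windowLen = 4L, threshold = 0.5,
                           tolerance = 3L, minLen = 5L)
    for (i in 1:120) {
        track <- round(runif(sample(10:60, 1)), 2)
        got <- as.data.frame(detectIntervals(track, cfg))
        want <- bruteForceIntervals(track, cfg@threshold, cfg@tolerance,
                                    cfg@minLen)
        expect_equal(nrow(got), nrow(want))
        if (nrow(want)) {
            expect_equal(got$start, want[, 1])
            expect_equal(got$end, want[, 2])
        }
    }
})

test_that("trimming shrinks to target residues and flags short leftovers", {
    cfg <- detectionConfig(minLen = 4L, targetSet = c("D", "E", "K", "R"))
    iv <- IRanges::IRanges(1, 8)
    tr <- trimIntervals("GGEKEKGG", iv, cfg)
    expect_equal(IRanges::start(tr), 3L)
    expect_equal(IRanges::end(tr), 6L)
    expect_false(S4Vectors::mcols(tr)$belowMinLen)

    tr <- trimIntervals("EKEK", IRanges::IRanges(1, 4), cfg)
    expect_equal(IRanges::width(tr), 4L)

    tr <- trimIntervals("GGGG", IRanges::IRanges(1, 4), cfg)
    expect_length(tr, 0)
    expect_equal(attr(tr, "nEmpty"), 1L)

    ## post-trim shorter than minLen: kept and flagged, dropped in strict mode
    cfg30 <- detectionConfig(minLen = 30L)
    s <- paste0(strrep("G", 10), "EK", strrep("G", 30))
    tr <- trimIntervals(s, IRanges::IRanges(1, 42), cfg30)
    expect_true(S4Vectors::mcols(tr)$belowMinLen)
    expect_length(trimIntervals(s, IRanges::IRanges(1, 42), cfg30,
                                strict = TRUE), 0)
})

test_that("proteome-level detection is deterministic and provenance-complete", {
    prot <- c(p1 = paste0(strrep("G", 40), strrep("EK", 30), strrep("G", 40)),
              p2 = strrep("G", 120))
    r1 <- detectEnrichedRegions(prot)
    r2 <- detectEnrichedRegions(prot)
    expect_identical(r1, r2)
    expect_equal(length(r1), 1L)
    expect_equal(as.character(GenomicRanges::seqnames(r1)), "p1")
    sq <- S4Vectors::mcols(r1)$sequence
    expect_equal(substr(sq, 1, 1) %in% c("D", "E", "K", "R"), TRUE)
    expect_equal(S4Vectors::mcols(r1)$targetSet, "DEKR")
    expect_error(detectEnrichedRegions(character(0)), "empty")
    expect_length(detectEnrichedRegions(c(g = strrep("G", 200))), 0)
})

test_that("lowering the threshold never shrinks detected coverage", {
    set.seed(5)
    prot <- replicate(10, paste(
        sample(c("E", "K", "G", "S"), 150, replace = TRUE,
               prob = c(.25, .25, .25, .25)), collapse = ""))
    names(prot) <- paste0("p", 1:10)
    covered <- function(thr) {
        cfg <- detectionConfig(threshold = thr, minLen = 10L)
        gr <- detectEnrichedRegions(prot, cfg)
        sum(IRanges::width(gr))
    }
    cov <- vapply(c(0.6, 0.5, 0.4, 0.3), covered, numeric(1))
    expect_true(all(diff(cov) >= 0))
})

test_that("BED export uses 0-based half-open coordinates", {
    prot <- c(p1 = paste0(strrep("G", 40), strrep("EK", 30), strrep("G", 40)))
    gr <- detectEnrichedRegions(prot)
    f <- tempfile(fileext = ".tsv")
    writeRegionsBed(gr, f)
    bed <- read.table(f, header = TRUE, sep = "\t")
    expect_equal(bed$start, IRanges::start(gr) - 1L)
    expect_equal(bed$end, IRanges::end(gr))
    expect_equal(bed$end - bed$start, IRanges::width(gr))
})
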