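test_that("alignment trimming removes the two extreme rows and gap columns", {
    aln <- c(a = "AAAA-", b = "AA---", c = "AAAAA", d = "AAA--")
    tr <- trimAlignment(aln)          # drops c (longest) and b (shortest)
    expect_named(tr, c("a", "d"))
    ## column 5 was gap-only in the survivors and is removed
    expect_equal(unname(nchar(tr)), c(4L, 4L))
    expect_error(trimAlignment(aln[1:3]), "at least 4")

    ## all rows equal length: first row and first *other* minimal row go
    aln2 <- c(r1 = "AAA", r2 = "CCC", r3 = "DDD", r4 = "EEE")
    tr2 <- trimAlignment(aln2)
    expect_named(tr2, c("r3", "r4"))
})

test_that("gap frequency counts characters globally", {
    expect_equal(gapFrequency(c(a = "EKKK", b = "EKKK")), 0)
    expect_equal(gapFrequency(c(a = "EK-K", b = "EKKK")), 1 / 8)
})

test_that("divergence matches closed-form column entropies", {
    expect_equal(divergence(c(a = "EKEK", b = "EKEK")), 0)
    expect_equal(divergence(c(a = "EEEE", b = "KKKK")), log(2))
    ## column {E,E,K,R}: entropy of (1/2, 1/4, 1/4)
    aln <- c(a = "E", b = "E", c = "K", d = "R")
    expect_equal(divergence(aln), -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
    expect_equal(divergence(aln, base = 2),
                 divergence(aln) / log(2))
    ## gaps excluded by default; included as a 21st symbol on request
    alnG <- c(a = "E", b = "E", c = "-", d = "-")
    expect_equal(divergence(alnG), 0)
    expect_equal(divergence(alnG, includeGaps = TRUE), log(2))
    ## invariant to row and column order
    set.seed(2)
    fam <- evolveFamily(strrep("ACDEFGHIKL", 8), nSpecies = 5,
                        pSub = 0.3, pIndel = 0.05, seed = 2)
    a <- fam$alignment
    expect_equal(divergence(a), divergence(rev(a)))
    m <- do.call(rbind, strsplit(a, ""))
    perm <- sample(ncol(m))
    shuffled <- apply(m[, perm], 1, paste, collapse = "")
    expect_equal(divergence(a), divergence(setNames(shuffled, names(a))))
})

test_that("region mapping round-trips through alignment columns", {
    set.seed(4)
    for (i in 1:20) {
        fam <- evolveFamily(strrep("ACDEFGHIKLMNPQRSTVWY", 4),
                            nSpecies = 4, pSub = 0.2, pIndel = 0.1)
        ref <- fam$alignment[["root"]]
        resCols <- which(strsplit(ref, "")[[1]] != "-")
        st <- sample(1:60, 1); en <- st + sample(5:15, 1)
        span <- mapRegionToColumns(ref, st, en)
        ## generator bookkeeping agrees with the mapping
        expect_equal(span[1], fam$columnMap[st])
        expect_equal(span[2], fam$columnMap[en])
        ## inverse: counting reference residues up to the span recovers
        ## the interval exactly
        expect_equal(sum(resCols <= span[1]), st)
        expect_equal(sum(resCols <= span[2]), en)
    }
    expect_error(mapRegionToColumns("AC-DE", 2, 9), "outside")
})

test_that("per-species enrichment reflects substitutions and gaps", {
    ## identical rows: every species shows the region's own enrichment
    aln <- c(ref = "GGEKEKEKGG", s1 = "GGEKEKEKGG", s2 = "GGEKEKEKGG")
    pr <- regionAlignmentProfile(aln, "ref", 3, 8, minAligned = 5L)
    expect_equal(unname(pr$enrichment), rep(1, 3))
    expect_equal(pr$meanEnrichment, 1)

    ## one substitution E->G drops one species by 1/L
    aln2 <- c(ref = "GGEKEKEKGG", s1 = "GGGKEKEKGG", s2 = "GGEKEKEKGG")
    pr2 <- regionAlignmentProfile(aln2, "ref", 3, 8, minAligned = 5L)
    expect_equal(unname(pr2$enrichment["s1"]), 1 - 1 / 6)

    ## a fully gapped species is absent
    aln3 <- c(ref = "GGEKEKEKGG", s1 = "GG------GG", s2 = "GGEKEKEKGG")
    pr3 <- regionAlignmentProfile(aln3, "ref", 3, 8, minAligned = 5L)
    expect_false(pr3$present[["s1"]])
    expect_equal(pr3$meanEnrichment, 1)
    expect_error(regionAlignmentProfile(aln3, "nope", 3, 8), "not in")
})

test_that("candidate-set enumeration filters by combined frequency", {
    uni <- setNames(rep(0.05, 20), AA_ALPHABET20)
    ## all sums are 0.2: none match 0.233 +/- 0.01, all match 0.2
    expect_length(enumerateResidueSets(uni, driftConfig()), 0)
    all16 <- enumerateResidueSets(uni, driftConfig(freqTarget = 0.2))
    expect_length(all16, choose(16, 4))
    expect_false(any(vapply(all16, function(s)
        any(s %in% c("D", "E", "K", "R")), logical(1))))
})

test_that("drift scores pin their unit-scale endpoints", {
    expect_equal(driftScore(0.233, 0.233, 0.55)$scaled, 0)
    expect_equal(driftScore(0.55, 0.233, 0.55)$scaled, 1)
    mid <- (0.233 + 0.55) / 2
    expect_equal(driftScore(mid, 0.233, 0.55)$scaled, 0.5)
    expect_error(driftScore(0.4, 0.3, 0.3), "degenerate")
    ## invariance to affine rescaling of the enrichment units
    a <- 2.3; b <- 0.17
    expect_equal(driftScore(a * mid + b, a * 0.233 + b, a * 0.55 + b)$scaled,
                 0.5)
})

test_that("zero-substitution families show no drift, free drift decays", {
    set.seed(31)
    pg <- genProteome(12, 260, seed = 31)
    prot <- character(12); regions <- list()
    for (i in 1:12) {
        ins <- insertRegion(pg$proteins[[i]], 60, fcr = 0.55)
        prot[i] <- ins$protein
        regions[[i]] <- data.frame(start = ins$start, end = ins$end)
    }
    names(prot) <- names(pg$proteins)
    ## no evolution at all: every region keeps its enrichment, scaled ~ 1
    alnFrozen <- lapply(seq_along(prot), function(i)
        evolveFamily(prot[[i]], nSpecies = 5, pSub = 0, pIndel = 0,
                     rootId = names(prot)[i])$alignment)
    names(alnFrozen) <- names(prot)
    resFrozen <- driftScan(prot, alnFrozen,
                           driftConfig(freqTarget = 0.2, freqTol = 0.001),
                           sets = list(c("D", "E", "K", "R")))
    expect_gt(resFrozen$table$scaled, 0.85)
    expect_lt(resFrozen$table$scaled, 1.15)

    ## free heavy drift: enrichment regresses toward background
    alnFree <- lapply(seq_along(prot), function(i)
        evolveFamily(prot[[i]], nSpecies = 5, pSub = 0.95, pIndel = 0,
                     conservation = "free",
                     rootId = names(prot)[i])$alignment)
    names(alnFree) <- names(prot)
    resFree <- driftScan(prot, alnFree,
                         driftConfig(freqTarget = 0.2, freqTol = 0.001),
                         sets = list(c("D", "E", "K", "R")))
    expect_lt(resFree$table$scaled, 0.45)
})
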