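test_that("proteome generation is seed-pure and frequency-faithful", {
    a <- genProteome(5, c(50, 90), seed = 77)
    b <- genProteome(5, c(50, 90), seed = 77)
    expect_identical(a, b)

    ## uniform background: each frequency within 3 SE of 0.05
    pg <- genProteome(100, 500, seed = 10)
    f <- aminoAcidFrequencies(pg$proteins)
    se <- sqrt(0.05 * 0.95 / (100 * 500))
    expect_true(all(abs(f - 0.05) < 3 * se))

    ## ORFs translate back to the proteins exactly
    aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(pg$orfs[1:10])))
    expect_equal(unname(aa), unname(pg$proteins[1:10]))
    expect_error(genProteome(2, 50, freqs = c(A = 0.5)), "sum to 1")
})

test_that("inserted regions meet their composition targets exactly", {
    pg <- genProteome(1, 300, seed = 5)
    ins <- insertRegion(pg$proteins[[1]], regionLength = 60, fcr = 0.5,
                        seed = 6)
    seg <- substr(ins$protein, ins$start, ins$end)
    expect_equal(nchar(seg), 60L)
    chars <- strsplit(seg, "")[[1]]
    expect_equal(sum(chars %in% c("D", "E", "K", "R")), 30L)
    expect_equal(nchar(ins$protein), 300L)
    ## outside the region the protein is untouched
    expect_equal(substr(ins$protein, 1, ins$start - 1),
                 substr(pg$proteins[[1]], 1, ins$start - 1))

    ## net-sign conventions
    insNeg <- insertRegion(pg$proteins[[1]], 60, 0.5, sign = "negative",
                           seed = 7)
    segN <- substr(insNeg$protein, insNeg$start, insNeg$end)
    expect_lt(ncpr(segN), -0.2)
    insPos <- insertRegion(pg$proteins[[1]], 60, 0.5, sign = "positive",
                           seed = 7)
    expect_gt(ncpr(substr(insPos$protein, insPos$start, insPos$end)), 0.2)

    expect_error(insertRegion("ACDEF", regionLength = 10), "longer")
})

test_that("kappa targeting reaches requested patterning or fails loudly", {
    pg <- genProteome(1, 200, seed = 12)
    for (target in c(0.2, 0.7)) {
        ins <- insertRegion(pg$proteins[[1]], 60, 0.5, sign = "neutral",
                            kappaTarget = target, seed = 13)
        expect_lt(abs(ins$achievedKappa - target), 0.05)
    }
    ## single charge species with no neutral residues cannot be patterned
    expect_error(insertRegion(pg$proteins[[1]], 60, fcr = 1,
                              sign = "positive", kappaTarget = 1,
                              model = chargeModel(positive = c("K", "R"),
                                                  negative = character(0)),
                              seed = 1), "infeasible")
})

test_that("structure tracks encode truth and add calibrated noise", {
    pg <- genProteome(1, 200, seed = 20)
    truth <- data.frame(start = c(30, 120), end = c(80, 170),
                        label = c("helical", "disordered"))
    tr <- genStructureTrack(pg$proteins[[1]], truth, noise = 0, seed = 21)
    cl <- classifyResidues(tr)
    expect_true(all(cl[30:80] == "helix"))
    expect_true(all(cl[120:170] == "disordered"))

    ## noise flips roughly the stated fraction of ss calls
    long <- strrep("A", 2000)
    t0 <- genStructureTrack(long, data.frame(start = 1, end = 2000,
                                             label = "helical"),
                            noise = 0, seed = 22)
    t1 <- genStructureTrack(long, data.frame(start = 1, end = 2000,
                                             label = "helical"),
                            noise = 0.1, seed = 22)
    flipped <- mean(t1@ss != "helix")
    expect_lt(abs(flipped - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))

    ## background mix yields no pure run beyond the training minimum
    bg <- genStructureTrack(long, NULL, seed = 23)
    runs <- rle(as.character(classifyResidues(bg)))
    expect_lt(max(runs$lengths[runs$values %in% c("helix", "disordered")]),
              26)
})

test_that("family evolution honours its rate dials and bookkeeping", {
    root <- genProteome(1, 150, seed = 40)$proteins[[1]]
    ## zero rates: identical rows, zero divergence and gaps
    fam0 <- evolveFamily(root, nSpecies = 4, pSub = 0, pIndel = 0, seed = 41)
    expect_true(all(fam0$alignment == fam0$alignment[[1]]))
    expect_equal(divergence(fam0$alignment), 0)
    expect_equal(gapFrequency(fam0$alignment), 0)

    ## indels only: gaps appear but columns stay homogeneous
    famI <- evolveFamily(root, nSpecies = 4, pSub = 0, pIndel = 0.1,
                         seed = 42)
    expect_gt(gapFrequency(famI$alignment), 0)
    expect_equal(divergence(famI$alignment), 0)

    ## composition-preserving regions diverge in sequence but not in
    ## target-set enrichment
    reg <- data.frame(start = 40, end = 99)
    famC <- evolveFamily(root, nSpecies = 6, pSub = 0.5, pIndel = 0,
                         regions = reg, seed = 43)
    rootSeg <- substr(root, 40, 99)
    for (sp in paste0("sp", 1:6)) {
        seg <- substr(famC$alignment[[sp]], famC$columnMap[40],
                      famC$columnMap[99])
        expect_false(seg == rootSeg)          # sequence diverged
        expect_equal(fcr(seg), fcr(rootSeg))  # enrichment preserved
    }
})
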