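# block fingerprints: nClusters well-separated chemotypes
blockFingerprints <- function(n, nClusters, bits = 128, seed = 1,
                              noise = 0.02) {
    set.seed(seed)
    cl <- rep_len(seq_len(nClusters), n)
    width <- bits %/% nClusters
    fp <- matrix(as.numeric(runif(n * bits) < noise), n, bits)
    for (i in seq_len(n)) {
        on <- (cl[i] - 1L) * width + seq_len(width)
        fp[i, on] <- 1
    }
    rownames(fp) <- sprintf("C%03d", seq_len(n))
    list(fp = fp, cluster = cl)
}

test_that("the SOM separates distinct chemotype blocks deterministically", {
    b <- blockFingerprints(40, 2, bits = 64, seed = 2)
    g <- trainSom(b$fp, somRows = 2, somCols = 1, epochs = 10, seed = 5)
    a <- somAssignment(g)
    expect_equal(length(unique(a[b$cluster == 1])), 1L)
    expect_equal(length(unique(a[b$cluster == 2])), 1L)
    expect_false(a[b$cluster == 1][1] == a[b$cluster == 2][1])

    g2 <- trainSom(b$fp, somRows = 2, somCols = 1, epochs = 10, seed = 5)
    expect_identical(somAssignment(g2), a)
    expect_identical(g2@codebook, g@codebook)

    expect_error(trainSom(matrix(numeric(), 0, 0), seed = 1), "empty")
})

test_that("occupied units are pure for well-separated chemotypes", {
    b <- blockFingerprints(200, 20, bits = 200, seed = 3)
    g <- trainSom(b$fp, epochs = 15, seed = 4)   # default grid rule
    a <- somAssignment(g)
    purity <- vapply(split(b$cluster, a), function(cl)
        max(table(cl)) / length(cl), 0)
    expect_gte(mean(purity), 0.8)
    # occupied-unit member lists partition the library
    expect_equal(sum(vapply(split(names(a), a), length, 0L)), 200L)
    expect_false(anyDuplicated(unlist(split(names(a), a))) > 0)
})

test_that("cluster enrichment finds planted potency structure", {
    b <- blockFingerprints(60, 6, bits = 96, seed = 6)
    g <- trainSom(b$fp, somRows = 3, somCols = 2, epochs = 10, seed = 6)
    a <- somAssignment(g)

    # null: all compounds share the library potency distribution
    set.seed(9)
    potNull <- setNames(rnorm(60, -5.5, 0.5), names(a))
    enrNull <- clusterEnrichment(g, potNull)
    expect_true(all(enrNull$p > 0 & enrNull$p <= 1, na.rm = TRUE))
    expect_lt(max(abs(enrNull$signed_logp), na.rm = TRUE),
              -log10(0.001))

    # planted: one chemotype's members 100-fold more potent
    pot <- potNull
    target <- names(a)[b$cluster == 3]
    pot[target] <- pot[target] - 2
    enr <- clusterEnrichment(g, pot)
    targetUnit <- unitLabels(g)[unique(a[target])]
    hit <- enr[enr$cluster %in% targetUnit, ]
    expect_true(any(hit$p < 0.01))                 # power at size >= 5
    expect_true(all(hit$signed_logp > 0))          # enriched = positive
    others <- enr[!enr$cluster %in% targetUnit, ]
    expect_lt(max(abs(others$signed_logp)), min(hit$signed_logp))

    # the heat map puts the extreme cell at the planted unit
    m <- enrichmentHeatmap(enr, g)
    expect_equal(dim(m), c(3L, 2L))
    peak <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)
    lab <- paste0("k", peak[1, 1], ".", peak[1, 2])
    expect_true(lab %in% targetUnit)
})

test_that("singleton clusters are untestable, never dropped", {
    fp <- rbind(diag(8), diag(8)[1:3, ])   # unit with 1 member possible
    rownames(fp) <- sprintf("C%d", 1:11)
    g <- trainSom(fp, somRows = 4, somCols = 3, epochs = 8, seed = 2)
    pot <- setNames(rnorm(11, -5), rownames(fp))
    enr <- clusterEnrichment(g, pot)
    expect_equal(sum(enr$n_members), 11L)
    if (any(enr$n_members == 1L))
        expect_true(all(enr$untestable[enr$n_members == 1L]))
})

test_that("t-test p-values agree in rank with a permutation oracle", {
    b <- blockFingerprints(30, 3, bits = 64, seed = 8)
    g <- trainSom(b$fp, somRows = 2, somCols = 2, epochs = 10, seed = 8)
    a <- somAssignment(g)
    set.seed(13)
    pot <- setNames(rnorm(30, -5.5, 0.6), names(a))
    pot[b$cluster == 1] <- pot[b$cluster == 1] - 1
    enr <- clusterEnrichment(g, pot)
    testable <- enr[!enr$untestable, ]

    # permutation oracle: label-shuffle null of the member-vs-rest mean gap
    permP <- vapply(seq_len(nrow(testable)), function(i) {
        members <- strsplit(testable$member_ids[i], ";")[[1]]
        m <- length(members)
        obs <- abs(mean(pot[members]) - mean(pot[setdiff(names(pot),
                                                         members)]))
        null <- vapply(seq_len(1e4), function(j) {
            g <- sample(length(pot), m)
            abs(mean(pot[g]) - mean(pot[-g]))
        }, 0)
        (sum(null >= obs) + 1) / (1e4 + 1)
    }, 0)
    expect_gte(cor(rank(testable$p), rank(permP), method = "spearman"),
               0.9)
})

test_that("null libraries keep the cluster false-positive rate near 5%", {
    b <- blockFingerprints(80, 8, bits = 96, seed = 20)
    g <- trainSom(b$fp, somRows = 3, somCols = 3, epochs = 10, seed = 20)
    flags <- unlist(lapply(1:200, function(r) {
        set.seed(3000 + r)
        pot <- setNames(rnorm(80, -5.5, 0.5), g@compoundIds)
        enr <- clusterEnrichment(g, pot)
        enr$p[!enr$untestable] < 0.05
    }))
    expect_lt(abs(mean(flags) - 0.05), 0.02)
})
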