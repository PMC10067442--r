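## Self-organizing-map clustering of chemotype fingerprints and per-cluster
## potency-enrichment testing.

#' Train a batch self-organizing map on fingerprint bits
#'
#' Standard batch SOM on 0/1 fingerprint vectors: the winner is the
#' nearest unit by Euclidean distance, and each epoch recomputes every
#' unit's weight vector as the neighbourhood-weighted mean of the data
#' mapped near it, with a Gaussian neighbourhood whose radius decays
#' geometrically from `max(rows, cols)/2` to 0.5 over the epochs.  The
#' codebook is initialized from seeded random data rows, so identical
#' seeds give identical grids and assignments.  The default grid side is
#' `ceiling(sqrt(5 * sqrt(N)))` (about 14x14 for an 887-compound library,
#' giving on the order of 190 occupied clusters).
#'
#' @param fingerprints 0/1 matrix, one row per compound (see
#'   [fingerprintMatrix()]); rownames are compound ids.
#' @param somRows,somCols grid dimensions (`NULL` = default rule).
#' @param epochs training epochs (default 20).
#' @param seed RNG seed.
#' @return a [SomGrid-class]; unit labels are `"k<row>.<col>"`.
#' @export
trainSom <- function(fingerprints, somRows = NULL, somCols = NULL,
                     epochs = 20, seed) {
    x <- as.matrix(fingerprints)
    if (nrow(x) == 0L || ncol(x) == 0L)
        stop("empty fingerprint matrix")
    seed <- checkSeed(seed)
    n <- nrow(x)
    if (is.null(somRows))
        somRows <- max(1L, ceiling(sqrt(5 * sqrt(n))))
    if (is.null(somCols)) somCols <- somRows
    somRows <- checkCount(somRows, "somRows"); somCols <- checkCount(somCols, "somCols")
    g <- somRows * somCols
    if (g < 2L) stop("the grid needs at least 2 units")
    epochs <- checkCount(epochs, "epochs")

    set.seed(seed)
    init <- x[sample.int(n, g, replace = n < g), , drop = FALSE]
    w <- init + matrix(stats::runif(g * ncol(x), 0, 1e-4), g, ncol(x))

    # squared grid distances between units
    row <- (seq_len(g) - 1L) %/% somCols + 1L
    col <- (seq_len(g) - 1L) %% somCols + 1L
    gridD2 <- outer(row, row, "-")^2 + outer(col, col, "-")^2

    xs2 <- rowSums(x^2)
    bmuOf <- function(w) {
        d <- outer(xs2, rowSums(w^2), "+") - 2 * tcrossprod(x, w)
        max.col(-d, ties.method = "first")
    }
    sigma0 <- max(somRows, somCols) / 2
    sigmaEnd <- 0.5
    for (e in seq_len(epochs)) {
        sigma <- sigma0 * (sigmaEnd / sigma0)^((e - 1) / max(1, epochs - 1))
        bmu <- bmuOf(w)
        h <- exp(-gridD2 / (2 * sigma^2))          # g x g
        cnt <- tabulate(bmu, nbins = g)
        sums <- matrix(0, g, ncol(x))
        agg <- rowsum(x, bmu)
        sums[as.integer(rownames(agg)), ] <- agg
        denom <- as.vector(h %*% cnt)
        num <- h %*% sums
        upd <- denom > 1e-12
        w[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
    }
    methods::new("SomGrid", somRows = somRows, somCols = somCols,
                 codebook = w, assignment = bmuOf(w),
                 compoundIds = if (is.null(rownames(x)))
                     as.character(seq_len(n)) else rownames(x))
}

#' Impute censored potencies for inactive compounds
#'
#' Inactive compounds carry no measurable AC50; for enrichment testing
#' they are imputed at `log10(2 * topConc)`, just above the top tested
#' concentration.
#'
#' @param logAc50 numeric log10 molar potencies, `NA` for inactives.
#' @param topConc top tested final concentration (molar).
#' @return completed log10 potency vector.
#' @export
imputePotency <- function(logAc50, topConc) {
    logAc50[is.na(logAc50)] <- log10(2 * topConc)
    logAc50
}

#' Per-cluster potency enrichment
#'
#' For every occupied SOM unit, a two-sample Welch t-test compares the
#' members' log potencies with the library distribution.  By default the
#' reference leaves the cluster's own members out: sharing members between
#' the two samples distorts the test's size for small clusters, whereas the
#' leave-cluster-out comparison keeps the false-positive rate at its
#' nominal level (set `excludeSelf = FALSE` for the library-average variant
#' that includes the members).  `signed_logp = -log10(p)` signed positive
#' when the cluster
#' is more potent (lower mean log AC50) than the library.  Clusters with
#' fewer than 2 members are reported as untestable, not dropped.
#'
#' @param grid a [SomGrid-class].
#' @param potencies named log10 molar potency vector covering every
#'   compound in the grid (impute censored values first, see
#'   [imputePotency()]).
#' @param day label copied to the output.
#' @param excludeSelf leave-cluster-out reference.
#' @return `data.frame`: `cluster`, `day`, `n_members`, `t`, `p`,
#'   `signed_logp`, `mean_member`, `mean_library`, `untestable`,
#'   `member_ids` (semicolon-joined).
#' @export
clusterEnrichment <- function(grid, potencies, day = "day7",
                              excludeSelf = TRUE) {
    ids <- grid@compoundIds
    miss <- setdiff(ids, names(potencies))
    if (length(miss))
        stop("potency missing for compound(s): ",
             paste(utils::head(miss, 3), collapse = ", "))
    pot <- as.numeric(potencies[ids])
    units <- sort(unique(grid@assignment))
    labels <- unitLabels(grid)
    rows <- lapply(units, function(u) {
        inC <- grid@assignment == u
        member <- pot[inC]
        ref <- if (excludeSelf) pot[!inC] else pot
        untest <- length(member) < 2L || stats::sd(member) == 0 ||
            stats::sd(ref) == 0
        if (!untest) {
            tt <- tryCatch(stats::t.test(member, ref, var.equal = FALSE),
                           error = function(e) NULL)
            untest <- is.null(tt)
        }
        if (untest) {
            t <- NA_real_; p <- NA_real_; slp <- NA_real_
        } else {
            t <- unname(tt$statistic); p <- tt$p.value
            slp <- -log10(max(p, .Machine$double.xmin)) *
                sign(mean(ref) - mean(member))
        }
        data.frame(cluster = labels[u], day = day,
                   n_members = sum(inC), t = t, p = p, signed_logp = slp,
                   mean_member = mean(member), mean_library = mean(ref),
                   untestable = untest,
                   member_ids = paste(ids[inC], collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Signed log-p heat-map matrix over the SOM grid
#'
#' @param enrichments table from [clusterEnrichment()].
#' @param grid the [SomGrid-class] it was computed on.
#' @return `somRows` x `somCols` numeric matrix of `signed_logp`;
#'   unoccupied units are `NA`.
#' @export
enrichmentHeatmap <- function(enrichments, grid) {
    m <- matrix(NA_real_, grid@somRows, grid@somCols,
                dimnames = list(paste0("r", seq_len(grid@somRows)),
                                paste0("c", seq_len(grid@somCols))))
    labels <- unitLabels(grid)
    idx <- match(enrichments$cluster, labels)
    m[cbind((idx - 1L) %/% grid@somCols + 1L,
            (idx - 1L) %% grid@somCols + 1L)] <- enrichments$signed_logp
    m
}
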