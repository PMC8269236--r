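# Independent alignment oracles, written as plain-R dynamic programs (and,
# for tiny inputs, true path enumeration) so they share no code with the
# package's alignment engine. Gap convention: a run of k gap columns costs
# gapOpen + k * gapExtend.

oracleSubScore <- function(a, b, mat) mat[a, b]

# Gotoh three-state global alignment score, end gaps penalized.
oracleGlobalScore <- function(a, b, mat, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
    Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            M[i + 1, j + 1] <- mat[A[i], B[j]] +
                max(M[i, j], X[i, j], Y[i, j])
            X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                                   X[i, j + 1] - ext,
                                   Y[i, j + 1] - open - ext)
            Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                                   Y[i + 1, j] - ext,
                                   X[i + 1, j] - open - ext)
        }
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Smith-Waterman three-state local score (floor at zero).
oracleLocalScore <- function(a, b, mat, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)
    Y <- matrix(NEG, n + 1, m + 1)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            M[i + 1, j + 1] <- max(0, mat[A[i], B[j]] +
                                       max(M[i, j], X[i, j], Y[i, j]))
            X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                                   X[i, j + 1] - ext,
                                   Y[i, j + 1] - open - ext)
            Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                                   Y[i + 1, j] - ext,
                                   X[i + 1, j] - open - ext)
            best <- max(best, M[i + 1, j + 1])
        }
    }
    best
}

# True exhaustive enumeration of all global alignments (monotone paths),
# scoring gap runs by scanning the realized column sequence. Exponential;
# used only at tiny lengths to anchor the DP oracles themselves.
oracleEnumGlobalScore <- function(a, b, mat, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    scorePath <- function(cols) {
        s <- 0
        run <- ""  # current gap-run type: "", "x" (gap in b), "y" (gap in a)
        for (c in cols) {
            if (c[1] != "-" && c[2] != "-") {
                s <- s + mat[c[1], c[2]]
                run <- ""
            } else {
                this <- if (c[2] == "-") "x" else "y"
                s <- s - ext - if (run == this) 0 else open
                run <- this
            }
        }
        s
    }
    recurse <- function(i, j, cols) {
        if (i > length(A) && j > length(B)) return(scorePath(cols))
        best <- -Inf
        if (i <= length(A) && j <= length(B))
            best <- max(best, recurse(i + 1, j + 1,
                                      c(cols, list(c(A[i], B[j])))))
        if (i <= length(A))
            best <- max(best, recurse(i + 1, j, c(cols, list(c(A[i], "-")))))
        if (j <= length(B))
            best <- max(best, recurse(i, j + 1, c(cols, list(c("-", B[j])))))
        best
    }
    recurse(1L, 1L, list())
}

# Local score by enumeration: best global-enumeration score over all
# substring pairs (or the empty alignment).
oracleEnumLocalScore <- function(a, b, mat, open = 11, ext = 1) {
    best <- 0
    for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
        for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
            s <- oracleEnumGlobalScore(substr(a, i1, i2), substr(b, j1, j2),
                                       mat, open, ext)
            best <- max(best, s)
        }
    best
}

# Classical-scaling oracle: explicit double centering + eigendecomposition.
oraclePcoa <- function(D, k) {
    n <- nrow(D)
    A <- -(D^2) / 2
    J <- diag(n) - matrix(1 / n, n, n)
    G <- J %*% A %*% J
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
    pos <- which(e$values > 1e-12)
    k <- min(k, length(pos))
    pts <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
        diag(sqrt(e$values[pos[seq_len(k)]]), k, k)
    list(points = pts, eigenvalues = e$values)
}

blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})
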