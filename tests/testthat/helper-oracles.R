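# Independent brute-force oracles. Each is deliberately naive (enumeration /
# closed form / direct definition) and shares no code with the package paths
# it checks.

# Two-sided binomial p by exhaustive enumeration of all outcomes 0..n.
oracleBinomTwoSided <- function(k, n, q0) {
    probs <- vapply(0:n, function(j)
        choose(n, j) * q0^j * (1 - q0)^(n - j), numeric(1))
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Benjamini-Hochberg by the textbook step-up definition.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 1
    for (i in m:1) {
        running <- min(running, m / i * p[o[i]])
        adj[o[i]] <- running
    }
    adj
}

# Expected unique clones after drawing D templates without replacement from
# a multiset with per-clone counts `counts` (multivariate hypergeometric).
oracleRichnessExpectation <- function(counts, D) {
    N <- sum(counts)
    sum(1 - choose(N - counts, D) / choose(N, D))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all C(n1+n2, n1)
# assignments of the pooled ranks (midranks under ties).
oracleRankSumP <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    n1 <- length(x)
    obs <- sum(r[seq_len(n1)])
    sets <- utils::combn(length(pooled), n1)
    stats <- apply(sets, 2, function(idx) sum(r[idx]))
    center <- n1 * (length(pooled) + 1) / 2
    mean(abs(stats - center) >= abs(obs - center) - 1e-9)
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns of the nonzero deltas.
oracleSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    obs <- sum(r[d > 0])
    center <- n * (n + 1) / 4
    signs <- expand.grid(rep(list(c(0, 1)), n))
    stats <- as.matrix(signs) %*% r
    mean(abs(stats - center) >= abs(obs - center) - 1e-9)
}

# ssGSEA score by direct transcription of the running-sum definition,
# scanning positions one at a time.
oracleSsgsea <- function(exprCol, geneIds, setGenes, tau) {
    r <- unname(rank(exprCol, ties.method = "average"))
    exprCol <- unname(exprCol)
    ord <- order(exprCol, decreasing = TRUE)
    inSet <- geneIds[ord] %in% setGenes
    wAll <- sum(abs(r[ord][inSet])^tau)
    nOut <- sum(!inSet)
    pin <- 0; pout <- 0; es <- 0
    for (i in seq_along(ord)) {
        if (inSet[i]) pin <- pin + abs(r[ord][i])^tau / wAll
        else pout <- pout + 1 / nOut
        es <- es + (pin - pout)
    }
    es
}
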