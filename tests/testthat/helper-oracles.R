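# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph / p.adjust / fisher.test).

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
bruteNE <- function(nodes, edges) {
    n <- length(nodes)
    if (n <= 1) return(0)
    d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
    diag(d) <- 0
    for (i in seq_len(nrow(edges))) {
        a <- edges$pathway_a[i]; b <- edges$pathway_b[i]
        d[a, b] <- 1; d[b, a] <- 1
    }
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    sum(inv) / (n * (n - 1))
}

# Hypergeometric upper tail P(X >= ov) by direct summation of choose() terms:
# X = overlap between a k-gene pathway and an n-gene query in an N-gene universe.
bruteHyperTail <- function(ov, k, n, N) {
    hi <- min(k, n)
    if (ov > hi) return(0)
    sum(vapply(ov:hi, function(x)
        choose(k, x) * choose(N - k, n - x) / choose(N, n), numeric(1)))
}

# Step-up BH: adj_i = min over j >= i (sorted) of p_(j) * m / j, clipped to 1.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m))
        adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- adj
    out
}

# Erdos-Renyi style random PathwayNetwork on n nodes (letters/numbered names).
randomNetwork <- function(n, p = 0.4, seed = 1) {
    set.seed(seed)
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    PathwayNetwork(nodes = nodes,
                   edges = data.frame(pathway_a = pairs[keep, 1],
                                      pathway_b = pairs[keep, 2]))
}

# Complete graph on n nodes.
completeNetwork <- function(n) {
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    PathwayNetwork(edges = data.frame(pathway_a = pairs[, 1],
                                      pathway_b = pairs[, 2]))
}

# Star: hub "h" with the given leaves.
starNetwork <- function(leaves = c("a", "b", "c")) {
    PathwayNetwork(edges = data.frame(pathway_a = "h", pathway_b = leaves))
}

# Ring on n nodes (sparse graph with known structure, cheap to scan).
ringNetwork <- function(n) {
    nodes <- sprintf("N%03d", seq_len(n))
    PathwayNetwork(edges = data.frame(pathway_a = nodes,
                                      pathway_b = nodes[c(2:n, 1)]))
}

# Tiny labelled dataset on the log2 scale, built by hand.
toyLogDataset <- function(values, labels) {
    ExpressionDataset(values, labels, scale = "log2")
}
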