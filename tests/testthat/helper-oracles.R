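# Independent brute-force oracles used to pin down the statistical
# machinery. Each is written from the definition, separately from the
# package implementation it checks.

# two-sided exact Wilcoxon rank-sum p by enumerating every split of the
# pooled values into the two groups (tie-free inputs)
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2L, function(idx) sum(ranks[idx])) -
    n1 * (n1 + 1) / 2
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# two-sided Fisher exact p by direct hypergeometric enumeration
oracle_fisher <- function(k_a, n_a, k_b, n_b) {
  K <- k_a + k_b
  xs <- max(0, K - n_b):min(n_a, K)
  probs <- choose(n_a, xs) * choose(n_b, K - xs) / choose(n_a + n_b, K)
  obs <- probs[xs == k_a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact conditional binomial p by explicit term-by-term computation
oracle_two_library <- function(k1, N1, k2, N2) {
  n <- k1 + k2
  p0 <- N1 / (N1 + N2)
  term <- function(k) {
    # binomial pmf built from a running product, no dbinom
    v <- 1
    if (k > 0) for (i in 1:k) v <- v * (n - k + i) / i * p0
    v * (1 - p0)^(n - k)
  }
  probs <- vapply(0:n, term, numeric(1))
  obs <- probs[k1 + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# upper-tail hypergeometric by direct summation
oracle_hyper_upper <- function(M, m, n, k) {
  js <- k:min(m, n)
  if (length(js) == 0 || k > min(m, n)) return(0)
  sum(choose(m, js) * choose(M - m, n - js) / choose(M, n))
}

# weighted UniFrac by explicit per-branch tabulation of descendant leaf
# sets (recursive descent, independent of the postorder accumulation)
oracle_unifrac <- function(a, b, tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  desc_tips <- function(node) {
    if (node <= n_tip) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- desc_tips(tree$edge[e, 2])
    A <- sum(a[intersect(names(a), leaves)])
    B <- sum(b[intersect(names(b), leaves)])
    num <- num + tree$edge.length[e] * abs(A - B)
    den <- den + tree$edge.length[e] * (A + B)
  }
  if (den == 0) 0 else num / den
}

# all permutations of 1..n, built by a different recursion than the
# package's generator
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in oracle_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# exact permutation p for |PCC| by full enumeration
oracle_perm_pcc <- function(x, y) {
  r_obs <- abs(cor(x, y))
  rs <- vapply(oracle_permutations(length(y)),
               function(p) abs(cor(x, y[p])), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# node degrees by counting incident edges one by one
oracle_degrees <- function(edges, nodes) {
  deg <- setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    deg[edges$source[i]] <- deg[edges$source[i]] + 1L
    deg[edges$target[i]] <- deg[edges$target[i]] + 1L
  }
  deg
}

# small OTU table fixture with known counts
fixture_table <- function(seed = 42, n_otu = 6, n_sample = 4) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otu * n_sample, 20), n_otu, n_sample,
                dimnames = list(sprintf("OTU%02d", 1:n_otu),
                                sprintf("S%02d", 1:n_sample)))
    otu_table(m, taxonomy = sprintf("Bacteria;Genus%02d", 1:n_otu))
  })
}

# minimal hand-built network object for graph-level oracles
fake_network <- function(edges, condition = "healthy") {
  nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(condition = condition,
                 nodes = data.frame(node = nodes,
                                    site = sub(":.*$", "", nodes),
                                    otu_id = sub("^[^:]*:", "", nodes),
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 params = list(r_min = 0.4, p_max = 0.01, n_perm = 0,
                               seed = 1)),
            class = "cooccurrence_network")
}

fake_edges <- function(source, target, r) {
  site <- function(v) sub(":.*$", "", v)
  data.frame(source = source, target = target, r = r,
             p = rep(0.001, length(r)),
             sign = ifelse(r > 0, "positive", "negative"),
             class = ifelse(site(source) != site(target), "inter",
                            paste0("intra_", site(source))),
             stringsAsFactors = FALSE)
}
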