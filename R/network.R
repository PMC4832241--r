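#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return sample correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

# deterministic 31-bit string hash: seeds per-pair permutation streams so
# network construction is independent of node input order
.stable_hash <- function(...) {
  s <- paste(c(...), collapse = "\x1f")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# all permutations of 1..n as an n! x n matrix (n <= 7 in practice)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Permutation p-value for a Pearson correlation
#'
#' Compares `|r(x, y)|` with the distribution of `|r(x, pi(y))|` over
#' permutations `pi`. When `n! <= 10000` all permutations are enumerated and
#' the p-value is the exact null tail probability; otherwise `n_perm` random
#' permutations are drawn and the add-one estimator
#' `(1 + hits) / (n_perm + 1)` is used.
#'
#' @param x,y numeric vectors (length >= 3, non-constant).
#' @param n_perm number of random permutations in the Monte-Carlo branch.
#' @param seed optional integer seed.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, n_perm = 10000, seed = NULL) {
  r_obs <- abs(pearson_r(x, y))
  n <- length(x)
  xs <- scale(x)[, 1L]
  ys <- scale(y)[, 1L]
  thr <- r_obs - 1e-12
  if (factorial(n) <= 10000) {
    perms <- .permutations(n)
    r_all <- abs(apply(perms, 1L, function(p) sum(xs * ys[p]) / (n - 1)))
    return(mean(r_all >= thr))
  }
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      r_p <- abs(sum(xs * ys[sample.int(n)]) / (n - 1))
      if (r_p >= thr) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Subject-paired site-tagged abundance vectors for one condition
#'
#' Builds, for each (site, OTU) with any reads in that condition, the vector
#' of relative abundances across the condition's subjects, ordered by
#' subject id so tongue and saliva vectors are subject-paired.
#'
#' @param table an [otu_table()].
#' @param meta a [sample_metadata()].
#' @param condition `"healthy"` or `"halitosis"`.
#' @return numeric matrix, nodes x subjects; rownames `"site:otu"`.
#' @export
site_otu_vectors <- function(table, meta, condition) {
  stopifnot(condition %in% CONDITIONS)
  validate_metadata(table, meta)
  meta <- meta[meta$sample_id %in% colnames(table$counts), , drop = FALSE]
  sel <- meta[meta$condition == condition, , drop = FALSE]
  subjects <- sort(unique(sel$subject_id))
  ab <- relative_abundance(table)
  rows <- list()
  for (site in SITES) {
    ss <- sel[sel$site == site, , drop = FALSE]
    ss <- ss[match(subjects, ss$subject_id), , drop = FALSE]
    if (anyNA(ss$sample_id))
      stop("every subject needs one ", site, " sample in condition ", condition)
    sub_ab <- ab[, ss$sample_id, drop = FALSE]
    keep <- rowSums(table$counts[, ss$sample_id, drop = FALSE]) > 0
    m <- sub_ab[keep, , drop = FALSE]
    rownames(m) <- paste(site, rownames(m), sep = ":")
    rows[[site]] <- m
  }
  out <- rbind(rows$tongue, rows$saliva)
  colnames(out) <- subjects
  out
}

.node_site <- function(node) sub(":.*$", "", node)

#' Build a condition-specific co-occurrence network
#'
#' Tests every unordered pair of site-tagged OTU nodes with Pearson's
#' correlation; an edge is retained when `|r| > r_min` and the permutation
#' p-value is below `p_max`. Permutations are seeded per pair from the
#' global seed and the lexicographically ordered node ids, so the result
#' does not depend on node input order. Zero-variance nodes are dropped
#' (correlation undefined) with a message.
#'
#' @param vectors matrix from [site_otu_vectors()] (nodes x subjects,
#'   >= 3 subjects).
#' @param condition condition label stored on the network.
#' @param r_min correlation magnitude threshold (default 0.4).
#' @param p_max permutation p-value threshold (default 0.01).
#' @param n_perm permutations per pair (default 10000).
#' @param seed global integer seed.
#' @return object of class `cooccurrence_network`: node table, edge table
#'   (`source`, `target`, `r`, `p`, `sign`, `class`), and parameters.
#' @export
build_network <- function(vectors, condition = "healthy", r_min = 0.4,
                          p_max = 0.01, n_perm = 10000, seed = 1) {
  if (ncol(vectors) < 3) stop("need at least 3 subjects")
  const <- apply(vectors, 1L, stats::sd) == 0
  if (any(const)) {
    message(sprintf("%d zero-variance node(s) dropped", sum(const)))
    vectors <- vectors[!const, , drop = FALSE]
  }
  nodes <- sort(rownames(vectors))
  vectors <- vectors[nodes, , drop = FALSE]
  edges <- list()
  n_nodes <- length(nodes)
  if (n_nodes >= 2) {
    for (i in seq_len(n_nodes - 1L)) {
      xi <- vectors[i, ]
      for (j in (i + 1L):n_nodes) {
        r <- stats::cor(xi, vectors[j, ])
        if (abs(r) <= r_min) next
        p <- permutation_pvalue(xi, vectors[j, ], n_perm = n_perm,
                                seed = .stable_hash(seed, nodes[i], nodes[j]))
        if (p >= p_max) next
        s1 <- .node_site(nodes[i]); s2 <- .node_site(nodes[j])
        cls <- if (s1 != s2) "inter" else paste0("intra_", s1)
        edges[[length(edges) + 1L]] <- data.frame(
          source = nodes[i], target = nodes[j], r = r, p = p,
          sign = if (r > 0) "positive" else "negative",
          class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0), r = numeric(0),
               p = numeric(0), sign = character(0), class = character(0),
               stringsAsFactors = FALSE)
  structure(list(condition = condition,
                 nodes = data.frame(node = nodes, site = .node_site(nodes),
                                    otu_id = sub("^[^:]*:", "", nodes),
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 params = list(r_min = r_min, p_max = p_max, n_perm = n_perm,
                               seed = seed)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network (%s): %d nodes, %d edges\n",
              x$condition, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Count network edges by class and sign
#'
#' Splits edges into inter-site (tongue-saliva) and intra-site classes,
#' positive and negative. Counts always sum to the total edge count.
#'
#' @param net a [build_network()] result.
#' @return named integer vector of the six class counts.
#' @export
classify_edges <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  classes <- c("inter_positive", "inter_negative",
               "intra_tongue_positive", "intra_tongue_negative",
               "intra_saliva_positive", "intra_saliva_negative")
  out <- setNames(integer(length(classes)), classes)
  if (nrow(net$edges)) {
    key <- paste(net$edges$class, net$edges$sign, sep = "_")
    tab <- table(key)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Hub nodes of a co-occurrence network
#'
#' Nodes whose degree strictly exceeds `min_degree` (the ">30 linkages"
#' rule), sorted by decreasing degree.
#'
#' @param net a [build_network()] result.
#' @param min_degree strict degree threshold (default 30).
#' @return data.frame with `node`, `site`, `degree`.
#' @export
hub_nodes <- function(net, min_degree = 30) {
  stopifnot(inherits(net, "cooccurrence_network"))
  deg <- node_degrees(net)
  hubs <- deg[deg$degree > min_degree, , drop = FALSE]
  hubs[order(-hubs$degree, hubs$node), , drop = FALSE]
}

#' Degree of every node in a network
#' @param net a [build_network()] result.
#' @return data.frame with `node`, `site`, `degree`.
#' @export
node_degrees <- function(net) {
  counts <- table(factor(c(net$edges$source, net$edges$target),
                         levels = net$nodes$node))
  data.frame(node = net$nodes$node, site = net$nodes$site,
             degree = as.integer(counts[net$nodes$node]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a network as an edge-list TSV and GraphML
#'
#' Writes `<prefix>_edges.tsv` (source, target, r, p, sign, class),
#' importable by Cytoscape, and `<prefix>.graphml` with node attributes
#' `site` and `degree`.
#'
#' @param net a [build_network()] result.
#' @param prefix output path prefix.
#' @return invisible character vector of the two paths written.
#' @export
export_network <- function(net, prefix) {
  stopifnot(inherits(net, "cooccurrence_network"))
  edge_path <- paste0(prefix, "_edges.tsv")
  graphml_path <- paste0(prefix, ".graphml")
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg <- node_degrees(net)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "r", "p", "sign", "class")],
    directed = FALSE, vertices = deg)
  igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(c(edge_path, graphml_path))
}

#' Read a network edge list written by [export_network()]
#' @param path edge-list TSV path.
#' @return edge data.frame.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
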