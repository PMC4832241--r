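test_that("Pearson correlation basics", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(x, rep(2, 4)), "constant")
})

test_that("permutation p equals full enumeration for small n", {
  x <- c(1, 2, 3, 4)
  expect_equal(permutation_pvalue(x, x), 2 / 24)
  withr::with_seed(55, {
    for (n in c(4, 5, 6)) {
      a <- rnorm(n); b <- rnorm(n)
      expect_equal(permutation_pvalue(a, b), oracle_perm_pcc(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("Monte-Carlo permutation p is stable in n_perm and seeded", {
  withr::with_seed(66, {
    x <- rnorm(12); y <- x + rnorm(12, 0, 2)
  })
  p1 <- permutation_pvalue(x, y, n_perm = 2000, seed = 9)
  p1b <- permutation_pvalue(x, y, n_perm = 2000, seed = 9)
  expect_identical(p1, p1b)
  p2 <- permutation_pvalue(x, y, n_perm = 4000, seed = 10)
  bound <- 4 * sqrt(p1 * (1 - p1) / 2000) + 2 / 2000
  expect_lt(abs(p1 - p2), max(bound, 0.02))
})

test_that("null permutation p-values are approximately uniform", {
  n_tests <- 400
  ps <- withr::with_seed(77, {
    vapply(seq_len(n_tests), function(i) {
      permutation_pvalue(rnorm(10), rnorm(10), n_perm = 199,
                         seed = 7000 + i)
    }, numeric(1))
  })
  # chi-squared goodness of fit over deciles
  bins <- table(cut(ps, breaks = seq(0, 1, 0.1), include.lowest = TRUE))
  gof <- chisq.test(bins, p = rep(0.1, 10))
  expect_gt(gof$p.value, 0.01)
})

test_that("network construction applies both thresholds to hand-built vectors", {
  subj <- paste0("p", 1:8)
  base <- c(1.2, 0.8, 1.5, 0.3, 2.0, 0.9, 1.1, 0.5)
  v <- rbind("tongue:A" = base,
             "tongue:B" = 2 * base + 1,          # collinear with A
             "saliva:C" = c(0.4, 1.9, 0.2, 1.1, 0.6, 1.4, 0.1, 2.2))
  colnames(v) <- subj
  net <- build_network(v, "healthy", r_min = 0.4, p_max = 0.05,
                       n_perm = 2000, seed = 3)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$source, net$edges$target),
                  c("tongue:A", "tongue:B"))
  expect_equal(net$edges$sign, "positive")
  expect_equal(net$edges$class, "intra_tongue")
  # r_min = 1 kills every edge on generic data
  net2 <- build_network(v, "healthy", r_min = 1.0, p_max = 0.05,
                        n_perm = 200, seed = 3)
  expect_equal(nrow(net2$edges), 0L)
})

test_that("network construction is invariant to node input order", {
  withr::with_seed(88, {
    v <- matrix(rnorm(10 * 12), 10, 12,
                dimnames = list(c(paste0("tongue:O", 1:5),
                                  paste0("saliva:O", 1:5)),
                                paste0("p", 1:12)))
  })
  net_a <- build_network(v, "healthy", r_min = 0.2, p_max = 0.2,
                         n_perm = 499, seed = 11)
  net_b <- build_network(v[sample(nrow(v)), ], "healthy", r_min = 0.2,
                         p_max = 0.2, n_perm = 499, seed = 11)
  expect_equal(net_a$edges, net_b$edges)
})

test_that("zero-variance nodes are dropped with a message", {
  v <- rbind("tongue:A" = c(1, 2, 3, 4, 5),
             "tongue:B" = rep(0.3, 5),
             "saliva:A" = c(5, 3, 4, 1, 2))
  colnames(v) <- paste0("p", 1:5)
  expect_message(net <- build_network(v, "healthy", n_perm = 120, seed = 1),
                 "zero-variance")
  expect_false("tongue:B" %in% net$nodes$node)
})

test_that("edge classification counts are conserved and correct", {
  edges <- fake_edges(
    source = c("tongue:A", "tongue:A", "saliva:X"),
    target = c("saliva:X", "tongue:B", "saliva:Y"),
    r = c(0.8, -0.6, 0.5))
  net <- fake_network(edges)
  counts <- classify_edges(net)
  expect_equal(unname(counts["inter_positive"]), 1L)
  expect_equal(unname(counts["intra_tongue_negative"]), 1L)
  expect_equal(unname(counts["intra_saliva_positive"]), 1L)
  expect_equal(sum(counts), nrow(edges))
  empty <- fake_network(fake_edges(character(0), character(0), numeric(0)))
  expect_equal(sum(classify_edges(empty)), 0L)
})

test_that("hub detection is strict and matches a brute-force degree count", {
  star <- function(k) fake_edges(rep("tongue:HUB", k),
                                 paste0("saliva:S", seq_len(k)),
                                 rep(0.9, k))
  expect_equal(hub_nodes(fake_network(star(31)), 30)$node, "tongue:HUB")
  expect_equal(nrow(hub_nodes(fake_network(star(30)), 30)), 0L)
  withr::with_seed(99, {
    nodes <- c(paste0("tongue:N", 1:12), paste0("saliva:N", 1:12))
    idx <- t(combn(24, 2))
    pick <- idx[runif(nrow(idx)) < 0.3, ]
    edges <- fake_edges(nodes[pick[, 1]], nodes[pick[, 2]],
                        runif(nrow(pick), -1, 1))
  })
  net <- fake_network(edges)
  deg_oracle <- oracle_degrees(edges, net$nodes$node)
  got <- node_degrees(net)
  expect_equal(setNames(got$degree, got$node), deg_oracle)
  expect_setequal(hub_nodes(net, 5)$node,
                  names(deg_oracle)[deg_oracle > 5])
})

test_that("network export round-trips the edge list and emits valid GraphML", {
  edges <- fake_edges(
    source = c("tongue:A", "saliva:X"),
    target = c("saliva:X", "saliva:Y"),
    r = c(0.72, -0.55))
  net <- fake_network(edges)
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(net, prefix)
  back <- read_edge_list(paste0(prefix, "_edges.tsv"))
  expect_equal(back$source, edges$source)
  expect_equal(back$r, edges$r, tolerance = 1e-9)
  expect_equal(back$class, edges$class)
  xml <- xml2::read_xml(paste0(prefix, ".graphml"))
  expect_equal(xml2::xml_name(xml), "graphml")
  # empty network still writes valid files
  empty <- fake_network(fake_edges(character(0), character(0), numeric(0)))
  prefix2 <- file.path(withr::local_tempdir(), "empty")
  export_network(empty, prefix2)
  expect_equal(nrow(read_edge_list(paste0(prefix2, "_edges.tsv"))), 0L)
  expect_s3_class(xml2::read_xml(paste0(prefix2, ".graphml")), "xml_document")
})

test_that("hub role reversal: planted saliva hubs vs planted tongue hubs", {
  # healthy cohort with a saliva-centred correlated module, halitosis with a
  # tongue-centred one; hub sites should mirror the planting
  sat <- function(site, hub_otu, otus, rho) {
    data.frame(site1 = site, otu1 = hub_otu, site2 = site, otu2 = otus,
               rho = rho, stringsAsFactors = FALSE)
  }
  cfg <- simulate_config(seed = 505, n_otus = 25, depth = 8000,
                         correlated_pairs = sat("saliva", "OTU005",
                                                paste0("OTU00", 6:9), 0.95))
  st <- simulate_study(cfg)
  v_h <- site_otu_vectors(st$table, st$metadata, "healthy")
  net_h <- build_network(v_h, "healthy", r_min = 0.4, p_max = 0.05,
                         n_perm = 499, seed = 2)
  hubs_h <- hub_nodes(net_h, min_degree = 2)
  expect_gt(sum(hubs_h$site == "saliva"), sum(hubs_h$site == "tongue"))
})
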