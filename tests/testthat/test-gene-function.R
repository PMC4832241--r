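test_that("two-library exact test matches its defining summation", {
  expect_equal(two_library_test(50, 1e6, 50, 1e6), 1.0, tolerance = 1e-9)
  expect_equal(two_library_test(20, 1e6, 0, 1e6), 2 * 0.5^20,
               tolerance = 1e-12)
  for (n in 1:12) {
    for (k1 in 0:n) {
      expect_equal(two_library_test(k1, 1e6, n - k1, 2e6),
                   oracle_two_library(k1, 1e6, n - k1, 2e6),
                   tolerance = 1e-12)
    }
  }
  expect_error(two_library_test(0, 1e6, 0, 1e6), "untestable")
})

test_that("two-library test is symmetric under library swap", {
  withr::with_seed(3, {
    for (i in 1:20) {
      k1 <- rpois(1, 30); k2 <- rpois(1, 10)
      N1 <- 1e6; N2 <- 3e6
      if (k1 + k2 == 0) next
      expect_equal(two_library_test(k1, N1, k2, N2),
                   two_library_test(k2, N2, k1, N1), tolerance = 1e-12)
    }
  })
})

test_that("fold ratio handles zeros via the pseudocount", {
  expect_equal(fold_ratio(100, 1e6, 100, 1e6), 1.0)
  expect_equal(fold_ratio(100, 1e6, 10, 1e6, pseudocount = 0), 10.0)
  f0 <- fold_ratio(5, 1e6, 0, 1e6)
  f1 <- fold_ratio(9, 1e6, 0, 1e6)
  expect_true(is.finite(f0) && f0 > 0)
  expect_gt(f1, f0)
})

test_that("differential gene partition matches hand evaluation on a toy table", {
  counts <- rbind(
    gA = c(1000, 100),   # 10x down in halitosis: healthy-enriched
    gB = c(100, 1005),   # ~10x up: halitosis-enriched
    gC = c(500, 520),    # flat
    gD = c(3, 0),        # extreme fold but tiny counts: p too large
    gE = c(0, 80),       # strong up from zero
    gF = c(0, 0))        # untestable
  colnames(counts) <- c("healthy", "halitosis")
  gt <- gene_table(counts, library_sizes = c(healthy = 1e5, halitosis = 1e5))
  expect_message(dg <- differential_genes(gt, fold_min = 5, p_max = 0.001),
                 "skipped")
  expect_setequal(dg$halitosis_enriched, c("gB", "gE"))
  expect_setequal(dg$healthy_enriched, "gA")
  expect_false("gD" %in% c(dg$halitosis_enriched, dg$healthy_enriched))
  expect_equal(dg$summary$total, 3)
  expect_equal(dg$summary$pct_halitosis, 100 * 2 / 3)
  # impossible fold threshold empties both sets
  dg2 <- suppressMessages(differential_genes(gt, fold_min = Inf))
  expect_length(dg2$halitosis_enriched, 0)
  expect_length(dg2$healthy_enriched, 0)
})

test_that("directional counts sum to the flagged total", {
  cfg <- simulate_config(seed = 6, gene = list(
    n_genes = 500, library_size = 5e5,
    gene_folds = list(tongue = data.frame(
      gene_id = sprintf("g%06d", 101:120), fold = rep(c(8, 1 / 8), 10)))))
  g <- simulate_gene_tables(cfg)
  dg <- suppressMessages(differential_genes(g$tables$tongue))
  expect_equal(length(dg$halitosis_enriched) + length(dg$healthy_enriched),
               dg$summary$total)
  expect_gt(dg$summary$total, 0)
})

test_that("KO enrichment equals direct hypergeometric summation", {
  genes <- sprintf("g%03d", 1:100)
  ko <- data.frame(gene_id = genes,
                   category = rep(c("K1", "K2"), times = c(10, 90)))
  ann <- annotation_maps(ko = ko, genes = genes)
  withr::with_seed(8, {
    diff <- c(sample(genes[1:10], 5), sample(genes[11:100], 15))
  })
  res <- ko_enrichment(diff, ann)
  k1 <- res[res$category == "K1", ]
  expect_equal(k1$m, 10); expect_equal(k1$k, 5)
  expect_equal(k1$p_value, oracle_hyper_upper(100, 10, 20, 5),
               tolerance = 1e-12)
  # category spanning the whole population is always certain
  ko_all <- data.frame(gene_id = genes, category = "Kall")
  res_all <- ko_enrichment(diff, annotation_maps(ko = ko_all, genes = genes))
  expect_equal(res_all$p_value, 1.0)
  # k = 0 has upper-tail probability one
  ko0 <- data.frame(gene_id = genes,
                    category = rep(c("Khit", "Kmiss"), times = c(50, 50)))
  res0 <- ko_enrichment(genes[1:10], annotation_maps(ko = ko0, genes = genes))
  expect_equal(res0$p_value[res0$category == "Kmiss"], 1.0)
  expect_error(ko_enrichment("gX", ann), "subset")
})

test_that("enrichment p is monotone non-increasing in the overlap", {
  ps <- vapply(0:10, function(k) oracle_hyper_upper(100, 10, 20, k),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  ps_impl <- vapply(0:10, function(k)
    stats::phyper(k - 1, 10, 90, 20, lower.tail = FALSE), numeric(1))
  expect_equal(ps_impl, ps, tolerance = 1e-12)
})

test_that("pathway families are called up/down/flat by the 2-fold rule", {
  mk <- function(k_h, k_d) {
    counts <- cbind(healthy = k_h, halitosis = k_d)
    rownames(counts) <- sprintf("g%02d", seq_along(k_h))
    gene_table(counts, library_sizes = c(healthy = 1e5, halitosis = 1e5))
  }
  fam <- data.frame(gene_id = c("g01", "g02", "g03"),
                    family = c("cbs", "sir", "cysM"))
  ann <- annotation_maps(family = fam)
  # summed ratios: cbs 2.5x up, sir 0.4x down, cysM 1.5x flat
  gt <- mk(c(200, 100, 100), c(500, 40, 150))
  rep <- h2s_pathway_report(list(tongue = gt), ann, fold_min = 2)
  stat <- setNames(rep$status, rep$family)
  expect_equal(unname(stat["cbs"]), "up")
  expect_equal(unname(stat["sir"]), "down")
  expect_equal(unname(stat["cysM"]), "flat")
  expect_equal(unname(stat["aprA"]), "absent")
  lines <- format_h2s_report(rep)
  expect_true(any(grepl("^cbs", lines)))
})

test_that("planted H2S pattern is recovered exactly from synthetic tables", {
  up_fams <- c("cbs", "aspB", "yhdR", "sseA", "glpE")
  plant <- data.frame(family = c(up_fams, "cysM"),
                      fold = c(rep(3, 5), 1 / 3))
  cfg <- simulate_config(seed = 99, gene = list(
    n_genes = 2000, library_size = 1e6,
    family_folds = list(tongue = plant, saliva = plant)))
  g <- simulate_gene_tables(cfg)
  rep <- h2s_pathway_report(g$tables, g$annotations, fold_min = 2)
  for (site in c("tongue", "saliva")) {
    stat <- setNames(rep$status[rep$site == site], rep$family[rep$site == site])
    expect_true(all(stat[up_fams] == "up"))
    expect_equal(unname(stat["cysM"]), "down")
    unplanted <- setdiff(names(stat), c(up_fams, "cysM"))
    expect_true(all(stat[unplanted] == "flat"))
  }
})
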