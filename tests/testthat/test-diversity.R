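test_that("rarefaction keeps exhaustive samples, drops shallow ones", {
  m <- matrix(c(60, 40, 0, 120, 50, 30, 10, 90, 80), 3, 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  tab <- otu_table(m)
  r <- rarefy(tab, depth = 100, seed = 1)
  expect_equal(r$counts[, "s1"], c(A = 60L, B = 40L, C = 0L))
  expect_true(all(colSums(r$counts) == 100L))
  expect_warning(r2 <- rarefy(tab, depth = 150, seed = 1), "dropped")
  expect_false("s1" %in% colnames(r2$counts))
  expect_error(rarefy(tab, depth = 1000), "every sample")
})

test_that("rarefied richness matches the hypergeometric expectation", {
  counts <- c(40, 25, 12, 8, 5, 4, 3, 2, 1)
  names(counts) <- paste0("O", seq_along(counts))
  tab <- otu_table(matrix(counts, ncol = 1,
                          dimnames = list(names(counts), "s1")))
  T_tot <- sum(counts); d <- 30
  # closed form: E[S] = sum_i 1 - C(T - c_i, d) / C(T, d)
  expected <- sum(1 - choose(T_tot - counts, d) / choose(T_tot, d))
  obs <- withr::with_seed(99, {
    mean(replicate(1000, {
      r <- rarefy(tab, depth = d)
      observed_otus(r$counts[, 1])
    }))
  })
  expect_lt(abs(obs - expected), 0.15)
})

test_that("Chao1 follows the bias-corrected formula", {
  expect_equal(chao1(c(5, 3, 2)), 3.0)
  expect_equal(chao1(c(1, 1, 2, 3)), 4.5)
  expect_error(chao1(c(0, 0)), "all-zero")
  withr::with_seed(17, {
    for (i in 1:20) {
      x <- rpois(30, 2)
      if (all(x == 0)) next
      expect_gte(chao1(x), observed_otus(x))
    }
  })
})

test_that("weighted UniFrac matches its defining branch sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
  a <- c(A = 0.5, B = 0.5, C = 0)
  b <- c(A = 0, B = 0, C = 1)
  expect_equal(weighted_unifrac(a, a, tr), 0)
  expect_equal(weighted_unifrac(a, b, tr), oracle_unifrac(a, b, tr))
  two <- ape::read.tree(text = "(A:1,B:1):0;")
  expect_equal(weighted_unifrac(c(A = 1, B = 0), c(A = 0, B = 1), two), 1)
  expect_error(weighted_unifrac(c(A = 0.5, Z = 0.5), c(A = 1, B = 0), two),
               "Z")
})

test_that("weighted UniFrac agrees with the brute-force oracle on random trees", {
  withr::with_seed(31, {
    for (i in 1:5) {
      tr <- ape::rtree(8, br = function(n) rexp(n, 2))
      a <- runif(8); a <- a / sum(a); names(a) <- tr$tip.label
      b <- runif(8); b <- b / sum(b); names(b) <- tr$tip.label
      expect_equal(weighted_unifrac(a, b, tr), oracle_unifrac(a, b, tr),
                   tolerance = 1e-10)
      expect_equal(weighted_unifrac(a, b, tr), weighted_unifrac(b, a, tr))
    }
  })
})

test_that("weighted UniFrac satisfies the triangle inequality numerically", {
  withr::with_seed(77, {
    tr <- ape::rtree(10, br = function(n) rexp(n, 2))
    abc <- lapply(1:3, function(i) {
      v <- runif(10); v <- v / sum(v); names(v) <- tr$tip.label; v
    })
    dab <- weighted_unifrac(abc[[1]], abc[[2]], tr)
    dbc <- weighted_unifrac(abc[[2]], abc[[3]], tr)
    dac <- weighted_unifrac(abc[[1]], abc[[3]], tr)
    expect_lte(dac, dab + dbc + 1e-12)
    expect_true(all(c(dab, dbc, dac) >= 0 & c(dab, dbc, dac) <= 1))
  })
})

test_that("AMOVA p-value matches exhaustive relabelling on 6 samples", {
  withr::with_seed(11, {
    pts <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 1.2), 3, 2))
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  })
  grp <- setNames(rep(c("g1", "g2"), each = 3), rownames(dm))
  res <- amova(dm, grp, n_perm = 9999, seed = 2)
  # exact reference: all C(6,3) = 20 assignments of labels to samples
  f_stat <- function(groups) halimicro:::.amova_f(dm^2, groups)
  f_obs <- f_stat(grp)
  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    g <- rep("g2", 6); g[idx] <- "g1"
    f_stat(g)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.05)
  expect_equal(res$f, f_obs)
})

test_that("AMOVA degenerates to p = 1 on equal distances and detects structure", {
  dm <- matrix(1, 6, 6) - diag(6)
  dimnames(dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  grp <- setNames(rep(c("a", "b"), each = 3), rownames(dm))
  expect_equal(amova(dm, grp, n_perm = 99, seed = 1)$p_value, 1.0)
  expect_error(amova(dm, setNames(c("a", rep("b", 5)), rownames(dm)),
                     n_perm = 9), "at least two samples")
  # two well-separated clusters
  withr::with_seed(5, {
    pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                 matrix(rnorm(10, 5, 0.1), 5, 2))
    dm2 <- as.matrix(dist(pts))
    dimnames(dm2) <- list(paste0("s", 1:10), paste0("s", 1:10))
  })
  grp2 <- setNames(rep(c("a", "b"), each = 5), rownames(dm2))
  expect_lte(amova(dm2, grp2, n_perm = 999, seed = 3)$p_value, 0.05)
})

test_that("alpha-diversity group test behaves at the edges", {
  expect_equal(alpha_group_test(c(3, 3, 3), c(3, 3, 3)), 1.0)
  expect_lt(alpha_group_test(c(0, 0, 0), c(10, 10, 10.0001)), 0.001)
  x <- c(1.2, 3.1, 2.2, 4.0)
  expect_equal(alpha_group_test(x, x), 1.0, tolerance = 1e-12)
})

test_that("planted extra richness raises halitosis tongue alpha diversity", {
  cfg <- simulate_config(seed = 60, n_otus = 120, depth = 10000,
                         richness_delta = 50, richness_relab = 1e-3)
  st <- simulate_study(cfg)
  r <- rarefy(st$table, depth = 7180, seed = 1)
  adiv <- merge(alpha_diversity(r), as.data.frame(st$metadata),
                by = "sample_id")
  tong <- adiv[adiv$site == "tongue", ]
  obs_h <- tong$observed_otus[tong$condition == "healthy"]
  obs_d <- tong$observed_otus[tong$condition == "halitosis"]
  expect_gt(mean(obs_d), mean(obs_h))
  expect_lt(alpha_group_test(obs_h, obs_d), 0.05)
  chao_h <- tong$chao1[tong$condition == "healthy"]
  chao_d <- tong$chao1[tong$condition == "halitosis"]
  expect_gt(mean(chao_d), mean(chao_h))
})
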