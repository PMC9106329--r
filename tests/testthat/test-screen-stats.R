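nt_only_library <- function(n_nt, n_target = 2) {
  cfg <- sim_config(n_genes = n_target, sgrnas_per_gene = 1,
                    n_pos_controls = 0, n_nt = n_nt, seed = 11)
  make_library(cfg)
}

small_cfg <- screen_config(min_nt = 2, n_permutations = 200, seed = 1)

test_that("NT median-of-ratios normalization matches direct computation", {
  lib <- nt_only_library(5)
  nt_ids <- lib$guide_id[lib$category == "non_targeting"]
  cm <- tibble(guide_id = lib$guide_id,
               s1 = c(100L, 7L, 10L, 25L, 40L, 55L, 12L),
               s2 = c(50L, 9L, 22L, 48L, 85L, 100L, 30L))
  norm <- normalize_counts(cm, lib, small_cfg)
  # direct median-of-ratios over NT rows only
  nt <- as.matrix(cm[cm$guide_id %in% nt_ids, c("s1", "s2")])
  geo <- sqrt(nt[, 1] * nt[, 2])
  expected <- apply(nt / geo, 2, median)
  expect_equal(unname(norm$size_factors), unname(expected))
  expect_equal(norm$matrix$s1, cm$s1 / expected[["s1"]])
})

test_that("proportional and identical columns give the expected factors", {
  lib <- nt_only_library(20, n_target = 1)
  n <- nrow(lib)
  base <- as.integer(10 + seq_len(n) * 3)
  cm <- tibble(guide_id = lib$guide_id, s1 = base, s2 = 2L * base)
  norm <- normalize_counts(cm, lib, small_cfg)
  sf <- unname(norm$size_factors)
  expect_equal(sf[2] / sf[1], 2)
  nt_rows <- lib$category == "non_targeting"
  expect_equal(norm$matrix$s1[nt_rows], norm$matrix$s2[nt_rows])
  cm2 <- tibble(guide_id = lib$guide_id, s1 = base, s2 = base)
  expect_equal(unname(normalize_counts(cm2, lib, small_cfg)$size_factors),
               c(1, 1))
  # guard: too few usable NT guides
  lib3 <- nt_only_library(3)
  cm3 <- tibble(guide_id = lib3$guide_id,
                s1 = rep(10L, nrow(lib3)), s2 = rep(10L, nrow(lib3)))
  expect_error(normalize_counts(cm3, lib3, screen_config(min_nt = 20)),
               "non-targeting")
})

test_that("mean-variance fit recovers Poisson and NB noise structure", {
  lib <- nt_only_library(2000)
  nt_rows <- lib$category == "non_targeting"
  mu <- exp(runif(nrow(lib), log(50), log(5000)))
  withr::with_seed(101, {
    cm <- tibble(guide_id = lib$guide_id,
                 s1 = rpois(nrow(lib), mu), s2 = rpois(nrow(lib), mu))
  })
  norm <- list(matrix = mutate(cm, s1 = as.numeric(s1), s2 = as.numeric(s2)),
               size_factors = c(s1 = 1, s2 = 1), pseudocount = 0.5)
  fit <- fit_mean_variance(norm, lib, c("s1", "s2"))
  # Poisson: predicted variance stays within 20% of the mean
  test_mu <- c(100, 500, 2000)
  expect_true(all(abs(predict_null_variance(fit, test_mu) / test_mu - 1)
                  < 0.2))

  withr::with_seed(102, {
    cmnb <- tibble(guide_id = lib$guide_id,
                   s1 = rnbinom(nrow(lib), mu = mu, size = 10),
                   s2 = rnbinom(nrow(lib), mu = mu, size = 10))
  })
  normnb <- list(matrix = mutate(cmnb, s1 = as.numeric(s1),
                                 s2 = as.numeric(s2)),
                 size_factors = c(s1 = 1, s2 = 1), pseudocount = 0.5)
  fitnb <- fit_mean_variance(normnb, lib, c("s1", "s2"))
  # var = mu + 0.1 mu^2  =>  b ~ 2, k ~ 0.1
  expect_lt(abs(fitnb$b - 2), 0.3)
  expect_lt(abs(fitnb$k - 0.1), 0.05)

  # guard: too few NT guides
  lib3 <- nt_only_library(3)
  norm3 <- list(matrix = tibble(guide_id = lib3$guide_id,
                                s1 = rep(10, nrow(lib3)),
                                s2 = rep(12, nrow(lib3))),
                size_factors = c(s1 = 1, s2 = 1), pseudocount = 0.5)
  expect_error(fit_mean_variance(norm3, lib3, c("s1", "s2")), "20")
})

test_that("sgRNA tails reduce to exact Poisson when k = 0", {
  lib <- tiny_library()
  norm <- list(matrix = tibble(guide_id = lib$guide_id,
                               c = c(200, 50, 10), t = c(200, 500, 3)),
               size_factors = c(c = 1, t = 1), pseudocount = 0.5)
  model <- mean_var_model(k = 0, b = 2)
  st <- sgrna_test(norm, model, "c", "t", lib, small_cfg)
  expect_equal(st$p_enrich,
               ppois(round(norm$matrix$t) - 1, norm$matrix$c,
                     lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(st$p_deplete, ppois(round(norm$matrix$t), norm$matrix$c),
               tolerance = 1e-12)
  # t = c = 200: both tails near 1/2 and they sum to 1 + P(X = 200)
  expect_equal(st$p_enrich[1] + st$p_deplete[1], 1 + dpois(200, 200))
  expect_true(st$p_enrich[1] > 0.4 && st$p_enrich[1] < 0.6)
  expect_true(st$p_deplete[1] > 0.4 && st$p_deplete[1] < 0.6)
})

test_that("enrichment p-values fall monotonically as treatment grows", {
  lib <- guide_library(sprintf("g%d", 1:5),
                       c(strrep("A", 19), strrep("C", 19), strrep("G", 19),
                         strrep("T", 19), paste0(strrep("A", 18), "C")),
                       sprintf("gene%d", 1:5), rep("rbp_target", 5))
  norm <- list(matrix = tibble(guide_id = lib$guide_id,
                               c = rep(100, 5),
                               t = c(100, 200, 400, 1000, 4000)),
               size_factors = c(c = 1, t = 1), pseudocount = 0.5)
  st <- sgrna_test(norm, mean_var_model(k = 0.05, b = 2), "c", "t", lib,
                   small_cfg)
  expect_true(all(diff(st$p_enrich) < 0))
  expect_true(all(st$p_enrich[-1] < st$p_deplete[-1]))
  # ranks are a permutation within each direction
  expect_setequal(st$rank_enrich, 1:5)
  expect_setequal(st$rank_deplete, 1:5)
})

test_that("alpha-RRA reproduces closed-form order-statistic values", {
  # one guide, selected at u = 0.01: Beta(1,1) CDF is the identity
  expect_equal(alpha_rra_score(p = 0.01, rank = 1, n_total = 100), 0.01)
  # two guides at u = (0.01, 0.02): min of Beta(1,2), Beta(2,1) CDFs
  s <- alpha_rra_score(p = c(0.01, 0.01), rank = c(1, 2), n_total = 100)
  expect_equal(s, min(1 - 0.99^2, 0.02^2))
  # nothing selected scores 1
  expect_equal(alpha_rra_score(p = c(0.5, 0.9), rank = c(50, 90),
                               n_total = 100), 1)
  expect_error(alpha_rra_score(numeric(0), integer(0), 10), "at least one")
})

test_that("alpha-RRA agrees with the brute-force oracle on random cases", {
  withr::with_seed(42, {
    for (i in 1:200) {
      m <- sample(1:12, 1)
      n_total <- sample(200:2000, 1)
      rank <- sample(n_total, m)
      p <- runif(m, 0, 0.2)
      expect_equal(alpha_rra_score(p, rank, n_total, 0.05),
                   rra_bruteforce(p, rank, n_total, 0.05),
                   tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment matches the step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  # order preserved
  expect_equal(bh_fdr(c(0.04, 0.001)), rev(bh_fdr(c(0.001, 0.04))))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene LFC is the same-direction median and z is NT-referenced", {
  r <- gene_lfc_and_z(c(1.0, 1.2, 1.4, -0.2), "positive",
                      nt_lfcs = rnorm(100))
  expect_equal(r$gene_lfc, 1.2)
  r2 <- gene_lfc_and_z(c(1.2, 1.2), "positive",
                       nt_lfcs = c(-0.5, 0.5, -0.5, 0.5))
  expect_equal(r2$z, 1.2 / sd(c(-0.5, 0.5, -0.5, 0.5)))
  # gene LFC equal to the NT mean gives z = 0
  r3 <- gene_lfc_and_z(c(0.3, 0.3), "positive",
                       nt_lfcs = c(0.1, 0.3, 0.5))
  expect_equal(r3$z, 0)
  # no guide in the requested direction -> flagged zero
  r4 <- gene_lfc_and_z(c(-1, -2), "positive", nt_lfcs = c(-0.5, 0.5))
  expect_true(r4$flagged)
  expect_equal(c(r4$gene_lfc, r4$z), c(0, 0))
  expect_error(gene_lfc_and_z(1, "positive", nt_lfcs = c(0.2, 0.2)),
               "zero")
})

test_that("the hit rule is inclusive on z and exclusive on FDR", {
  res <- tibble(gene = c("a", "b", "c", "d"),
                z = c(2.0, 1.9, -3.0, -2.5),
                fdr = c(0.049, 0.001, 0.2, 0.05))
  hits <- call_hits(res, screen_config())
  expect_equal(hits$is_hit, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("permutation p-values hit their floor and ceiling", {
  cfg <- sim_config(n_genes = 12, n_pos_controls = 0, n_nt = 60, seed = 7)
  lib <- make_library(cfg)
  eff <- tibble(gene = "RBP0001", expansion_effect = 0,
                accumulation_effect = -3)
  cm <- simulate_screen_counts(lib, eff, cfg)
  res <- screen_test(cm, lib, "cd138neg", "cd138pos",
                     screen_config(n_permutations = 500, seed = 3))
  g <- res$gene
  # the strong planted gene reaches the floor 1/(n+1)
  expect_equal(g$p_perm[g$gene == "RBP0001"], 1 / 501)
  expect_equal(g$direction[g$gene == "RBP0001"], "negative")
  # a gene with score 1 (no selected guides) has p_perm = 1
  if (any(g$rra_score == 1)) {
    expect_true(all(g$p_perm[g$rra_score == 1] == 1))
  }
  expect_true(all(g$p_perm >= 1 / 501 & g$p_perm <= 1))
})

test_that("identical config and seed give identical result tables", {
  cfg <- sim_config(n_genes = 15, n_pos_controls = 0, n_nt = 60, seed = 8)
  lib <- make_library(cfg)
  cm <- simulate_screen_counts(lib, NULL, cfg)
  sc <- screen_config(n_permutations = 300, seed = 17)
  r1 <- screen_test(cm, lib, "day4", "day8", sc)
  r2 <- screen_test(cm, lib, "day4", "day8", sc)
  expect_identical(r1$gene, r2$gene)
  expect_identical(r1$sgrna, r2$sgrna)
})

test_that("NT pseudo-gene z-scores are calibrated on a null screen", {
  cfg <- sim_config(n_genes = 30, n_pos_controls = 0, n_nt = 400,
                    seed = 21)
  lib <- make_library(cfg)
  cm <- simulate_screen_counts(lib, NULL, cfg)
  sc <- screen_config(n_permutations = 100, seed = 5)
  res <- screen_test(cm, lib, "day4", "day8", sc)
  nt_lfc <- res$sgrna$lfc[res$sgrna$category == "non_targeting"]
  # disjoint pseudo-genes of 10 NT guides vs a resampled reference
  withr::with_seed(6, {
    idx <- sample(length(nt_lfc))
    groups <- split(nt_lfc[idx], (seq_along(idx) - 1) %/% 10)
    pg <- vapply(groups, median, numeric(1))
    ref <- vapply(1:200, function(i) median(sample(nt_lfc, 10)),
                  numeric(1))
  })
  z <- (pg - mean(ref)) / sd(ref)
  expect_lt(abs(mean(z)), 0.2)
  expect_true(sd(z) > 0.7 && sd(z) < 1.4)
})
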