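test_that("permute_profile preserves the value multiset deterministically", {
  de <- de_vector_from(stats::setNames(c(0.1, 0.7, 0.3, 0.9),
                                       c("A", "B", "C", "D")))
  p1 <- permute_profile(de, 5)
  p2 <- permute_profile(de, 5)
  expect_identical(p1$values, p2$values)
  expect_equal(sort(unname(p1$values)), sort(unname(de$values)))
  expect_equal(names(p1$values), names(de$values))

  one <- de_vector_from(c(A = 0.4))
  expect_equal(permute_profile(one, 99)$values, one$values)
})

test_that("permutation null reuses C and respects linearity", {
  w <- small_world(seed = 31)
  de <- build_de_vector(w$profile, w$net)
  cm <- multi_rwr(w$net, names(de$values), rwr_params())

  # constant DE: every permuted PS equals the real PS
  dec <- de
  dec$values[] <- 0.25
  nullc <- permutation_null(cm, dec, w$pathways, w$net, h = 5,
                            rng_seed = 1)
  real <- compute_pathway_scores(compute_risk_scores(cm, dec),
                                 w$pathways, w$net)
  expect_equal(unname(nullc$ps_random),
               matrix(real$ps, nrow(real), 5), tolerance = 1e-12)

  # h = 1 gives one null value per pathway
  n1 <- permutation_null(cm, de, w$pathways, w$net, h = 1, rng_seed = 1)
  expect_equal(ncol(n1$ps_random), 1L)

  # brute-force oracle: permutation k recomputed from first principles
  nl <- permutation_null(cm, de, w$pathways, w$net, h = 3, rng_seed = 7)
  de_k <- permute_profile(de, 7 + 2)
  ps_k <- compute_pathway_scores(compute_risk_scores(cm, de_k),
                                 w$pathways, w$net)
  expect_equal(unname(nl$ps_random[, 2]), ps_k$ps, tolerance = 1e-12)

  # null mean ~ PS under the mean-DE vector (linearity of the chain)
  big <- permutation_null(cm, de, w$pathways, w$net, h = 400,
                          rng_seed = 11)
  dem <- de
  dem$values[] <- mean(de$values)
  psm <- compute_pathway_scores(compute_risk_scores(cm, dem),
                                w$pathways, w$net)
  expect_lt(max(abs(rowMeans(big$ps_random) - psm$ps) / psm$ps), 0.15)
})

test_that("empirical P-value counts ties as extreme", {
  nulls <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(empirical_pvalue(0.5, nulls), 0)
  expect_equal(empirical_pvalue(0.25, nulls), 0.5)
  expect_equal(empirical_pvalue(0.3, nulls), 0.5)  # >= rule
  expect_equal(empirical_pvalue(0.05, nulls), 1)
  expect_equal(empirical_pvalue(0.3, rep(0.3, 4)), 1)
  set.seed(1)
  big <- runif(1000)
  expect_equal(empirical_pvalue(median(big), big), 0.5, tolerance = 0.01)
})

test_that("BH adjustment matches hand values and stats::p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  p <- runif(50)^2
  expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  # monotone in p-rank and order-invariant
  ord <- order(p)
  expect_true(all(diff(bh_fdr(p)[ord]) >= -1e-15))
  expect_equal(bh_fdr(p)[ord], bh_fdr(p[ord]))
})

test_that("GPD refinement behaves at the boundaries", {
  set.seed(3)
  nulls <- rexp(1000)
  # score below the tail threshold: empirical P returned unchanged
  mid <- median(nulls)
  expect_equal(gpd_refine(mid, nulls), empirical_pvalue(mid, nulls))
  # refined tail P never exceeds n_exceed / h
  ps <- max(nulls) + 1
  expect_lte(gpd_refine(ps, nulls), 250 / 1000)
  # degenerate exceedances fall back with a warning
  flat <- c(rep(1, 400), runif(600, 0, 0.5))
  expect_warning(pf <- gpd_refine(2, flat, min_exceed = 50),
                 "falling back")
  expect_equal(pf, 1 / 1001)
})

test_that("refinement is consistent with the empirical overlap zone", {
  set.seed(4)
  nulls <- rexp(1000)
  s <- sort(nulls, decreasing = TRUE)
  for (k in c(20, 50, 100)) {
    ps <- (s[k] + s[k + 1]) / 2
    emp <- empirical_pvalue(ps, nulls)
    ref <- gpd_refine(ps, nulls)
    expect_lt(max(ref / emp, emp / ref), 1.5)
  }
})

test_that("pathway_enrichment assembles a coherent result table", {
  w <- small_world(seed = 41, effect = 1)
  de <- build_de_vector(w$profile, w$net)
  cm <- multi_rwr(w$net, names(de$values), rwr_params())
  pt <- compute_pathway_scores(compute_risk_scores(cm, de),
                               w$pathways, w$net)
  nl <- permutation_null(cm, de, w$pathways, w$net, h = 200,
                         rng_seed = 3)
  res <- pathway_enrichment(pt, nl, fdr_threshold = 0.01)
  expect_true(all(res$p_final >= 0 & res$p_final <= 1))
  expect_true(all(res$fdr >= res$p_final - 1e-12))
  expect_equal(res$significant, res$fdr < 0.01)
  expect_false(is.unsorted(res$fdr))
  # GPD off: zeros replaced by the conservative estimate
  res0 <- pathway_enrichment(pt, nl, gpd = FALSE)
  zero <- res0$p_empirical == 0
  expect_true(all(res0$p_final[zero] == 1 / 201))
})
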