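test_that("ssGSEA equals position-by-position running-sum enumeration", {
  prof <- c(a = 2.0, b = 1.5, c = 0.3, d = -0.2, e = -1.1)
  for (gs in list(c("a", "c"), c("b", "e"), "a", c("c", "d", "e"))) {
    for (norm in c(TRUE, FALSE)) {
      expect_equal(ssgsea_score(prof, gs, alpha_w = 0.25, normalize = norm),
                   oracle_ssgsea(prof, gs, 0.25, norm))
    }
  }
  # larger random profiles, several exponents
  for (s in 1:5) {
    prof <- random_profile(40, s)
    gs <- names(prof)[sample(40, 8)]
    for (aw in c(0, 0.25, 1)) {
      expect_equal(ssgsea_score(prof, gs, aw, TRUE),
                   oracle_ssgsea(prof, gs, aw, TRUE))
    }
  }
})

test_that("ssGSEA is monotone in position and rank-invariant", {
  prof <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  expect_gt(ssgsea_score(prof, "a"), ssgsea_score(prof, "e"))
  # any strictly increasing transform leaves the score unchanged
  prof2 <- exp(prof) + 7
  gs <- c("b", "d")
  expect_equal(ssgsea_score(prof, gs), ssgsea_score(prof2, gs))
  expect_error(ssgsea_score(prof, c("x", "y")), "intersect")
  expect_error(ssgsea_score(c(a = 1, b = NaN), "a"), "finite")
})

test_that("unnormalized scores of a set and its reversed-ranking mirror cancel", {
  for (s in 1:5) {
    prof <- random_profile(30, s + 50)
    gs <- names(prof)[sample(30, 6)]
    fwd <- ssgsea_score(prof, gs, alpha_w = 0, normalize = FALSE)
    rev <- ssgsea_score(-prof, gs, alpha_w = 0, normalize = FALSE)
    # with uniform weights the running sums are exactly antisymmetric
    expect_lt(abs(fwd + rev), 1e-8)
  }
})

test_that("score_collection composes ssgsea_score across profiles and sets", {
  sim <- small_sim()
  coll <- simulate_perturbation_collection(small_cfg(), sim$truth,
                                           n_fin = 4, n_ain = 4, seed = 3)
  ferro <- module_genes(sim, "ferro")
  sc <- score_collection(coll, list(ferro = ferro))
  expect_equal(nrow(sc), 8)
  one <- coll[coll$dataset_id == sc$dataset_id[1], ]
  expect_equal(sc$ferro[1],
               ssgsea_score(stats::setNames(one$log2fc, one$gene), ferro))
  # planted signal: FIN mean above AIN mean
  expect_gt(mean(sc$ferro[sc$class == "FIN"]),
            mean(sc$ferro[sc$class == "AIN"]))
  # duplicated profiles give identical rows
  dup <- dplyr::bind_rows(one,
                          dplyr::mutate(one, dataset_id = "COPY"))
  sc2 <- score_collection(dup, list(ferro = ferro))
  expect_equal(sc2$ferro[1], sc2$ferro[2])
})

test_that("landscape coordinates recover the dose gradient and are symmetric", {
  sim <- small_sim()
  de <- fixture("landscape_de", function() {
    dose_contrasts(sim$counts, sim$samples, 24,
                   contrasts = list(c("JB2", "DMSO"), c("JB3", "DMSO"),
                                    c("JB6", "DMSO")))
  })
  names(de) <- c("JB2", "JB3", "JB6")
  ferro <- module_genes(sim, "ferro")
  apopt <- module_genes(sim, "apopt")
  land <- landscape_scores(de, ferro, apopt)
  x <- land$ferro[match(c("JB2", "JB3", "JB6"), land$treatment)]
  y <- land$apopt[match(c("JB2", "JB3", "JB6"), land$treatment)]
  expect_true(all(diff(x) < 0))   # ferroptosis enrichment falls along gradient
  expect_true(all(diff(y) > 0))   # apoptosis enrichment rises
  swapped <- landscape_scores(de, apopt, ferro)
  expect_equal(swapped$ferro, land$apopt)
  expect_equal(swapped$apopt, land$ferro)
})

test_that("Fisher ORA equals the hypergeometric tail", {
  universe <- paste0("u", 1:20)
  pathway <- universe[1:5]
  query <- c(universe[1:4], universe[10])
  got <- fisher_ora(query, universe, list(pw = pathway))
  # enumeration: P(X >= 4), X ~ Hypergeom(N = 20, K = 5, n = 5)
  p_exact <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(got$p, p_exact)

  # exhaustive check over all tables with a small universe
  set.seed(2)
  for (i in 1:20) {
    n_u <- sample(8:30, 1)
    uni <- paste0("g", seq_len(n_u))
    pw <- sample(uni, sample(seq_len(n_u), 1))
    qu <- sample(uni, sample(seq_len(n_u), 1))
    got_i <- fisher_ora(qu, uni, list(pw = pw))
    k <- length(pw); n <- length(qu); a <- length(intersect(qu, pw))
    p_enum <- sum(dhyper(a:min(k, n), k, n_u - k, n))
    expect_equal(got_i$p, p_enum, tolerance = 1e-12)
  }

  # zero overlap with a tiny pathway is never enriched
  got0 <- fisher_ora(paste0("u", 6:10), universe, list(pw = universe[1:2]))
  expect_gt(got0$p, 0.4)
  # pathway equal to the universe is uninformative
  gotu <- fisher_ora(query, universe, list(pw = universe))
  expect_equal(gotu$p, 1)
  expect_error(fisher_ora(c("u1", "zzz"), universe, list(pw = pathway)),
               "outside universe")
})

test_that("panel z-score integration matches the formula and conserves means", {
  fc <- tibble::tibble(gene = "g1", c1 = 2, c2 = 4, c3 = 6)
  out <- panel_zscore_summary(fc)
  expect_equal(out$mean_z, c(0, 1, 2))

  # row-mean conservation: averaged over conditions the summary is 1
  set.seed(4)
  fc2 <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:10)),
                          tibble::as_tibble(matrix(runif(40, 0.5, 3), 10,
                                                   dimnames = list(NULL, paste0("c", 1:4)))))
  out2 <- panel_zscore_summary(fc2)
  expect_equal(mean(out2$mean_z), 1)

  # degenerate gene dropped with warning; all-degenerate is an error
  fc3 <- dplyr::bind_rows(fc2[1:3, ],
                          tibble::tibble(gene = "flat", c1 = 1, c2 = 1,
                                         c3 = 1, c4 = 1))
  expect_warning(out3 <- panel_zscore_summary(fc3), "zero variance")
  expect_equal(nrow(out3), 4)
  flat_only <- tibble::tibble(gene = "flat", c1 = 1, c2 = 1)
  expect_error(suppressWarnings(panel_zscore_summary(flat_only)), "zero")

  # unity-centred variant shifts deviations from FC = 1
  outu <- panel_zscore_summary(fc, center = "unity")
  expect_equal(outu$mean_z, 1 + (c(2, 4, 6) - 1) / 2)
})
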