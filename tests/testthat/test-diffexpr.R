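test_that("low-count filtering matches direct CPM enumeration", {
  counts <- tibble::tibble(gene = c("a", "b", "c"),
                           s1 = c(0, 5, 100), s2 = c(0, 0, 50),
                           s3 = c(0, 8, 10), s4 = c(0, 1, 2))
  # brute-force CPM per cell
  m <- as.matrix(counts[, -1])
  cpm <- t(t(m) / colSums(m)) * 1e6
  keep <- rowSums(cpm >= 1) >= 2
  got <- filter_low_counts(counts, min_cpm = 1, min_samples = 2)
  expect_identical(got$gene, counts$gene[keep])
  # all-zero gene always removed for positive threshold
  expect_false("a" %in% got$gene)
  # min_cpm = 0 is the identity on the gene set
  expect_identical(filter_low_counts(counts, 0, 4)$gene, counts$gene)
  expect_error(filter_low_counts(counts, 1e9, 1), "no genes")
  expect_error(filter_low_counts(counts, 1, 9), "min_samples")
})

test_that("log-CPM follows its definition and is depth-scale invariant", {
  counts <- tibble::tibble(gene = c("a", "b"), s1 = c(10, 90))
  e <- normalize_logcpm(counts, prior_count = 0)
  expect_equal(2^e$s1, c(1e5, 9e5))

  # direct formula with a prior
  counts0 <- tibble::tibble(gene = c("a", "b"), s1 = c(0, 1e6))
  e0 <- normalize_logcpm(counts0, prior_count = 0.5)
  expect_equal(e0$s1[1], log2(0.5 / (1e6 + 1) * 1e6))

  # doubling counts and depth leaves log-CPM unchanged (prior 0)
  c1 <- tibble::tibble(gene = letters[1:4], s1 = c(5, 10, 20, 65))
  c2 <- c1; c2$s1 <- c2$s1 * 2
  expect_equal(normalize_logcpm(c1, 0)$s1, normalize_logcpm(c2, 0)$s1)

  expect_error(normalize_logcpm(tibble::tibble(gene = "a", s1 = 0), 0),
               "library size")
})

test_that("median-ratio normalization removes asymmetric composition bias", {
  # two samples, equal depth of the null genes, one sample with a large
  # induced block: plain CPM shrinks null-gene fold changes, median-ratio
  # restores them
  set.seed(1)
  base <- rpois(200, 500)
  s1 <- base
  s2 <- base
  s2[1:40] <- s2[1:40] * 8  # 20% of genes strongly induced in s2
  counts <- tibble::tibble(gene = sprintf("g%03d", 1:200), s1 = s1, s2 = s2)
  raw <- normalize_logcpm(counts, 0.5)
  nrm <- normalize_logcpm(counts, 0.5, norm = "median_ratio")
  null_lfc_raw <- median(raw$s2[-(1:40)] - raw$s1[-(1:40)])
  null_lfc_nrm <- median(nrm$s2[-(1:40)] - nrm$s1[-(1:40)])
  expect_lt(null_lfc_raw, -0.5)          # visible bias
  expect_lt(abs(null_lfc_nrm), 0.1)      # removed
})

test_that("moderated t matches a step-by-step oracle on a worked fixture", {
  # 5 genes with hand-specified means and spreads, 3 vs 3 samples
  m <- rbind(c(10.0, 10.2, 9.8, 8.0, 8.1, 7.9),
             c(5.0, 5.5, 4.5, 5.2, 5.1, 4.9),
             c(7.0, 7.1, 6.9, 9.0, 9.2, 8.8),
             c(3.0, 3.8, 2.2, 3.1, 3.0, 2.9),
             c(12.0, 12.1, 11.9, 12.0, 12.2, 11.8))
  rownames(m) <- paste0("g", 1:5)
  colnames(m) <- c(paste0("A", 1:3), paste0("B", 1:3))
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                           tibble::as_tibble(m))
  got <- moderated_t_contrast(expr, rep(c("A", "B"), each = 3), c("A", "B"))
  want <- oracle_moderated_t(m, 1:3, 4:6)
  expect_equal(got$log2fc, want$lfc)
  expect_equal(got$t, want$t, tolerance = 1e-6)
  expect_equal(got$p, want$p, tolerance = 1e-6)
  expect_true(all(got$q >= got$p))
  expect_equal(sign(got$t), sign(got$log2fc))
})

test_that("forcing the prior df to zero recovers the ordinary t", {
  set.seed(3)
  m <- matrix(rnorm(50 * 6), 50,
              dimnames = list(paste0("g", 1:50),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                           tibble::as_tibble(m))
  got <- moderated_t_contrast(expr, rep(c("A", "B"), each = 3), c("A", "B"),
                              prior_df = 0)
  plain <- apply(m, 1, function(x) {
    t.test(x[1:3], x[4:6], var.equal = TRUE)$statistic
  })
  expect_equal(got$t, unname(plain), tolerance = 1e-10)
  expect_equal(got$df, rep(4, 50))
})

test_that("moderated t agrees with limma on simulated data", {
  set.seed(8)
  m <- matrix(rnorm(300 * 6, sd = rep(sqrt(rchisq(300, 4) / 4), 6)), 300,
              dimnames = list(paste0("g", 1:300),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  m[1:30, 1:3] <- m[1:30, 1:3] + 2
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                           tibble::as_tibble(m))
  got <- moderated_t_contrast(expr, rep(c("A", "B"), each = 3), c("A", "B"))

  design <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(got$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(got$t, unname(fit$t[, 2]), tolerance = 1e-4)
  expect_equal(got$p, unname(fit$p.value[, 2]), tolerance = 1e-4)
  expect_equal(attr(got, "prior")$d0, fit$df.prior, tolerance = 1e-3)
})

test_that("null moderated-t p-values are calibrated and uniform", {
  set.seed(21)
  m <- matrix(rnorm(10000 * 6), 10000,
              dimnames = list(paste0("g", 1:10000),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                           tibble::as_tibble(m))
  got <- moderated_t_contrast(expr, rep(c("A", "B"), each = 3), c("A", "B"))
  frac <- mean(got$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), 3 * se)
  expect_gt(ks.test(got$p, "punif")$p.value, 0.01)
})

test_that("swapping the contrast direction negates effects only", {
  sim <- small_sim()
  de_a <- small_contrasts_24()[["JB2-vs-DMSO"]]
  expr <- normalize_logcpm(
    filter_low_counts(sim$counts[, c("gene",
      sim$samples$sample_id[sim$samples$timepoint_h == 24])], 1, 1),
    norm = "median_ratio")
  grp <- stats::setNames(sim$samples$treatment, sim$samples$sample_id)
  de_b <- moderated_t_contrast(expr, grp[names(expr)[-1]], c("DMSO", "JB2"))
  common <- intersect(de_a$gene, de_b$gene)
  ia <- match(common, de_a$gene); ib <- match(common, de_b$gene)
  expect_equal(de_a$log2fc[ia], -de_b$log2fc[ib])
  expect_equal(de_a$t[ia], -de_b$t[ib])
  expect_equal(de_a$p[ia], de_b$p[ib])
  expect_equal(de_a$q[ia], de_b$q[ib])
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)   # m = 1
  set.seed(5)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-rank
    # permutation invariance
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
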