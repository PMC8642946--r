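test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(11)
  for (i in 1:5) {
    p <- stats::runif(50 + i * 37)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  expect_error(bh_adjust(c(0.1, NA, 0.2)), "indices: 2")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("moderated t-test handles forced means and degenerate limits", {
  set.seed(3)
  m <- matrix(stats::rnorm(40), 10,
              dimnames = list(paste0("F", 1:10), paste0("S", 1:4)))
  ga <- c("S1", "S2"); gb <- c("S3", "S4")
  # identical group means give t = 0, p = 1
  m0 <- m
  m0[1, gb] <- m0[1, ga]
  res <- moderated_ttest(m0, ga, gb)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  # d0 = 0 equals the ordinary pooled-variance t-test
  res0 <- moderated_ttest(m, ga, gb, d0 = 0)
  for (i in 1:10) {
    tt <- stats::t.test(m[i, ga], m[i, gb], var.equal = TRUE)
    expect_equal(res0$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res0$p[i], tt$p.value, tolerance = 1e-10)
  }
  # d0 = Inf replaces every variance by the prior s0^2
  resInf <- moderated_ttest(m, ga, gb, d0 = Inf, s02 = 0.5)
  pooled_d <- unname(rowMeans(m[, ga]) - rowMeans(m[, gb]))
  expect_equal(resInf$t, pooled_d / sqrt(0.5 * (1 / 2 + 1 / 2)),
               tolerance = 1e-12)
  expect_error(moderated_ttest(m, ga, c("S2", "S3")), "overlap")
  expect_error(moderated_ttest(m, "S1", gb), ">= 2")
})

test_that("null features give approximately uniform p-values", {
  set.seed(29)
  m <- matrix(stats::rnorm(200 * 6), 200,
              dimnames = list(sprintf("F%03d", 1:200), paste0("S", 1:6)))
  res <- moderated_ttest(m, paste0("S", 1:3), paste0("S", 4:6))
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  # 1% critical value of the KS statistic at n = 200
  expect_lt(unname(ks$statistic), 1.63 / sqrt(200))
})

test_that("DEP calls follow the fold-change and FDR thresholds", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(1.6, 1.4, 3, -2.5),
                    adj_p = c(0.04, 0.04, 0.06, 0.005))
  out <- call_deps(res)
  expect_equal(out$dep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$direction, c("up_a", NA, NA, "up_b"))
  strict <- call_deps(res, preset = "strict")
  expect_equal(strict$dep, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("DEP calls are invariant under sample relabelling", {
  set.seed(5)
  m <- matrix(stats::rnorm(100 * 8), 100,
              dimnames = list(sprintf("F%03d", 1:100), paste0("S", 1:8)))
  ga <- paste0("S", 1:4); gb <- paste0("S", 5:8)
  r1 <- call_deps(moderated_ttest(m, ga, gb))
  perm <- m[, sample(colnames(m))]
  r2 <- call_deps(moderated_ttest(perm, ga, gb))
  expect_equal(r1$dep, r2$dep)
  expect_equal(r1$log2fc, r2$log2fc)
})

test_that("CV computation and high-variation flags behave", {
  cv <- compute_cv(matrix(c(5, 5, 5), 1), log2_input = FALSE)
  expect_equal(cv$cv, 0)
  expect_false(cv$high_variation)
  cv2 <- compute_cv(matrix(c(5, 15), 1), log2_input = FALSE)
  expect_equal(cv2$cv, stats::sd(c(5, 15)) / 10, tolerance = 1e-12)
  # zero-mean features are excluded with a record
  m3 <- rbind(a = c(0, 0), b = c(1, 2))
  cv3 <- compute_cv(m3, log2_input = FALSE)
  expect_equal(attr(cv3, "excluded"), "a")
  # planted high-variance proteins are enriched among flags
  set.seed(8)
  base <- matrix(stats::rnorm(1000 * 8, 12, 0.2), 1000)
  base[1:50, ] <- matrix(stats::rnorm(50 * 8, 12, 1.5), 50)
  rownames(base) <- sprintf("P%04d", 1:1000)
  cv4 <- compute_cv(base)
  flagged <- cv4$protein[cv4$high_variation]
  expect_gt(mean(flagged %in% sprintf("P%04d", 1:50)), 0.8)
  expect_gt(length(flagged), 20)
})

test_that("single-parent expression flags planted on/off proteins", {
  d <- strain_design()
  set.seed(15)
  # baseline abundances are shared across strains (correlated z-scores),
  # with small within-strain noise, as in real proteomes
  mu <- stats::rnorm(500, 14, 1)
  m <- mu + matrix(stats::rnorm(500 * 8, 0, 0.05), 500,
                   dimnames = list(sprintf("P%04d", 1:500), d$sample))
  silent_d2 <- sprintf("P%04d", 1:5)
  silent_b6 <- sprintf("P%04d", 6:10)
  m[silent_d2, d$sample[d$genotype == "B6"]] <- 16
  m[silent_d2, d$sample[d$genotype == "D2"]] <- 4
  m[silent_b6, d$sample[d$genotype == "D2"]] <- 16
  m[silent_b6, d$sample[d$genotype == "B6"]] <- 4
  spe <- call_spe(m, d)
  expect_setequal(spe$protein[spe$spe], c(silent_d2, silent_b6))
  expect_true(all(spe$silent_parent[match(silent_d2, spe$protein)] == "D2"))
  expect_true(all(spe$silent_parent[match(silent_b6, spe$protein)] == "B6"))
  expect_warning(call_spe(m[1:10, ], d), "percentiles")
})

test_that("reciprocal-hybrid screen recovers planted parent-of-origin effects", {
  d <- strain_design()
  set.seed(23)
  m <- matrix(stats::rnorm(300 * 8, 0, 0.1), 300,
              dimnames = list(sprintf("P%04d", 1:300), d$sample))
  planted <- sprintf("P%04d", 1:6)
  m[planted, d$sample[d$genotype == "B6D2F1"]] <-
    m[planted, d$sample[d$genotype == "B6D2F1"]] + 1
  res <- compare_reciprocal_hybrids(m, d)
  expect_true(all(planted %in% res$feature[res$candidate]))
  expect_true(all(res$direction[match(planted, res$feature)] ==
                    "maternal_B6_higher"))
  # identical F1 groups yield no candidates
  m2 <- m
  m2[, d$sample[d$genotype == "D2B6F1"]] <- m2[, d$sample[d$genotype == "B6D2F1"]]
  expect_equal(sum(compare_reciprocal_hybrids(m2, d)$candidate), 0)
  # boundary: p below cut but fold change too small is excluded
  res3 <- compare_reciprocal_hybrids(m, d, fc_cut = 2)
  expect_equal(sum(res3$candidate), 0)
})

test_that("power is calibrated at zero effect and monotone in effect size", {
  pw <- simulate_power(n_per_group = 2, effect_sizes = c(0, 1, 3),
                       n_features = 400, n_reps = 3, seed = 31)
  expect_lt(pw$power[pw$effect == 0], 0.05)
  expect_lte(pw$fdp[pw$effect == 0], 0.1)
  expect_true(all(diff(pw$power) >= -0.05))
  expect_gt(pw$power[pw$effect == 3], 0.95)
  expect_error(simulate_power(n_per_group = 1), "n_per_group")
})
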