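test_that("relatedness matrices reproduce the pedigree expectations", {
  R <- build_relatedness_matrices()
  genotypes <- c("B6", "D2", "B6D2F1", "D2B6F1")
  R1_expected <- matrix(c(1, 0, 0.5, 0.5,
                          0, 1, 0.5, 0.5,
                          0.5, 0.5, 1, 0.5,
                          0.5, 0.5, 0.5, 1), 4, 4, byrow = TRUE,
                        dimnames = list(genotypes, genotypes))
  R2_expected <- matrix(c(1, 0, 0, 0,
                          0, 1, 0, 0,
                          0, 0, 1, 0.25,
                          0, 0, 0.25, 1), 4, 4, byrow = TRUE,
                        dimnames = list(genotypes, genotypes))
  expect_identical(R$R1_strain, R1_expected)
  expect_identical(R$R2_strain, R2_expected)
  expect_identical(R$R1_strain, t(R$R1_strain))
  expect_identical(R$R2_strain, t(R$R2_strain))

  # sample-level expansion: same-genotype animals are fully related
  d <- strain_design()
  Rs <- build_relatedness_matrices(d)
  b6 <- d$sample[d$genotype == "B6"]
  expect_equal(Rs$R1[b6[1], b6[2]], 1)
  expect_equal(Rs$R2[b6[1], b6[2]], 1)
  f1a <- d$sample[d$genotype == "B6D2F1"][1]
  expect_equal(Rs$R1[b6[1], f1a], 0.5)
  expect_equal(Rs$R2[b6[1], f1a], 0)
  bad <- d
  bad$genotype <- as.character(bad$genotype)
  bad$genotype[1] <- "CAST"
  expect_error(build_relatedness_matrices(bad), "CAST")
})

test_that("D/A ratio reproduces forced-arithmetic cases", {
  out <- dominance_additivity_ratio(c(10, 10, 10), c(20, 20, 20),
                                    c(15, 20, 12.5))
  expect_equal(out$da_ratio, c(0, 1, -0.5))
  expect_equal(out$class, c("additive", "dominant", "dominant"))
  expect_equal(out$additivity, rep(5, 3))
  over <- dominance_additivity_ratio(10, 20, 22)
  expect_equal(over$da_ratio, 1.4)
  expect_equal(over$class, "over_under_dominant")
  eq <- dominance_additivity_ratio(10, 10, 12)
  expect_true(eq$undefined)
  expect_true(is.na(eq$da_ratio))
})

test_that("heritability formula and guards are exact", {
  expect_equal(heritability(data.frame(va = 3, vd = 1, vs = 0, ve = 1))$h2,
               0.8)
  z <- heritability(data.frame(va = 0, vd = 0, vs = 0, ve = 0))
  expect_equal(z$h2, 0)
  expect_true(z$degenerate)
  expect_equal(heritability(data.frame(va = 1, vd = 0, vs = 0, ve = 1e-12))$h2,
               1, tolerance = 1e-9)
  expect_error(heritability(data.frame(va = -1, vd = 0, vs = 0, ve = 1)),
               "non-negative")
  # monotonicity over a grid
  grid <- expand.grid(va = c(0.5, 1, 2), ve = c(0.5, 1, 2))
  h <- heritability(data.frame(va = grid$va, vd = 0.5, vs = 0.1,
                               ve = grid$ve))$h2
  hm <- matrix(h, 3)
  expect_true(all(diff(hm) > 0))        # increasing in va
  expect_true(all(t(diff(t(hm))) < 0))  # decreasing in ve
})

test_that("variance components handle degenerate and constructed inputs", {
  d <- strain_design()
  vc0 <- estimate_variance_components(rep(3, 8), d)
  expect_true(vc0$degenerate)
  expect_equal(vc0[, c("va", "vd", "vs", "ve", "h2")],
               data.frame(va = 0, vd = 0, vs = 0, ve = 0, h2 = 0))
  # pure sex effect: genotypes identical, sexes differ
  y_sex <- ifelse(d$sex == "M", 1, 0) * 2
  vc1 <- estimate_variance_components(y_sex, d)
  expect_lt(vc1$va, 0.05)
  expect_lt(vc1$vd, 0.05)
  expect_gt(vc1$vs, 0.5)
  expect_equal(vc1$vs, 1, tolerance = 0.05)  # beta^2/4 with beta = 2
  expect_error(estimate_variance_components(1:4, d[1:4, ]), ">= 6")
})

test_that("REML estimates are scale-equivariant and locally optimal", {
  d <- strain_design()
  set.seed(77)
  sim <- simulate_proteome(d, sim_params(n_proteins = 5, frac_null = 0,
                                         seed = 77),
                           additive_model = "pedigree")
  y <- sim$abundance$log2_abs[3, ]
  mats <- build_relatedness_matrices(d)
  vc <- estimate_variance_components(y, d, mats)
  vc_scaled <- estimate_variance_components(10 * y, d, mats)
  expect_equal(vc_scaled$va, 100 * vc$va, tolerance = 1e-8)
  expect_equal(vc_scaled$ve, 100 * vc$ve, tolerance = 1e-8)
  expect_equal(vc_scaled$h2, vc$h2, tolerance = 1e-8)

  # restricted likelihood at the optimum beats random feasible points
  X <- cbind(1, as.numeric(d$sex == "M"))
  ll_at <- function(v) f1proteome:::.reml_ll(log(v), y, X, mats$R1, mats$R2)
  ll_best <- ll_at(pmax(c(vc$va, vc$vd, vc$ve), 1e-8))
  set.seed(78)
  worse <- replicate(100, ll_at(stats::runif(3, 1e-4, 2 * stats::var(y))))
  expect_true(all(worse <= ll_best + 1e-6))
})

test_that("REML recovers variance components at distribution level", {
  d <- strain_design()
  p <- sim_params(n_proteins = 150, sigma_a = 1, sigma_d = 0.5,
                  sigma_s = 0, sigma_e = 0.5, frac_null = 0, psm_cv = 0,
                  seed = 101)
  sim <- simulate_proteome(d, p, additive_model = "pedigree")
  vc <- estimate_vc_all(sim$abundance$log2_abs, d)
  expect_gt(mean(vc$converged), 0.95)
  # medians over proteins sit near the generating values (small-n REML is
  # noisy per protein; the distribution centre is informative)
  expect_equal(stats::median(vc$h2), 0.83, tolerance = 0.12)
  expect_equal(mean(vc$ve), 0.25, tolerance = 0.35)
})

test_that("random-sex variant reports a sex variance component", {
  d <- strain_design()
  set.seed(55)
  y <- stats::rnorm(8, 10, 0.2) + ifelse(d$sex == "M", 1.5, 0)
  vc <- estimate_variance_components(y, d, sex = "random")
  expect_gt(vc$vs, 0.1)
})
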