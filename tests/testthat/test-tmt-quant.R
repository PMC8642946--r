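test_that("isotope correction solves the linear mixing system", {
  # identity matrix leaves intensities untouched
  psms <- make_psm_table(rbind(c(1000, 500), c(200, 800)))
  out <- correct_isotope_impurity(psms, diag(2))
  expect_equal(as.matrix(out[, c("S1", "S2")]),
               as.matrix(psms[, c("S1", "S2")]), ignore_attr = TRUE)

  # hand-solved 2x2 system: m = [[.9,.1],[.1,.9]], y = (1000, 500)
  # det = 0.8; x1 = (0.9*1000 - 0.1*500)/0.8 = 1062.5, x2 = 437.5
  psms1 <- make_psm_table(matrix(c(1000, 500), 1))
  m <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  out1 <- correct_isotope_impurity(psms1, m)
  expect_equal(unname(unlist(out1[1, c("S1", "S2")])), c(1062.5, 437.5))
  expect_false(out1$isotope_clipped[1])

  # all-zero observations stay zero; singular matrix is a hard error
  psms0 <- make_psm_table(matrix(0, 1, 2))
  out0 <- correct_isotope_impurity(psms0, m)
  expect_equal(unname(unlist(out0[1, c("S1", "S2")])), c(0, 0))
  expect_error(correct_isotope_impurity(psms1, matrix(0.5, 2, 2)), "singular")
  expect_error(correct_isotope_impurity(psms1, diag(3)), "dimension")

  # negative solutions are clipped to zero and flagged
  psms2 <- make_psm_table(matrix(c(100, 0), 1))
  out2 <- correct_isotope_impurity(psms2, m)
  expect_equal(out2$S2[1], 0)
  expect_true(out2$isotope_clipped[1])
})

test_that("low-intensity filter applies min and median thresholds", {
  psms <- make_psm_table(rbind(c(800, 5000, 6000),    # min 800 -> removed
                               c(1200, 4000, 4500),   # median 4000 -> removed
                               c(1500, 6000, 7000)))  # kept
  out <- filter_low_intensity(psms)
  expect_equal(out$psm_id, "PSM003")
  removed <- attr(out, "removed")
  expect_setequal(removed$psm_id, c("PSM001", "PSM002"))
  expect_equal(removed$reason[removed$psm_id == "PSM001"], "min_intensity")
  expect_equal(removed$reason[removed$psm_id == "PSM002"], "median_intensity")
  expect_warning(filter_low_intensity(psms[0, ]), "empty")
})

test_that("loading normalisation equalises trimmed medians", {
  set.seed(1)
  base <- 2^stats::rnorm(200, 13, 1)
  psms <- make_psm_table(cbind(A = base, B = 2 * base, C = 0.5 * base),
                         channels = c("A", "B", "C"))
  out <- normalize_loading(psms)
  l2 <- log2(as.matrix(out[, c("A", "B", "C")]))
  tm <- apply(l2, 2, stats::median)
  expect_lt(max(tm) - min(tm), 1e-9)
  # identical channels get identical scaling factors
  psms2 <- make_psm_table(cbind(A = base, B = base), channels = c("A", "B"))
  sf <- attr(normalize_loading(psms2), "scaling_log2")
  expect_equal(sf[["A"]], sf[["B"]])
  # idempotence: re-normalising leaves factors at ~0
  sf2 <- attr(normalize_loading(out), "scaling_log2")
  expect_lt(max(abs(sf2)), 1e-9)
  expect_error(normalize_loading(psms, trim_fraction = 0.6), "trim_fraction")
})

test_that("random lognormal tables pass the post-hoc trimmed-median check", {
  set.seed(7)
  m <- matrix(2^stats::rnorm(5 * 300, 12, 1.5), 300, 5)
  out <- normalize_loading(make_psm_table(m), trim_fraction = 0.1)
  l2 <- log2(as.matrix(out[, attr(out, "channels")]))
  tms <- apply(l2, 2, function(x) {
    s <- sort(x); k <- floor(length(s) * 0.1)
    stats::median(s[(k + 1):(length(s) - k)])
  })
  expect_lt(max(dist(tms)), 1e-9)
})

test_that("protein roll-up averages centred PSM profiles", {
  # single PSM: relative profile equals that PSM's centred profile
  one <- make_psm_table(matrix(c(1000, 2000, 4000), 1),
                        proteins = "P1")
  ab <- summarize_proteins(one)
  expected <- log2(c(1000, 2000, 4000))
  expect_equal(unname(ab$log2_rel["P1", ]), expected - mean(expected))

  # mirrored profiles p and -p cancel to zero
  p <- c(-1, 0, 1)
  two <- make_psm_table(2^rbind(10 + p, 10 - p), proteins = c("P1", "P1"))
  ab2 <- summarize_proteins(two)
  expect_equal(unname(ab2$log2_rel["P1", ]), c(0, 0, 0), tolerance = 1e-12)

  # top-3 grand mean on a 5-PSM fixture, computed by hand
  ints <- rbind(c(100, 100), c(900, 900), c(500, 500), c(300, 300),
                c(700, 700))
  five <- make_psm_table(ints, proteins = rep("P1", 5))
  ab3 <- summarize_proteins(five)
  expect_equal(unname(ab3$abs_intensity["P1"]), mean(c(900, 700, 500)))

  # mean-centring conservation across proteins
  set.seed(2)
  many <- make_psm_table(matrix(2^stats::rnorm(40 * 6, 12, 1), 40, 6),
                         proteins = rep(sprintf("P%d", 1:10), each = 4))
  ab4 <- summarize_proteins(many)
  expect_true(all(abs(rowSums(ab4$log2_rel)) < 1e-9))
})

test_that("correction + roll-up recovers planted profiles with zero PSM noise", {
  d <- strain_design()
  imp <- diag(8) * 0.92
  imp[cbind(2:8, 1:7)] <- 0.04
  imp[cbind(1:7, 2:8)] <- 0.04
  p <- sim_params(n_proteins = 40, psm_cv = 0, impurity = imp,
                  loading_bias = rep(1, 8), seed = 17)
  sim <- simulate_proteome(d, p)
  psms <- correct_isotope_impurity(sim$psms, imp)
  psms <- filter_low_intensity(psms, 0, 0)
  ab <- summarize_proteins(psms, d)
  truth_rel <- sim$abundance$log2_rel[rownames(ab$log2_rel), ]
  expect_equal(ab$log2_rel, truth_rel, tolerance = 1e-7)
})

test_that("loading normalisation undoes channel bias up to a constant shape", {
  # with loading bias and noise-free PSMs the normalised chain recovers the
  # planted profile shape exactly; channel offsets differ only by the
  # trimmed-median sampling convention
  d <- strain_design()
  p <- sim_params(n_proteins = 60, psm_cv = 0, seed = 19)
  sim <- simulate_proteome(d, p)
  ab <- quantify_proteins(sim$psms, metadata = d, min_intensity = 0,
                          min_median = 0)
  truth_rel <- sim$abundance$log2_rel[rownames(ab$log2_rel), ]
  delta <- ab$log2_rel - truth_rel
  expect_lt(max(apply(delta, 2, stats::sd)), 1e-7)
  expect_lt(max(abs(colMeans(delta))), 0.5)
})
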