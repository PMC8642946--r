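test_that("missense application substitutes and validates residues", {
  ref <- c(P1 = "AAKRCCK")
  v <- data.frame(accession = "P1", position = 5, ref = "C", alt = "Y")
  out <- apply_missense_variants(ref, v)
  expect_equal(unname(out["P1_p5C>Y"]), "AAKRYCK")
  expect_equal(unname(out["P1"]), "AAKRCCK")  # reference retained
  bad <- data.frame(accession = "P1", position = 5, ref = "W", alt = "Y")
  expect_error(apply_missense_variants(ref, bad), "position 5")
  oob <- data.frame(accession = "P1", position = 99, ref = "C", alt = "Y")
  expect_error(apply_missense_variants(ref, oob), "out of range")
  expect_error(apply_missense_variants(ref,
      data.frame(accession = "P1", position = 5, ref = "C", alt = "C")),
      "differ")
  # empty variant table returns the input database
  empty <- v[0, ]
  expect_identical(apply_missense_variants(ref, empty), ref)
})

test_that("tryptic digestion enumerates products and honours the proline rule", {
  d0 <- tryptic_digest("AAKRCCK", missed_cleavages = 0, min_len = 1)
  expect_equal(d0$peptide, c("AAK", "R", "CCK"))
  expect_equal(d0$start, c(1, 4, 5))
  d1 <- tryptic_digest("AAKRCCK", missed_cleavages = 1, min_len = 1)
  expect_setequal(d1$peptide, c("AAK", "R", "CCK", "AAKR", "RCCK"))
  dp <- tryptic_digest("AKPR", missed_cleavages = 0, min_len = 1)
  expect_equal(dp$peptide, "AKPR")
  expect_equal(tryptic_digest("AAKRCCK", 0, min_len = 4)$peptide,
               character(0))
  expect_error(tryptic_digest("AAXK", 0), "non-standard")
  expect_equal(nrow(tryptic_digest("AAXK", 0, on_nonstandard = "skip")), 0)
  expect_error(tryptic_digest(""), "empty")
})

test_that("digest concatenation reconstructs random sequences", {
  set.seed(41)
  for (i in 1:50) {
    s <- random_protein_seq(30 + i)
    d <- tryptic_digest(s, missed_cleavages = 0, min_len = 1, max_len = 1e6)
    expect_identical(paste(d$peptide, collapse = ""), s)
  }
})

test_that("variant peptide pairs align by coordinates with site-change handling", {
  ref <- c(P1 = "AAKRCCK")
  v <- data.frame(accession = "P1", position = 5, ref = "C", alt = "Y")
  pairs <- enumerate_variant_peptide_pairs(ref, v, missed_cleavages = 0,
                                           min_len = 1)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$b_peptide, "CCK")
  expect_equal(pairs$d_peptide, "YCK")
  expect_true(is.na(pairs$singleton_reason))

  # cleavage-site loss: K3N removes a site, coordinates no longer align
  v2 <- data.frame(accession = "P1", position = 3, ref = "K", alt = "N")
  p2 <- enumerate_variant_peptide_pairs(ref, v2, missed_cleavages = 0,
                                        min_len = 1)
  expect_true(any(p2$singleton_reason == "site_change", na.rm = TRUE))
  sing <- p2[which(p2$singleton_reason == "site_change"), ]
  expect_equal(sing$d_peptide, "AANR")

  # two variants inside one peptide give a multi-variant pair
  ref3 <- c(P2 = "AAKGGCWGGK")
  v3 <- data.frame(accession = c("P2", "P2"), position = c(6, 7),
                   ref = c("C", "W"), alt = c("S", "F"))
  p3 <- enumerate_variant_peptide_pairs(ref3, v3, missed_cleavages = 0,
                                        min_len = 1)
  expect_equal(p3$b_peptide, "GGCWGGK")
  expect_equal(p3$d_peptide, "GGSFGGK")
  expect_true(p3$multi_variant)
  expect_equal(p3$n_variants, 2)

  # I/L substitutions are flagged MS-indistinguishable, not dropped
  v4 <- data.frame(accession = "P1", position = 1, ref = "A", alt = "A")
  expect_error(enumerate_variant_peptide_pairs(ref, v4), "differ")
  ref5 <- c(P3 = "GGIGGKAAK")
  v5 <- data.frame(accession = "P3", position = 3, ref = "I", alt = "L")
  p5 <- enumerate_variant_peptide_pairs(ref5, v5, missed_cleavages = 0,
                                        min_len = 1)
  expect_true(p5$il_ambiguous)
})

test_that("every emitted pair revalidates against the allele digests", {
  set.seed(43)
  d <- strain_design()
  vp <- simulate_variant_peptides(d, n_pairs = 60, seed = 43)
  pairs <- enumerate_variant_peptide_pairs(vp$proteome$reference,
                                           vp$proteome$variants)
  proper <- pairs[is.na(pairs$singleton_reason), ]
  expect_gt(nrow(proper), 0)
  alt_db <- vp$proteome$reference
  for (i in seq_len(nrow(vp$proteome$variants))) {
    acc <- vp$proteome$variants$accession[i]
    substr(alt_db[[acc]], vp$proteome$variants$position[i],
           vp$proteome$variants$position[i]) <- vp$proteome$variants$alt[i]
  }
  for (i in seq_len(nrow(proper))) {
    acc <- proper$accession[i]
    ref_peps <- tryptic_digest(vp$proteome$reference[[acc]])$peptide
    alt_peps <- tryptic_digest(alt_db[[acc]])$peptide
    expect_true(proper$b_peptide[i] %in% ref_peps)
    expect_true(proper$d_peptide[i] %in% alt_peps)
    expect_equal(nchar(proper$b_peptide[i]), nchar(proper$d_peptide[i]))
    hamming <- sum(strsplit(proper$b_peptide[i], "")[[1]] !=
                     strsplit(proper$d_peptide[i], "")[[1]])
    expect_equal(hamming, proper$n_variants[i])
  }
  # deterministic output order
  expect_identical(order(pairs$accession, pairs$start, method = "radix"),
                   seq_len(nrow(pairs)))
})

test_that("identified peptides are assigned to alleles and pairs completed", {
  ref <- c(P1 = "AAKRCCK")
  v <- data.frame(accession = "P1", position = 5, ref = "C", alt = "Y")
  pairs <- enumerate_variant_peptide_pairs(ref, v, missed_cleavages = 0,
                                           min_len = 1)
  md <- strain_design()
  quant <- data.frame(peptide = c("YC[+57.021]K", "CCK", "AAK"),
                      matrix(1000, 3, 8), check.names = FALSE)
  names(quant)[-1] <- md$sample
  matched <- match_identified_peptides(quant, pairs, md)
  asg <- attr(matched, "assignments")
  expect_equal(asg$allele, c("D", "B", "non_variant"))
  expect_true(matched$pairs$complete[1])
  expect_equal(unname(matched$b_abund[1, 1]), 1000)
  # modification stripping removed the bracketed group
  expect_equal(asg$sequence[1], "YCK")
})

test_that("FASTA round-trip preserves sequences", {
  f <- tempfile(fileext = ".fasta")
  seqs <- c(A1 = "MAAKCCR", B2 = "MGGKLLR")
  write_protein_fasta(seqs, f)
  expect_identical(read_protein_fasta(f), seqs)
})
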