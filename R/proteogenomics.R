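#' Read / write protein FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' the sequence representation used throughout the proteogenomics stage.
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_protein_fasta
#' @param sequences named character vector of sequences.
#' @export
write_protein_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

.standard_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_variants <- function(variants) {
  need <- c("accession", "position", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  bad <- !(variants$ref %in% .standard_aa & variants$alt %in% .standard_aa)
  if (any(bad)) stop("non-standard amino acid in variants: rows ",
                     paste(which(bad), collapse = ", "))
  variants
}

#' Build a customised protein database from missense variants
#'
#' Appends, to the reference entries, one alternate sequence per
#' (protein, variant) with a structured header `ACC_pPOSREF>ALT` encoding
#' accession, 1-based protein position and the substitution. Every
#' variant's reference residue must match the reference sequence.
#'
#' @param reference named character vector (or FASTA path) of reference
#'   protein sequences.
#' @param variants data.frame with columns `accession`, `position`, `ref`,
#'   `alt` (and optionally `gene`).
#' @return named character vector: reference entries then variant entries.
#' @export
apply_missense_variants <- function(reference, variants) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_protein_fasta(reference)
  }
  variants <- .check_variants(variants)
  out <- reference
  for (i in seq_len(nrow(variants))) {
    acc <- variants$accession[i]
    pos <- variants$position[i]
    if (!acc %in% names(reference)) stop("unknown accession: ", acc)
    seqc <- reference[[acc]]
    if (pos < 1 || pos > nchar(seqc)) {
      stop("variant position out of range for ", acc, ": ", pos)
    }
    have <- substr(seqc, pos, pos)
    if (have != variants$ref[i]) {
      stop("reference mismatch for ", acc, " position ", pos,
           ": expected ", variants$ref[i], ", found ", have)
    }
    alt_seq <- seqc
    substr(alt_seq, pos, pos) <- variants$alt[i]
    out[paste0(acc, "_p", pos, variants$ref[i], ">", variants$alt[i])] <- alt_seq
  }
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves after K/R (suppressed before proline when `proline_rule`),
#' emitting every product with at most `missed_cleavages` internal sites
#' and length within bounds, in N-to-C order with 1-based coordinates.
#'
#' @param sequence one protein sequence.
#' @param missed_cleavages maximal internal K/R sites per peptide.
#' @param min_len,max_len peptide length bounds.
#' @param proline_rule suppress cleavage before proline?
#' @param on_nonstandard `"error"` (default) or `"skip"` (return zero rows)
#'   for sequences with non-standard residues.
#' @return data.frame with `peptide`, `start`, `end`, `missed`.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 2, min_len = 6,
                           max_len = 50, proline_rule = TRUE,
                           on_nonstandard = c("error", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% .standard_aa)) {
    if (on_nonstandard == "error") {
      stop("non-standard residue in sequence: ",
           paste(setdiff(aa, .standard_aa), collapse = ", "))
    }
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed = integer()))
  }
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  if (proline_rule) {
    cut_after <- cut_after[cut_after == n | aa[cut_after + 1] != "P"]
  }
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_seg <- length(starts)
  rows <- vector("list", n_seg * (missed_cleavages + 1))
  k <- 0L
  for (i in seq_len(n_seg)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > n_seg) break
      len <- ends[j] - starts[i] + 1L
      if (len < min_len || len > max_len) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        peptide = substr(sequence, starts[i], ends[j]),
        start = starts[i], end = ends[j], missed = mc,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed = integer()))
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out[order(out$start, out$end, method = "radix"), , drop = FALSE]
}

.collapse_il <- function(x) gsub("I", "L", x)

#' Enumerate B-allele / D-allele variant peptide pairs
#'
#' For each protein, applies all of its missense variants to obtain the
#' D-allele sequence (the B-allele is the reference), digests both alleles
#' and pairs every D-allele tryptic peptide covering at least one variant
#' site with the reference peptide of identical coordinates. When a
#' substitution creates or destroys a cleavage site the coordinates no
#' longer align and the peptide is emitted as an unpaired singleton with
#' reason `"site_change"`. Pairs covering several variants are flagged
#' `multi_variant`; pairs whose sequences coincide after I/L collapse are
#' flagged `il_ambiguous` (mass-identical residues cannot support allele
#' assignment). Output is sorted by (accession, start).
#'
#' @param reference named character vector (or FASTA path) of reference
#'   proteins.
#' @param variants missense variant table (`accession`, `position`, `ref`,
#'   `alt`).
#' @param missed_cleavages,min_len,max_len,proline_rule digestion settings.
#' @return data.frame with one row per pair or singleton: `pair_id`,
#'   `accession`, `b_peptide`, `d_peptide`, `start`, `end`,
#'   `variant_positions`, `n_variants`, `multi_variant`, `il_ambiguous`,
#'   `singleton_reason` (NA for proper pairs).
#' @export
enumerate_variant_peptide_pairs <- function(reference, variants,
                                            missed_cleavages = 2,
                                            min_len = 6, max_len = 50,
                                            proline_rule = TRUE) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_protein_fasta(reference)
  }
  variants <- .check_variants(variants)
  out <- list()
  for (acc in sort(unique(variants$accession), method = "radix")) {
    vs <- variants[variants$accession == acc, , drop = FALSE]
    vs <- vs[order(vs$position), , drop = FALSE]
    if (!acc %in% names(reference)) stop("unknown accession: ", acc)
    ref_seq <- reference[[acc]]
    alt_seq <- ref_seq
    for (i in seq_len(nrow(vs))) {
      if (substr(ref_seq, vs$position[i], vs$position[i]) != vs$ref[i]) {
        stop("reference mismatch for ", acc, " position ", vs$position[i])
      }
      substr(alt_seq, vs$position[i], vs$position[i]) <- vs$alt[i]
    }
    ref_dig <- tryptic_digest(ref_seq, missed_cleavages, min_len, max_len,
                              proline_rule)
    alt_dig <- tryptic_digest(alt_seq, missed_cleavages, min_len, max_len,
                              proline_rule)
    ref_key <- paste(ref_dig$start, ref_dig$end)
    for (i in seq_len(nrow(alt_dig))) {
      covered <- vs$position[vs$position >= alt_dig$start[i] &
                             vs$position <= alt_dig$end[i]]
      if (!length(covered)) next
      match_i <- match(paste(alt_dig$start[i], alt_dig$end[i]), ref_key)
      b_pep <- if (is.na(match_i)) NA_character_ else ref_dig$peptide[match_i]
      out[[length(out) + 1L]] <- data.frame(
        accession = acc,
        b_peptide = b_pep,
        d_peptide = alt_dig$peptide[i],
        start = alt_dig$start[i], end = alt_dig$end[i],
        variant_positions = paste(covered, collapse = ";"),
        n_variants = length(covered),
        multi_variant = length(covered) > 1,
        il_ambiguous = !is.na(b_pep) &&
          .collapse_il(b_pep) == .collapse_il(alt_dig$peptide[i]),
        singleton_reason = if (is.na(match_i)) "site_change" else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(pair_id = character(), accession = character(),
                      b_peptide = character(), d_peptide = character(),
                      start = integer(), end = integer(),
                      variant_positions = character(), n_variants = integer(),
                      multi_variant = logical(), il_ambiguous = logical(),
                      singleton_reason = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$accession, out$start, out$end, method = "radix"), ,
             drop = FALSE]
  out <- cbind(pair_id = sprintf("%s_%d_%d", out$accession, out$start,
                                 out$end),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.strip_mods <- function(x) {
  gsub("[^A-Z]", "", gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x))
}

#' Match identified peptides to variant peptide pairs
#'
#' Assigns each identified peptide sequence (modifications stripped by
#' removing bracketed groups and all non-uppercase characters) to the
#' B-allele or D-allele of an enumerated pair, or labels it non-variant.
#' Pairs with both alleles detected are marked complete; per-sample
#' abundances are attached to each allele.
#'
#' @param quant data.frame with a `peptide` column and one abundance column
#'   per sample (linear scale; NA = not detected).
#' @param pairs output of [enumerate_variant_peptide_pairs()] (or the
#'   generator's pair table).
#' @param metadata sample sheet; its `sample` column names the abundance
#'   columns of `quant`.
#' @return object of class `pase_pairs`: list with `pairs` (pair table plus
#'   `complete` flag), `b_abund`, `d_abund` (pair x sample matrices) and
#'   `metadata`; the per-peptide allele assignment is in the `assignments`
#'   attribute.
#' @export
match_identified_peptides <- function(quant, pairs, metadata) {
  stopifnot("peptide" %in% names(quant),
            all(metadata$sample %in% names(quant)))
  seqs <- .strip_mods(quant$peptide)
  if ("singleton_reason" %in% names(pairs)) {
    ptab <- pairs[is.na(pairs$singleton_reason), , drop = FALSE]
  } else ptab <- pairs
  conflict <- ptab$b_peptide == ptab$d_peptide
  if (any(conflict)) {
    stop("pair(s) with identical alleles: ",
         paste(ptab$pair_id[conflict], collapse = ", "))
  }
  b_idx <- match(seqs, ptab$b_peptide)
  d_idx <- match(seqs, ptab$d_peptide)
  both <- !is.na(b_idx) & !is.na(d_idx)
  if (any(both)) {
    stop("peptide(s) matching both alleles: ",
         paste(unique(seqs[both]), collapse = ", "))
  }
  allele <- ifelse(!is.na(b_idx), "B", ifelse(!is.na(d_idx), "D",
                                              "non_variant"))
  samples <- metadata$sample
  np <- nrow(ptab)
  b_ab <- d_ab <- matrix(NA_real_, np, length(samples),
                         dimnames = list(ptab$pair_id, samples))
  qm <- as.matrix(quant[, samples, drop = FALSE])
  for (i in which(!is.na(b_idx))) b_ab[b_idx[i], ] <- qm[i, ]
  for (i in which(!is.na(d_idx))) d_ab[d_idx[i], ] <- qm[i, ]
  ptab$complete <- rowSums(!is.na(b_ab)) > 0 & rowSums(!is.na(d_ab)) > 0
  out <- structure(list(pairs = ptab, b_abund = b_ab, d_abund = d_ab,
                        metadata = metadata), class = "pase_pairs")
  attr(out, "assignments") <- data.frame(peptide = quant$peptide,
                                         sequence = seqs, allele = allele,
                                         stringsAsFactors = FALSE)
  out
}
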