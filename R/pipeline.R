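#' Default pipeline configuration
#'
#' Every threshold printed for the study is surfaced with its default:
#' PSM intensity floors 1000/5000, trimmed-median loading normalisation
#' (10% per tail), differential expression at BH-FDR 0.05 and |log2FC| 1.5,
#' reciprocal-hybrid screen at p 0.01 and |log2FC| 0.3, allelic-ratio
#' threshold tau = 1 log2 unit, BH 0.05 for ASE tests, tryptic digestion
#' with <= 2 missed cleavages.
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "results/pipeline",
    stages = list(simulate = TRUE, tmt = TRUE, diffexpr = TRUE,
                  inheritance = TRUE, proteogenomics = TRUE,
                  transcript_ase = TRUE, compare = TRUE),
    simulate = list(n_proteins = 300L, sigma_a = 1, sigma_d = 0.5,
                    sigma_s = 0.2, sigma_e = 0.5, frac_null = 0.3,
                    psm_cv = 0.1, n_pairs = 200L, pair_effect = 2,
                    pair_noise_sd = 0.25, n_genes = 1000L, depth = 100),
    tmt = list(min_intensity = 1000, min_median = 5000, trim_fraction = 0.1),
    diffexpr = list(fdr = 0.05, fc_cut = 1.5),
    hybrid = list(p_cut = 0.01, fc_cut = 0.3),
    pase = list(tau = 1, gate_significance = FALSE, fdr = 0.05),
    transcript = list(min_total = 10, pseudocount = 0.5, tau = 1),
    digest = list(missed_cleavages = 2L, min_len = 6L, max_len = 50L),
    inputs = list(reference_fasta = NULL, variants_tsv = NULL)
  )
}

.merge_config <- function(default, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(default)) stop("unknown config key: ", here)
    if (is.list(default[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) stop("config key ", here, " must be a map")
      default[[key]] <- .merge_config(default[[key]], user[[key]], here)
    } else {
      default[key] <- user[key]
    }
  }
  default
}

.check_range <- function(cfg, keys, lo, hi, open_lo = FALSE) {
  v <- cfg
  for (k in keys) v <- v[[k]]
  name <- paste(keys, collapse = ".")
  if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
    stop("config key ", name, " must be a number")
  }
  if (v < lo || v > hi || (open_lo && v <= lo)) {
    stop("config key ", name, " = ", v, " out of range [", lo, ", ", hi, "]")
  }
  invisible(v)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), injects defaults, rejects unknown
#' keys with their key path, range-checks every threshold, and checks that
#' referenced input files exist.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- .merge_config(default_config(), config)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("seed must be an integer")
  .check_range(cfg, c("simulate", "n_proteins"), 1, 1e7)
  .check_range(cfg, c("simulate", "frac_null"), 0, 1)
  for (k in c("sigma_a", "sigma_d", "sigma_s", "sigma_e", "psm_cv")) {
    .check_range(cfg, c("simulate", k), 0, 100)
  }
  .check_range(cfg, c("simulate", "depth"), 1, 1e9)
  .check_range(cfg, c("tmt", "min_intensity"), 0, Inf)
  .check_range(cfg, c("tmt", "min_median"), 0, Inf)
  .check_range(cfg, c("tmt", "trim_fraction"), 0, 0.5 - 1e-12)
  .check_range(cfg, c("diffexpr", "fdr"), 0, 1, open_lo = TRUE)
  .check_range(cfg, c("diffexpr", "fc_cut"), 0, Inf)
  .check_range(cfg, c("hybrid", "p_cut"), 0, 1, open_lo = TRUE)
  .check_range(cfg, c("hybrid", "fc_cut"), 0, Inf)
  .check_range(cfg, c("pase", "tau"), 0, Inf, open_lo = TRUE)
  .check_range(cfg, c("pase", "fdr"), 0, 1, open_lo = TRUE)
  .check_range(cfg, c("transcript", "tau"), 0, Inf, open_lo = TRUE)
  .check_range(cfg, c("transcript", "min_total"), 0, Inf)
  .check_range(cfg, c("transcript", "pseudocount"), 0, Inf, open_lo = TRUE)
  .check_range(cfg, c("digest", "missed_cleavages"), 0, 10)
  .check_range(cfg, c("digest", "min_len"), 1, 100)
  .check_range(cfg, c("digest", "max_len"), 1, 1000)
  for (k in c("reference_fasta", "variants_tsv")) {
    f <- cfg$inputs[[k]]
    if (!is.null(f) && !file.exists(f)) {
      stop("config inputs.", k, ": file not found: ", f)
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the complete synthetic-study analysis pipeline
#'
#' Executes simulate -> TMT quantification -> differential expression /
#' SPE / hybrid screen -> variance components and heritability ->
#' proteogenomics + protein ASE -> transcript ASE -> cross-level
#' comparison, writing every output table as TSV under `config$outdir` and
#' returning a manifest with per-stage row counts and file digests.
#' Re-running with an identical config reproduces identical outputs. A
#' failing stage aborts with the stage named; files it already wrote are
#' renamed with a `.quarantine` suffix.
#'
#' @param config validated config, config list, or YAML path.
#' @return manifest list (invisibly written to `manifest.json` as well).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("f1proteome")),
                   seed = cfg$seed, created = format(Sys.time(), tz = "UTC"),
                   stages = list(), files = list())
  out <- function(name) file.path(cfg$outdir, name)
  stage_files <- character()
  run_stage <- function(name, fun) {
    stage_files <<- character()
    res <- tryCatch(fun(), error = function(e) {
      for (f in stage_files) if (file.exists(f)) {
        file.rename(f, paste0(f, ".quarantine"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- res
    invisible(res)
  }
  emit <- function(df, name) {
    f <- .write_tsv(df, out(name))
    stage_files <<- c(stage_files, f)
    f
  }

  state <- new.env(parent = emptyenv())
  s <- cfg$stages

  if (isTRUE(s$simulate)) run_stage("simulate", function() {
    design <- strain_design()
    sp <- cfg$simulate
    params <- sim_params(n_proteins = sp$n_proteins, sigma_a = sp$sigma_a,
                         sigma_d = sp$sigma_d, sigma_s = sp$sigma_s,
                         sigma_e = sp$sigma_e, frac_null = sp$frac_null,
                         psm_cv = sp$psm_cv, seed = cfg$seed)
    sim <- simulate_proteome(design, params)
    state$design <- design
    state$sim <- sim
    emit(design, "design.tsv")
    emit(as.data.frame(sim$psms), "psms.tsv")
    emit(sim$truth, "protein_truth.tsv")
    emit(cbind(protein = rownames(sim$abundance$log2_abs),
               as.data.frame(sim$abundance$log2_abs)), "protein_true_log2.tsv")
    list(n_samples = nrow(design), n_proteins = sp$n_proteins,
         n_psms = nrow(sim$psms))
  })

  if (isTRUE(s$tmt)) run_stage("tmt", function() {
    ab <- quantify_proteins(state$sim$psms, metadata = state$design,
                            min_intensity = cfg$tmt$min_intensity,
                            min_median = cfg$tmt$min_median,
                            trim_fraction = cfg$tmt$trim_fraction)
    state$abundance <- ab
    emit(cbind(protein = rownames(ab$log2_rel),
               as.data.frame(ab$log2_rel),
               abs_intensity = ab$abs_intensity), "protein_abundance.tsv")
    as.list(attr(ab, "counts"))
  })

  if (isTRUE(s$diffexpr)) run_stage("diffexpr", function() {
    md <- state$design
    m <- state$abundance$log2_rel
    b6 <- md$sample[md$genotype == "B6"]
    d2 <- md$sample[md$genotype == "D2"]
    res <- call_deps(moderated_ttest(m, b6, d2),
                     fc_cut = cfg$diffexpr$fc_cut, fdr = cfg$diffexpr$fdr)
    cv <- compute_cv(state$abundance)
    spe <- call_spe(state$abundance)
    hyb <- compare_reciprocal_hybrids(m, md, p_cut = cfg$hybrid$p_cut,
                                      fc_cut = cfg$hybrid$fc_cut)
    state$dep <- res
    emit(res, "diffexpr.tsv")
    emit(cv, "cv_high_variation.tsv")
    emit(spe, "spe.tsv")
    emit(hyb, "hybrid_screen.tsv")
    list(n_dep = sum(res$dep), n_high_cv = sum(cv$high_variation),
         n_spe = sum(spe$spe), n_hybrid_candidates = sum(hyb$candidate))
  })

  if (isTRUE(s$inheritance)) run_stage("inheritance", function() {
    vc <- estimate_vc_all(state$abundance)
    da <- inheritance_summary(state$abundance)
    tab <- merge(vc, da, by = "protein", sort = TRUE)
    emit(tab, "inheritance.tsv")
    R <- build_relatedness_matrices(state$design)
    emit(cbind(genotype = rownames(R$R1_strain),
               as.data.frame(R$R1_strain)), "R1_strain.tsv")
    emit(cbind(genotype = rownames(R$R2_strain),
               as.data.frame(R$R2_strain)), "R2_strain.tsv")
    list(n_proteins = nrow(tab),
         median_h2 = stats::median(tab$h2),
         median_da = stats::median(tab$da_ratio, na.rm = TRUE))
  })

  if (isTRUE(s$proteogenomics)) run_stage("proteogenomics", function() {
    sp <- cfg$simulate
    vp <- simulate_variant_peptides(state$design, n_pairs = sp$n_pairs,
                                    effect = sp$pair_effect,
                                    noise_sd = sp$pair_noise_sd,
                                    seed = cfg$seed + 1L)
    fasta <- out("reference_synthetic.fasta")
    write_protein_fasta(vp$proteome$reference, fasta)
    stage_files <- c(stage_files, fasta)
    emit(vp$proteome$variants, "missense_variants.tsv")
    custom <- apply_missense_variants(vp$proteome$reference,
                                      vp$proteome$variants)
    write_protein_fasta(custom, out("custom_db_synthetic.fasta"))
    pairs <- enumerate_variant_peptide_pairs(
      vp$proteome$reference, vp$proteome$variants,
      missed_cleavages = cfg$digest$missed_cleavages,
      min_len = cfg$digest$min_len, max_len = cfg$digest$max_len)
    emit(pairs, "variant_peptide_pairs.tsv")
    # identified-peptide quant table from the generator's abundances
    quant <- rbind(
      data.frame(peptide = vp$pairs$pairs$b_peptide,
                 as.data.frame(vp$pairs$b_abund), check.names = FALSE),
      data.frame(peptide = vp$pairs$pairs$d_peptide,
                 as.data.frame(vp$pairs$d_abund), check.names = FALSE))
    matched <- match_identified_peptides(quant, pairs, state$design)
    ratios <- compute_allelic_ratios(matched)
    test <- pase_test(matched)
    sig <- if (cfg$pase$gate_significance) {
      !is.na(test$adj_p) & test$adj_p < cfg$pase$fdr
    } else NULL
    calls <- classify_pase(ratios, tau = cfg$pase$tau, significant = sig)
    calls$adj_p <- test$adj_p[match(calls$pair_id, test$pair_id)]
    # map pairs back to genes for the cross-level comparison
    acc <- matched$pairs$accession[match(calls$pair_id,
                                         matched$pairs$pair_id)]
    calls$gene <- vp$proteome$variants$gene[
      match(acc, vp$proteome$variants$accession)]
    state$pase_calls <- calls
    state$pase_truth <- vp$truth
    emit(calls, "pase_calls.tsv")
    emit(vp$truth, "pase_truth.tsv")
    c(list(n_pairs = nrow(pairs), n_complete = sum(matched$pairs$complete)),
      as.list(attr(calls, "counts")))
  })

  if (isTRUE(s$transcript_ase)) run_stage("transcript_ase", function() {
    sp <- cfg$simulate
    ac <- simulate_allele_counts(n_genes = sp$n_genes, depth = sp$depth,
                                 effect = sp$pair_effect,
                                 seed = cfg$seed + 2L)
    test <- binomial_ase_test(ac$counts, min_total = cfg$transcript$min_total)
    calls <- classify_transcript_regulation(
      ac$counts, ac$parental, tau = cfg$transcript$tau,
      pseudocount = cfg$transcript$pseudocount)
    calls$adj_p <- test$adj_p[match(calls$gene, test$gene)]
    state$transcript_calls <- calls
    state$transcript_truth <- ac$truth
    emit(ac$counts, "allele_counts.tsv")
    emit(ac$parental, "parental_expression.tsv")
    emit(test, "transcript_ase_test.tsv")
    emit(calls, "transcript_ase_calls.tsv")
    c(list(n_tested = sum(test$tested),
           n_significant = sum(test$adj_p < 0.05, na.rm = TRUE)),
      as.list(attr(calls, "counts")))
  })

  if (isTRUE(s$compare)) run_stage("compare", function() {
    cmp <- compare_levels(state$pase_calls, state$transcript_calls)
    emit(as.data.frame(cmp$category_table), "category_overlap.tsv")
    emit(data.frame(odds_ratio = cmp$odds_ratio, p_value = cmp$p_value,
                    n_genes = cmp$n_genes), "level_comparison.tsv")
    list(n_genes = cmp$n_genes, p_value = cmp$p_value)
  })

  files <- sort(setdiff(list.files(cfg$outdir, full.names = TRUE),
                        file.path(cfg$outdir, "manifest.json")),
                method = "radix")
  manifest$files <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
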