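#' PSM table constructor
#'
#' A PSM table is a data.frame with identifier columns (`psm_id`, `peptide`,
#' `protein`) and one linear-scale reporter-intensity column per channel;
#' the channel column names are recorded in the `channels` attribute so
#' that flag columns added later are never mistaken for intensities.
#'
#' @param df data.frame holding the identifier and intensity columns.
#' @param channels character vector naming the intensity columns.
#' @return the table with class `psm_table`.
#' @export
as_psm_table <- function(df, channels) {
  stopifnot(is.data.frame(df),
            all(c("psm_id", "peptide", "protein") %in% names(df)),
            all(channels %in% names(df)))
  bad <- unlist(df[channels])
  if (any(bad < 0, na.rm = TRUE)) stop("reporter intensities must be >= 0")
  if (anyDuplicated(df$psm_id)) stop("psm_id values must be unique")
  attr(df, "channels") <- channels
  class(df) <- unique(c("psm_table", class(df)))
  df
}

psm_channels <- function(psms) {
  ch <- attr(psms, "channels")
  if (is.null(ch)) stop("not a PSM table (missing channels attribute)")
  ch
}

.psm_intensity <- function(psms) {
  as.matrix(psms[, psm_channels(psms), drop = FALSE])
}

.set_intensity <- function(psms, m) {
  psms[, psm_channels(psms)] <- m
  psms
}

#' Correct reporter intensities for isotope impurity
#'
#' Observed reporter intensities are modelled as `m %*% x` where `x` are the
#' true channel signals and `m[i, j]` is the fraction of channel j's signal
#' read in channel i; correction solves the linear system per PSM. Negative
#' solutions (possible with noisy low-intensity PSMs) are clipped to zero
#' and flagged in the `isotope_clipped` column.
#'
#' @param psms PSM table.
#' @param m impurity matrix (channels x channels, non-negative, column sums
#'   <= 1 + tolerance, invertible).
#' @return corrected PSM table.
#' @export
correct_isotope_impurity <- function(psms, m) {
  ch <- psm_channels(psms)
  m <- as.matrix(m)
  if (nrow(m) != length(ch) || ncol(m) != length(ch)) {
    stop("impurity matrix dimension (", nrow(m), "x", ncol(m),
         ") does not match channel count (", length(ch), ")")
  }
  if (any(m < 0)) stop("impurity matrix entries must be non-negative")
  if (any(colSums(m) > 1 + 1e-6)) {
    stop("impurity matrix column sums must be <= 1 (+ tolerance)")
  }
  if (abs(det(m)) < 1e-12) stop("impurity matrix is singular")
  y <- .psm_intensity(psms)
  nas <- is.na(y)
  y[nas] <- 0
  x <- t(solve(m, t(y)))
  clipped <- rowSums(x < -1e-9, na.rm = TRUE) > 0
  x[x < 0] <- 0
  x[nas] <- NA_real_
  psms <- .set_intensity(psms, x)
  psms$isotope_clipped <- clipped
  psms
}

#' Filter PSMs on minimum and median reporter intensity
#'
#' A PSM is removed iff its cross-channel minimum intensity is below
#' `min_intensity` or its cross-channel median is below `min_median`
#' (defaults 1000 and 5000). PSMs missing in more than half of the channels
#' are also dropped. Removals are recorded in the `removed` attribute of the
#' returned table (psm_id + reason), never silently.
#'
#' @param psms PSM table.
#' @param min_intensity,min_median intensity thresholds (>= 0).
#' @return filtered PSM table with a `removed` attribute.
#' @export
filter_low_intensity <- function(psms, min_intensity = 1000,
                                 min_median = 5000) {
  if (min_intensity < 0 || min_median < 0) stop("thresholds must be >= 0")
  y <- .psm_intensity(psms)
  if (nrow(y) == 0) {
    warning("empty PSM table")
    attr(psms, "removed") <- data.frame(psm_id = character(),
                                        reason = character())
    return(psms)
  }
  n_obs <- rowSums(!is.na(y))
  too_missing <- n_obs < ncol(y) / 2
  mins <- suppressWarnings(apply(y, 1, min, na.rm = TRUE))
  meds <- apply(y, 1, stats::median, na.rm = TRUE)
  low_min <- !too_missing & mins < min_intensity
  low_med <- !too_missing & !low_min & meds < min_median
  drop <- too_missing | low_min | low_med
  removed <- data.frame(
    psm_id = psms$psm_id[drop],
    reason = c("missing_channels", "min_intensity", "median_intensity")[
      ifelse(too_missing[drop], 1L, ifelse(low_min[drop], 2L, 3L))],
    stringsAsFactors = FALSE
  )
  kept <- psms[!drop, , drop = FALSE]
  attr(kept, "channels") <- psm_channels(psms)
  attr(kept, "removed") <- removed
  class(kept) <- class(psms)
  kept
}

.trimmed_median <- function(x, trim_fraction) {
  x <- sort(x[!is.na(x)])
  k <- floor(length(x) * trim_fraction)
  if (2 * k >= length(x)) return(stats::median(x))
  stats::median(x[(k + 1):(length(x) - k)])
}

#' Normalise channel loading with trimmed medians
#'
#' Scales each channel so the trimmed medians of log2 intensity agree
#' across channels (target: their mean). Corrects the equal-loading bias
#' introduced by pipetting/labelling differences; the per-channel log2
#' scaling factors are recorded in the `scaling_log2` attribute.
#'
#' @param psms PSM table (filtered).
#' @param trim_fraction fraction trimmed from each tail before the median
#'   (in [0, 0.5)).
#' @return normalised PSM table.
#' @export
normalize_loading <- function(psms, trim_fraction = 0.1) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)")
  }
  y <- .psm_intensity(psms)
  if (nrow(y) < 1) stop("no PSMs to normalise")
  all_missing <- colSums(!is.na(y) & y > 0) == 0
  if (any(all_missing)) {
    stop("channel(s) with no usable values: ",
         paste(psm_channels(psms)[all_missing], collapse = ", "))
  }
  l2 <- log2(y)
  l2[!is.finite(l2)] <- NA
  tm <- apply(l2, 2, .trimmed_median, trim_fraction = trim_fraction)
  shift <- mean(tm) - tm
  out <- sweep(y, 2, 2^shift, `*`)
  psms <- .set_intensity(psms, out)
  attr(psms, "scaling_log2") <- shift
  psms
}

#' Protein abundance container
#'
#' @param log2_rel proteins x samples matrix of mean-centred log2 relative
#'   abundance (each row sums to zero).
#' @param abs_intensity per-protein absolute intensity scalar (> 0).
#' @param metadata sample sheet ([strain_design()] format).
#' @param log2_abs optional proteins x samples absolute log2 matrix.
#' @return object of class `protein_abundance`.
#' @export
protein_abundance <- function(log2_rel, abs_intensity, metadata,
                              log2_abs = NULL) {
  stopifnot(is.matrix(log2_rel), nrow(metadata) == ncol(log2_rel))
  structure(list(log2_rel = log2_rel, abs_intensity = abs_intensity,
                 metadata = metadata, log2_abs = log2_abs),
            class = "protein_abundance")
}

#' @export
print.protein_abundance <- function(x, ...) {
  cat("protein_abundance:", nrow(x$log2_rel), "proteins x",
      ncol(x$log2_rel), "samples\n")
  invisible(x)
}

.resolve_matrix <- function(mat) {
  if (inherits(mat, "protein_abundance")) mat$log2_rel else as.matrix(mat)
}

#' Roll PSMs up to protein relative and absolute abundance
#'
#' Per protein, the relative log2 profile is the mean of its PSMs'
#' mean-centred log2 profiles; the absolute intensity scalar is the grand
#' mean (over channels and PSMs) of its three most intense PSMs, ranked by
#' total cross-channel intensity with ties broken by psm_id (all PSMs when
#' fewer than three). Proteins with no remaining PSMs are absent.
#'
#' @param psms filtered, normalised PSM table.
#' @param metadata sample sheet matching the channel columns; NULL derives a
#'   bare sheet from the channel names.
#' @return [protein_abundance()] object.
#' @export
summarize_proteins <- function(psms, metadata = NULL) {
  ch <- psm_channels(psms)
  if (is.null(metadata)) {
    metadata <- data.frame(sample = ch, stringsAsFactors = FALSE)
  }
  y <- .psm_intensity(psms)
  l2 <- log2(y)
  l2[!is.finite(l2)] <- NA
  centred <- l2 - rowMeans(l2, na.rm = TRUE)
  proteins <- sort(unique(psms$protein), method = "radix")
  rel <- matrix(NA_real_, length(proteins), length(ch),
                dimnames = list(proteins, ch))
  abs_int <- stats::setNames(numeric(length(proteins)), proteins)
  total <- rowSums(y, na.rm = TRUE)
  for (i in seq_along(proteins)) {
    idx <- which(psms$protein == proteins[i])
    rel[i, ] <- colMeans(centred[idx, , drop = FALSE], na.rm = TRUE)
    ord <- idx[order(-total[idx], psms$psm_id[idx], method = "radix")]
    top <- ord[seq_len(min(3L, length(ord)))]
    abs_int[i] <- mean(y[top, , drop = FALSE], na.rm = TRUE)
  }
  rel[is.nan(rel)] <- NA
  # re-centre rows: with missing values the PSM average need not sum to 0
  rel <- rel - rowMeans(rel, na.rm = TRUE)
  protein_abundance(rel, abs_int, metadata)
}

#' Run the full PSM-to-protein quantification chain
#'
#' Applies isotope-impurity correction, low-intensity filtering, loading
#' normalisation and protein roll-up in their mandatory order.
#'
#' @param psms raw PSM table.
#' @param impurity impurity matrix or NULL to skip correction.
#' @param metadata sample sheet.
#' @param min_intensity,min_median,trim_fraction stage parameters.
#' @return [protein_abundance()] object with a `counts` attribute recording
#'   PSM/protein numbers per stage.
#' @export
quantify_proteins <- function(psms, impurity = NULL, metadata = NULL,
                              min_intensity = 1000, min_median = 5000,
                              trim_fraction = 0.1) {
  n0 <- nrow(psms)
  if (!is.null(impurity)) psms <- correct_isotope_impurity(psms, impurity)
  psms <- filter_low_intensity(psms, min_intensity, min_median)
  psms <- normalize_loading(psms, trim_fraction)
  out <- summarize_proteins(psms, metadata)
  attr(out, "counts") <- c(psms_in = n0, psms_kept = nrow(psms),
                           proteins = nrow(out$log2_rel))
  out
}
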