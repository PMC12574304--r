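#' Coverage matrices
#'
#' Entities (bins or marker taxa) by samples, normalized per sample as
#' raw / sample total x 1e6 ("per million"). The raw matrix and the sample
#' totals are retained; the unit label records what the raw values are
#' (e.g. `"bases"` or `"reads"`), since correlation is unit-free but the
#' copy-number slope is only interpretable when both matrices share a unit.
#'
#' @param raw Numeric matrix, entities x samples (non-negative).
#' @param sample_totals Named vector of per-sample sequencing totals (> 0
#'   for every sample).
#' @param unit Unit label for the raw values.
#' @return Object of class `coverage_matrix`: list with `norm`, `raw`,
#'   `sample_totals`, `unit`.
#' @export
coverage_matrix <- function(raw, sample_totals, unit = "bases") {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop_arg("coverage values must be non-negative")
  if (is.null(colnames(raw))) stop_arg("raw matrix needs sample column names")
  if (is.null(names(sample_totals))) stop_arg("sample_totals must be named")
  miss <- setdiff(colnames(raw), names(sample_totals))
  if (length(miss)) stop_arg("no total for sample(s): ", paste(miss, collapse = ", "))
  tot <- sample_totals[colnames(raw)]
  if (any(tot <= 0)) stop_arg("sample totals must be > 0")
  norm <- sweep(raw, 2, tot, "/") * 1e6
  structure(list(norm = norm, raw = raw, sample_totals = tot, unit = unit),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d entit%s x %d sample(s), unit '%s' per million\n",
              nrow(x$norm), if (nrow(x$norm) == 1) "y" else "ies",
              ncol(x$norm), x$unit))
  invisible(x)
}

#' Per-bin, per-sample coverage profiles
#'
#' The raw depth of a bin in a sample is the sum of bases mapped to its
#' member contigs divided by the total length of those contigs; the profile
#' is then normalized per sample (depth / sample total x 1e6). Bins whose
#' member contigs have zero total length are excluded with a warning.
#'
#' @param depth_table data.frame with columns `contig`, `sample`,
#'   `mapped_bases` (summed mapped bases of that contig in that sample).
#' @param bins A [bin_assignment()].
#' @param contig_lengths Named vector of contig lengths in bp; every binned
#'   contig must be present.
#' @param sample_depths Named vector of per-sample total sequencing depth.
#' @return A [coverage_matrix()] with one row per bin (unit `"depth"`).
#' @export
bin_coverage_profile <- function(depth_table, bins, contig_lengths, sample_depths) {
  depth_table <- as.data.frame(depth_table, stringsAsFactors = FALSE)
  need <- c("contig", "sample", "mapped_bases")
  if (!all(need %in% names(depth_table)))
    stop_arg("depth_table needs columns ", paste(need, collapse = ", "))
  missing_len <- setdiff(bins$contig, names(contig_lengths))
  if (length(missing_len))
    stop("no length for binned contig(s): ",
         paste(missing_len, collapse = ", "), call. = FALSE)
  samples <- sort(unique(depth_table$sample))
  bin_ids <- sort(unique(bins$bin))
  map <- stats::setNames(bins$bin, bins$contig)
  bin_len <- tapply(contig_lengths[bins$contig], bins$bin, sum)[bin_ids]
  zero_len <- bin_len == 0
  if (any(zero_len)) {
    warning("excluding bin(s) with zero total contig length: ",
            paste(bin_ids[zero_len], collapse = ", "))
    bin_ids <- bin_ids[!zero_len]
    bin_len <- bin_len[!zero_len]
  }
  dt <- depth_table[depth_table$contig %in% bins$contig, , drop = FALSE]
  raw <- matrix(0, nrow = length(bin_ids), ncol = length(samples),
                dimnames = list(bin_ids, samples))
  if (nrow(dt)) {
    agg <- tapply(dt$mapped_bases,
                  list(map[dt$contig], dt$sample), sum)
    agg[is.na(agg)] <- 0
    raw[rownames(agg), colnames(agg)] <- agg
  }
  raw <- raw / as.numeric(bin_len)
  coverage_matrix(raw, sample_depths, unit = "depth")
}

#' Filter low-count taxa and normalize per sample
#'
#' Removes taxa whose total read count across all samples is below
#' `min_total_reads` (a row is retained when its sum is >= the threshold),
#' then normalizes the survivors per sample as count / sample total x 1e6.
#'
#' @param counts Numeric matrix of non-negative read counts, taxa x samples.
#' @param min_total_reads Minimum row-sum to retain a taxon (default 10).
#' @param sample_depths Named vector of per-sample total sequencing depth.
#' @return A [coverage_matrix()] (unit `"reads"`); attribute `filter_report`
#'   holds the numbers of removed and retained taxa.
#' @export
filter_and_normalise_taxa <- function(counts, min_total_reads = 10, sample_depths) {
  assert_scalar_number(min_total_reads, "min_total_reads", min = 0)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_arg("counts must be non-negative")
  keep <- rowSums(counts) >= min_total_reads
  out <- coverage_matrix(counts[keep, , drop = FALSE], sample_depths,
                         unit = "reads")
  attr(out, "filter_report") <- list(removed = sum(!keep), retained = sum(keep),
                                     min_total_reads = min_total_reads)
  out
}

#' Link a bin to marker taxa by coverage correlation
#'
#' Computes, for every taxon, the Pearson correlation between the taxon's
#' normalized profile and the bin's normalized profile over the shared
#' samples, with a two-sided p-value and a multiplicity adjustment across
#' all tested taxa (Benjamini-Hochberg by default), plus the
#' through-the-origin regression slope of the taxon profile on the bin
#' profile. Results are sorted by r descending; the top row is the best
#' hit. Taxa with zero variance have an undefined correlation and are
#' excluded from the ranking (reported in the `excluded` attribute).
#'
#' @param bin_profile Named numeric vector: the bin's normalized profile by
#'   sample (one [coverage_matrix()] row), or a 1-row `coverage_matrix`.
#' @param taxa A [coverage_matrix()] of taxon profiles.
#' @param adjust Multiple-testing method for [stats::p.adjust()] (default
#'   `"BH"`).
#' @return data.frame with columns `taxon`, `r`, `p`, `p_adj`, `slope`,
#'   `n_samples`, `rank`, sorted by `r` descending; attribute `excluded`
#'   lists zero-variance taxa.
#' @export
link_bin_to_taxa <- function(bin_profile, taxa, adjust = "BH") {
  if (inherits(bin_profile, "coverage_matrix")) {
    if (nrow(bin_profile$norm) != 1L)
      stop_arg("bin_profile coverage_matrix must have exactly one row")
    bin_profile <- bin_profile$norm[1, ]
  }
  if (!inherits(taxa, "coverage_matrix")) stop_arg("`taxa` must be a coverage_matrix")
  shared <- intersect(names(bin_profile), colnames(taxa$norm))
  if (length(shared) < 3L) stop_arg("need >= 3 shared samples, got ", length(shared))
  x <- bin_profile[shared]
  if (stats::sd(x) == 0) stop_arg("bin profile has zero variance over shared samples")
  m <- taxa$norm[, shared, drop = FALSE]
  if (!nrow(m)) stop_arg("taxa matrix is empty")
  const <- apply(m, 1, stats::sd) == 0
  if (any(const))
    message(sum(const), " zero-variance taxon/taxa excluded from ranking: ",
            paste(utils::head(rownames(m)[const], 5), collapse = ", "))
  mt <- m[!const, , drop = FALSE]
  res <- apply(mt, 1, function(y) {
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    c(r = unname(ct$estimate), p = ct$p.value,
      slope = sum(x * y) / sum(x * x))
  })
  out <- data.frame(taxon = rownames(mt), r = res["r", ], p = res["p", ],
                    p_adj = stats::p.adjust(res["p", ], method = adjust),
                    slope = res["slope", ], n_samples = length(shared),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$taxon), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- rownames(m)[const]
  attr(out, "adjust") <- adjust
  out
}

#' Estimate ribosomal operon copy number from coverage regression
#'
#' Fits the taxon profile on the bin profile by least squares through the
#' origin: slope = sum(x*y) / sum(x^2). At zero intercept the slope is the
#' ratio of marker depth to genome depth, i.e. an estimate of the per-genome
#' ribosomal operon copy number. A seeded bootstrap over samples gives a
#' percentile confidence interval. A free-intercept fit is available behind
#' `intercept = TRUE` (the slope then loses the copy-number reading).
#'
#' @param taxon_profile,bin_profile Named numeric vectors over shared
#'   samples (>= 3), same normalization unit.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap (default 20251029).
#' @param intercept Fit a free intercept instead of through-the-origin?
#' @return List of class `copy_number_estimate`: `slope`, `copies`
#'   (nearest integer), `ci` (percentile interval), `n_samples`,
#'   `intercept` (coefficient, 0 unless `intercept = TRUE`).
#' @export
estimate_copy_number <- function(taxon_profile, bin_profile, n_boot = 1000,
                                 conf = 0.95, seed = 20251029,
                                 intercept = FALSE) {
  shared <- intersect(names(taxon_profile), names(bin_profile))
  if (length(shared) < 3L) stop_arg("need >= 3 shared samples, got ", length(shared))
  y <- taxon_profile[shared]
  x <- bin_profile[shared]
  if (all(x == 0)) stop_arg("bin profile is all zero")
  fit_slope <- function(xx, yy) {
    if (intercept) unname(stats::coef(stats::lm(yy ~ xx))[2])
    else sum(xx * yy) / sum(xx * xx)
  }
  slope <- fit_slope(x, y)
  icept <- if (intercept) unname(stats::coef(stats::lm(y ~ x))[1]) else 0
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      k <- sample.int(length(x), replace = TRUE)
      if (all(x[k] == 0)) return(NA_real_)
      fit_slope(x[k], y[k])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(slope = slope, copies = round(slope), ci = ci,
                 conf = conf, n_samples = length(shared),
                 intercept = icept, n_boot = n_boot),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("copy number: slope %.2f (~%d operons), %g%% CI [%.2f, %.2f], n = %d samples\n",
              x$slope, x$copies, 100 * x$conf, x$ci[1], x$ci[2], x$n_samples))
  invisible(x)
}
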