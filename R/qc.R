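n50_value <- function(lengths) {
  lengths <- sort(lengths, decreasing = TRUE)
  half <- sum(lengths) / 2
  lengths[which(cumsum(lengths) >= half)[1]]
}

#' Assembly statistics of a contig set
#'
#' Total length, contig count, N50 and GC content. N50 is the standard
#' descending-scan definition: the length L of the contig at which the
#' cumulative sum of lengths sorted in decreasing order first reaches half
#' the total. GC is (G+C)/(A+C+G+T); N and other ambiguity codes are
#' excluded from the denominator. Optionally summarises per-sample depth
#' ranges from a depth table.
#'
#' @param contigs A FASTA path, a [Biostrings::DNAStringSet], a character
#'   vector of sequences, or a numeric vector of contig lengths (GC is then
#'   `NA`).
#' @param depth_table Optional data.frame with columns `contig`, `sample`,
#'   `mapped_bases`; per-sample depth = mapped bases / total length.
#' @return List of class `assembly_stats`: `total_length`, `n_contigs`,
#'   `n50`, `gc`, and `coverage_range` (per-sample min/max depth or `NULL`).
#' @export
assembly_stats <- function(contigs, depth_table = NULL) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- Biostrings::readDNAStringSet(contigs)
  if (is.numeric(contigs)) {
    if (!length(contigs)) stop_arg("empty contig set")
    lengths <- contigs
    gc <- NA_real_
  } else {
    if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
    if (!length(contigs)) stop_arg("empty contig set")
    lengths <- Biostrings::width(contigs)
    freq <- colSums(Biostrings::letterFrequency(contigs, c("A", "C", "G", "T")))
    gc <- unname((freq["G"] + freq["C"]) / sum(freq))
  }
  cov <- NULL
  if (!is.null(depth_table)) {
    tot <- sum(lengths)
    depth <- tapply(depth_table$mapped_bases, depth_table$sample, sum) / tot
    cov <- data.frame(sample = names(depth), depth = as.numeric(depth),
                      stringsAsFactors = FALSE)
  }
  structure(list(total_length = sum(lengths), n_contigs = length(lengths),
                 n50 = n50_value(lengths), gc = gc,
                 coverage_range = if (is.null(cov)) NULL else
                   c(min = min(cov$depth), max = max(cov$depth)),
                 per_sample_depth = cov),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("assembly: %.2f Mbp in %d contigs, N50 %d%s\n",
              x$total_length / 1e6, x$n_contigs, round(x$n50),
              if (is.na(x$gc)) "" else sprintf(", GC %.1f%%", 100 * x$gc)))
  invisible(x)
}

#' Parse a BUSCO-style short summary
#'
#' Extracts the complete, duplicated, fragmented and missing marker
#' percentages from a BUSCO short-summary text file (the
#' `C:..%[S:..%,D:..%],F:..%,M:..%` line) or from a JSON report with fields
#' named `Complete`/`Duplicated`/`Fragmented`/`Missing` (case-insensitive,
#' `one_line_summary` also accepted).
#'
#' @param path Path to a short-summary `.txt` or `.json` file.
#' @return List with `complete`, `duplicated`, `fragmented`, `missing`
#'   percentages.
#' @export
read_busco_summary <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  grab <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, ":[0-9.]+%"), txt))
    if (length(m)) as.numeric(sub("%$", "", sub(paste0(key, ":"), "", m[1])))
    else NA_real_
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::fromJSON(txt)
    names(js) <- tolower(names(js))
    res <- js[["results"]] %||% js
    names(res) <- tolower(names(res))
    pick <- function(keys) {
      for (k in keys) if (!is.null(res[[k]])) return(as.numeric(res[[k]]))
      NA_real_
    }
    out <- list(complete = pick(c("complete", "complete percentage", "c")),
                duplicated = pick(c("duplicated", "multi copy percentage", "d")),
                fragmented = pick(c("fragmented", "fragmented percentage", "f")),
                missing = pick(c("missing", "missing percentage", "m")))
  } else {
    out <- list(complete = grab("C"), duplicated = grab("D"),
                fragmented = grab("F"), missing = grab("M"))
  }
  if (anyNA(unlist(out)))
    stop_arg("could not find C/D/F/M percentages in ", path)
  out
}

#' Effective completion of a MAG
#'
#' Complete and fragmented marker fractions summed: fragmented markers are
#' present in the assembly, so `complete + fragmented` is the effective
#' completion. The duplicated fraction is carried through as a contamination
#' proxy. Full precision is retained; `display` fields round to 1 decimal
#' for reporting.
#'
#' @param complete,fragmented Percentages in `[0, 100]`. `complete` may also
#'   be the list returned by [read_busco_summary()].
#' @param duplicated,missing Optional percentages in `[0, 100]`.
#' @return List of class `completion_report`: `complete`, `duplicated`,
#'   `fragmented`, `missing`, `effective_completion`, and
#'   `effective_completion_display` (rounded to 1 decimal).
#' @export
effective_completion <- function(complete, fragmented = NULL, duplicated = NA,
                                 missing = NA) {
  if (is.list(complete)) {
    rep <- complete
    fragmented <- rep$fragmented
    duplicated <- rep$duplicated %||% NA
    missing <- rep$missing %||% NA
    complete <- rep$complete
  }
  for (v in list(complete, fragmented))
    assert_scalar_number(v, "completion percentage", min = 0, max = 100)
  eff <- complete + fragmented
  structure(list(complete = complete, duplicated = duplicated,
                 fragmented = fragmented, missing = missing,
                 effective_completion = eff,
                 effective_completion_display = round(eff, 1)),
            class = "completion_report")
}

#' @export
print.completion_report <- function(x, ...) {
  cat(sprintf("completion %.1f%% + fragmented %.1f%% -> effective %.1f%%%s\n",
              x$complete, x$fragmented, x$effective_completion_display,
              if (is.na(x$duplicated)) ""
              else sprintf(" (duplicated %.1f%%)", x$duplicated)))
  invisible(x)
}

#' Read SNV records with allele frequencies
#'
#' From a TSV with columns `contig`, `pos`, `ref_depth`, `alt_depth`
#' (frequency = alt / (ref + alt)), or from a VCF: per-record alternate
#' allele frequency is taken from the sample `AD` field (alt / (ref + alt)),
#' or from a varScan-style `FREQ` percentage when AD is absent. VCF parsing
#' uses the vcfR package.
#'
#' @param path Path to a `.vcf`(`.gz`) or TSV file.
#' @return data.frame with columns `contig`, `pos`, `freq`.
#' @export
read_snvs <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop_arg("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
    if (!is.null(ad) && !all(is.na(ad))) {
      parts <- strsplit(ad[, 1], ",", fixed = TRUE)
      refd <- as.numeric(vapply(parts, `[`, "", 1))
      altd <- as.numeric(vapply(parts, function(p) p[2] %||% NA_character_, ""))
      freq <- altd / (refd + altd)
    } else {
      fr <- vcfR::extract.gt(v, element = "FREQ")
      freq <- as.numeric(sub("%$", "", fr[, 1])) / 100
    }
    fix <- vcfR::getFIX(v)
    return(data.frame(contig = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                      freq = freq, stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("contig", "pos", "ref_depth", "alt_depth")
  if (!all(need %in% names(df)))
    stop_arg("SNV TSV needs columns ", paste(need, collapse = ", "))
  data.frame(contig = df$contig, pos = df$pos,
             freq = df$alt_depth / (df$ref_depth + df$alt_depth),
             stringsAsFactors = FALSE)
}

#' Allele-frequency spectrum of MAG SNVs
#'
#' Characterises the alternate-allele frequency spectrum to separate two
#' regimes: a population of closely related strains spreads frequencies
#' evenly, while a diploid (or two-haplotype) signal concentrates them near
#' 0.5. The spectrum is summarised by a histogram, a Kolmogorov-Smirnov
#' test of the frequencies inside `(f_min, f_max)` against the uniform
#' distribution on that range, the central-mode score (fraction of
#' frequencies in `[0.4, 0.6]`), and per-contig SNV densities when a contig
#' length table is given. The label is `"haplotype-like"` when the central
#' score exceeds `central_threshold`, `"strain-diversity-like"` when
#' uniformity is not rejected at `alpha` and the central score is below the
#' threshold, and `"ambiguous"` otherwise.
#'
#' @param snvs data.frame from [read_snvs()], or a numeric vector of
#'   frequencies. Frequencies outside (0, 1) are rejected and counted.
#' @param contig_lengths Optional named vector of contig lengths (bp) for
#'   SNV densities per kbp.
#' @param bins Number of histogram bins (default 20).
#' @param f_min,f_max Frequency range for the uniformity test (default
#'   0.05-0.95, trimming detection-limit edge effects).
#' @param alpha Significance level for the uniformity test (default 0.01).
#' @param central_window Central window (default `c(0.4, 0.6)`).
#' @param central_threshold Central-score threshold (default 0.5).
#' @return List of class `snv_spectrum`: `n`, `n_rejected`, `histogram`,
#'   `ks_stat`, `ks_p`, `central_score`, `density` (per contig, or `NULL`),
#'   `label`.
#' @export
snv_spectrum <- function(snvs, contig_lengths = NULL, bins = 20,
                         f_min = 0.05, f_max = 0.95, alpha = 0.01,
                         central_window = c(0.4, 0.6),
                         central_threshold = 0.5) {
  if (is.data.frame(snvs)) { freq <- snvs$freq } else { freq <- as.numeric(snvs) }
  ok <- !is.na(freq) & freq > 0 & freq < 1
  n_rejected <- sum(!ok)
  f <- freq[ok]
  if (!length(f)) stop_arg("no SNV frequencies strictly inside (0, 1)")
  h <- graphics::hist(f, breaks = seq(0, 1, length.out = bins + 1), plot = FALSE)
  inside <- f[f >= f_min & f <= f_max]
  ks <- if (length(inside) >= 3)
    suppressWarnings(stats::ks.test(inside, "punif", f_min, f_max))
  else list(statistic = NA_real_, p.value = NA_real_)
  central <- mean(f >= central_window[1] & f <= central_window[2])
  label <- if (central > central_threshold) "haplotype-like"
    else if (!is.na(ks$p.value) && ks$p.value >= alpha) "strain-diversity-like"
    else "ambiguous"
  dens <- NULL
  if (!is.null(contig_lengths) && is.data.frame(snvs)) {
    cnt <- table(snvs$contig[ok])
    shared <- intersect(names(cnt), names(contig_lengths))
    dens <- data.frame(contig = shared,
                       snv_per_kbp = as.numeric(cnt[shared]) /
                         (contig_lengths[shared] / 1000),
                       stringsAsFactors = FALSE)
  }
  structure(list(n = length(f), n_rejected = n_rejected, histogram = h,
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value,
                 central_score = central, density = dens, label = label,
                 alpha = alpha),
            class = "snv_spectrum")
}

#' @export
print.snv_spectrum <- function(x, ...) {
  cat(sprintf("snv_spectrum: %d SNVs, central score %.3f, KS p %.3g -> %s\n",
              x$n, x$central_score, x$ks_p, x$label))
  invisible(x)
}

#' Per-ORF coverage-depth distribution
#'
#' Estimates the modal ORF depth from the histogram peak and reports the
#' fraction of ORFs within +/-50% of the mode; genes in a single copy
#' cluster at the genome's base depth, so a dominant mode indicates that
#' most genes are single-copy despite strain diversity. The summary label
#' is `"single-copy-dominant"` when that fraction strictly exceeds 0.5.
#'
#' @param depths Numeric vector of per-ORF mean depths (>= 10 ORFs), or a
#'   data.frame with a `depth` column.
#' @param bins Number of histogram bins (default 30).
#' @return List of class `orf_coverage`: `n`, `mode`, `dispersion` (median
#'   absolute deviation / mode), `single_copy_fraction`, `label`.
#' @export
orf_coverage_distribution <- function(depths, bins = 30) {
  if (is.data.frame(depths)) depths <- depths$depth
  depths <- as.numeric(depths)
  if (length(depths) < 10L) stop_arg("need >= 10 ORF depths")
  if (any(depths < 0)) stop_arg("depths must be >= 0")
  if (all(depths == 0)) stop_arg("all ORF depths are zero")
  h <- graphics::hist(depths, breaks = bins, plot = FALSE)
  mode <- h$mids[which.max(h$counts)]  # ties: lowest bin, deterministic
  frac <- mean(depths >= 0.5 * mode & depths <= 1.5 * mode)
  structure(list(n = length(depths), mode = mode,
                 dispersion = stats::mad(depths) / mode,
                 single_copy_fraction = frac,
                 label = if (frac > 0.5) "single-copy-dominant"
                         else "not-single-copy-dominant"),
            class = "orf_coverage")
}

#' @export
print.orf_coverage <- function(x, ...) {
  cat(sprintf("orf_coverage: mode %.1fx, %.0f%% of %d ORFs within +/-50%% -> %s\n",
              x$mode, 100 * x$single_copy_fraction, x$n, x$label))
  invisible(x)
}

#' Proportion of AM colonisation contributed by fine root endophytes
#'
#' Given the percentage of root length colonised by fungi with FRE
#' morphology and by Glomeromycotina AMF, returns the FRE share of total AM
#' colonisation: 100 * fre / (fre + gamf).
#'
#' @param fre_percent,gamf_percent Root-length colonisation percentages
#'   (>= 0, not both zero).
#' @return List with `proportion` (full precision, %) and `display`
#'   (rounded to 1 decimal).
#' @export
fre_colonisation_proportion <- function(fre_percent, gamf_percent) {
  assert_scalar_number(fre_percent, "fre_percent", min = 0)
  assert_scalar_number(gamf_percent, "gamf_percent", min = 0)
  if (fre_percent == 0 && gamf_percent == 0)
    stop_arg("proportion undefined: both colonisation percentages are zero")
  p <- 100 * fre_percent / (fre_percent + gamf_percent)
  list(proportion = p, display = round(p, 1))
}
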