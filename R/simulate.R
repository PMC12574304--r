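random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fragment [1, len] by a Poisson breakpoint process tuned so the realized
# N50 is near `n50` (exponential fragments of mean m have length-weighted
# median ~1.678 m); `forced` breakpoints are always included
fragment_positions <- function(len, n50, forced = integer()) {
  rate <- 1.678 / n50
  k <- stats::rpois(1, rate * len)
  cuts <- sort(unique(c(forced, if (k) sample.int(len - 1L, min(k, len - 1L)))))
  cuts <- cuts[cuts >= 1 & cuts <= len - 1]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, len)
  cbind(start = starts, end = ends)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate a fragmented assembly with a planted multi-copy rDNA operon
#'
#' Generates a target genome carrying `rdna_copies` identical copies of a
#' random reference operon, fragments it (and independent decoy genomes)
#' with a Poisson breakpoint process tuned to the requested N50, forces a
#' breakpoint inside every operon copy so each copy is split across at
#' least two unitigs, links consecutive fragments of each genome, and bins
#' contigs by their genome of origin (with an optional misassignment rate).
#' Decoy genomes form disconnected graph components.
#'
#' @param seed Integer RNG seed; identical seed and parameters reproduce
#'   the outputs bit-exactly.
#' @param genome_length Target genome length in bp (default 3e5, a
#'   desk-scale fragmented-genome regime).
#' @param fragment_n50 Requested fragment N50 in bp (default 5000; realized
#'   N50 is approximate).
#' @param rdna_copies Number of planted operon copies (default 3).
#' @param operon_length Reference operon length in bp (default 4500).
#' @param n_decoy_genomes,decoy_length Decoy genomes and their length
#'   (defaults 5 and 1e5).
#' @param misassignment_rate Fraction of contigs assigned to a wrong bin
#'   (default 0).
#' @param out_dir Optional directory; writes `assembly.gfa`,
#'   `contigs.fasta`, `reference_operon.fasta`, `bins.tsv`, `truth.json`.
#' @return List with `graph` ([assembly_graph()]), `reference` (operon
#'   sequence), `bins` ([bin_assignment()]), and `truth` (target bin and
#'   contigs, operon placements, per-unitig reference intervals, seed,
#'   parameters).
#' @export
gen_assembly <- function(seed, genome_length = 3e5, fragment_n50 = 5000,
                         rdna_copies = 3, operon_length = 4500,
                         n_decoy_genomes = 5, decoy_length = 1e5,
                         misassignment_rate = 0, out_dir = NULL) {
  assert_scalar_number(rdna_copies, "rdna_copies", min = 1)
  if (operon_length >= genome_length)
    stop_arg("operon_length must be < genome_length")
  if (rdna_copies * operon_length * 2 > genome_length)
    stop_arg("infeasible: ", rdna_copies, " operon copies of ", operon_length,
             " bp cannot be spaced within a ", genome_length, " bp genome")
  with_seed(seed, {
    reference <- random_dna(operon_length)
    genome <- random_dna(genome_length)
    # non-overlapping operon placements: pick starts in disjoint blocks
    block <- genome_length %/% rdna_copies
    starts <- vapply(seq_len(rdna_copies) - 1L, function(i)
      i * block + sample.int(block - operon_length, 1), numeric(1))
    for (s in starts)
      substr(genome, s + 1, s + operon_length) <- reference
    placements <- data.frame(copy = seq_len(rdna_copies),
                             start = starts, end = starts + operon_length)

    frag_genome <- function(seqstr, prefix, forced = integer()) {
      fr <- fragment_positions(nchar(seqstr), fragment_n50, forced)
      data.frame(id = sprintf("%s_%04d", prefix, seq_len(nrow(fr))),
                 start = fr[, "start"], end = fr[, "end"],
                 sequence = substring(seqstr, fr[, "start"], fr[, "end"]),
                 genome = prefix, stringsAsFactors = FALSE)
    }
    forced <- as.integer(round(starts + operon_length / 2))
    frags <- frag_genome(genome, "target", forced)
    for (d in seq_len(n_decoy_genomes))
      frags <- rbind(frags, frag_genome(random_dna(decoy_length),
                                        paste0("decoy", d)))

    unitigs <- data.frame(id = frags$id, length = frags$end - frags$start + 1,
                          sequence = frags$sequence, stringsAsFactors = FALSE)
    links <- do.call(rbind, lapply(split(frags, frags$genome), function(g) {
      if (nrow(g) < 2) return(NULL)
      data.frame(from = g$id[-nrow(g)], from_orient = "+",
                 to = g$id[-1], to_orient = "+", overlap = 0L,
                 stringsAsFactors = FALSE)
    }))
    graph <- assembly_graph(unitigs, links)

    # per-unitig reference intervals (0-based half-open on the operon)
    mk <- do.call(rbind, lapply(seq_len(rdna_copies), function(i) {
      ov_s <- pmax(frags$start - 1, placements$start[i])
      ov_e <- pmin(frags$end, placements$end[i])
      hit <- which(ov_e - ov_s > 0 & frags$genome == "target")
      if (!length(hit)) return(NULL)
      data.frame(unitig_id = frags$id[hit], copy = i,
                 ref_start = ov_s[hit] - placements$start[i],
                 ref_end = ov_e[hit] - placements$start[i],
                 stringsAsFactors = FALSE)
    }))

    bin_of <- ifelse(frags$genome == "target", "bin_target",
                     paste0("bin_", frags$genome))
    if (misassignment_rate > 0) {
      flip <- which(stats::runif(nrow(frags)) < misassignment_rate)
      pool <- unique(bin_of)
      for (i in flip)
        bin_of[i] <- sample(setdiff(pool, bin_of[i]), 1)
    }
    bins <- bin_assignment(frags$id, bin_of)

    truth <- list(target_bin = "bin_target",
                  target_contigs = frags$id[frags$genome == "target"],
                  operon_length = operon_length,
                  rdna_copies = rdna_copies,
                  operon_placements = placements,
                  marker_unitigs = mk,
                  seed = seed,
                  params = list(genome_length = genome_length,
                                fragment_n50 = fragment_n50,
                                n_decoy_genomes = n_decoy_genomes,
                                decoy_length = decoy_length,
                                misassignment_rate = misassignment_rate))
    out <- list(graph = graph, reference = reference, bins = bins,
                truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      export_gfa(graph, file.path(out_dir, "assembly.gfa"))
      writeLines(c(paste0(">", unitigs$id, "\n", unitigs$sequence)),
                 file.path(out_dir, "contigs.fasta"))
      writeLines(c(">reference_operon", reference),
                 file.path(out_dir, "reference_operon.fasta"))
      write_tsv(data.frame(contig_id = bins$contig, bin_id = bins$bin),
                file.path(out_dir, "bins.tsv"))
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    out
  })
}

#' Alignment records implied by a simulation truth
#'
#' Formats the planted unitig-to-reference intervals of a [gen_assembly()]
#' truth as perfect-identity alignment records, directly usable by
#' [flag_marker_unitigs()] without running an aligner.
#'
#' @param truth The `truth` element of a [gen_assembly()] result.
#' @return data.frame with columns `unitig_id`, `identity`, `ref_start`,
#'   `ref_end`, `aln_len`, `strand`.
#' @export
truth_alignments <- function(truth) {
  mk <- truth$marker_unitigs
  data.frame(unitig_id = mk$unitig_id, identity = 1.0,
             ref_start = mk$ref_start, ref_end = mk$ref_end,
             aln_len = mk$ref_end - mk$ref_start, strand = "+",
             stringsAsFactors = FALSE)
}

log_uniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate multi-sample coverage with one planted proportional taxon
#'
#' Draws per-sample depths for the planted target bin log-uniformly over
#' `bin_depth_range`, emits a per-contig depth table that reproduces those
#' depths exactly, and builds a marker-taxon read-count matrix in which
#' exactly one taxon is proportional to the bin profile with slope `slope`
#' (the planted rDNA copy number) under multiplicative lognormal noise of
#' coefficient of variation `noise_cv`. Decoy taxa are independent of the
#' bin; `n_low_decoys` of them total fewer than `decoy_read_floor` reads so
#' the low-count filter has known casualties.
#'
#' @param seed Integer RNG seed.
#' @param truth Truth from [gen_assembly()] (target bin and contig ids).
#' @param contig_lengths Named lengths of the binned contigs (e.g.
#'   [unitig_lengths()] of the simulated graph).
#' @param n_samples Number of samples (default 12).
#' @param bin_depth_range Target-bin depth range across samples (default
#'   `c(1, 568)`).
#' @param slope Planted copy-number slope (default 63).
#' @param noise_cv Lognormal noise CV on the planted taxon (default 0.10).
#' @param n_decoy_taxa Decoy taxa count (default 250).
#' @param n_low_decoys How many decoys fall below the read floor (default 20).
#' @param decoy_read_floor Read floor the low decoys stay under (default 10).
#' @param out_dir Optional directory; writes `depth.tsv`,
#'   `taxa_counts.tsv`, `sample_totals.tsv`, `coverage_truth.json`.
#' @return List with `depth_table`, `taxa_counts` (matrix), `sample_totals`,
#'   and `truth` (planted taxon id, slope, bin depths, low-decoy ids).
#' @export
gen_coverage <- function(seed, truth, contig_lengths, n_samples = 12,
                         bin_depth_range = c(1, 568), slope = 63,
                         noise_cv = 0.10, n_decoy_taxa = 250,
                         n_low_decoys = 20, decoy_read_floor = 10,
                         out_dir = NULL) {
  if (slope <= 0) stop_arg("slope must be > 0")
  if (noise_cv < 0) stop_arg("noise_cv must be >= 0")
  if (n_samples < 3) stop_arg("need >= 3 samples")
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    totals <- stats::setNames(round(stats::runif(n_samples, 1.5e10, 4.7e10)),
                              samples)
    bin_depth <- stats::setNames(
      log_uniform(n_samples, bin_depth_range[1], bin_depth_range[2]), samples)

    contigs <- truth$target_contigs
    lens <- contig_lengths[contigs]
    if (anyNA(lens)) stop_arg("missing contig length for target contigs")
    depth_table <- data.frame(
      contig = rep(contigs, times = n_samples),
      sample = rep(samples, each = length(contigs)),
      mapped_bases = as.numeric(outer(lens, bin_depth)),
      stringsAsFactors = FALSE)

    sigma <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    lognoise <- function(n) if (sigma == 0) rep(1, n) else
      exp(stats::rnorm(n, -sigma^2 / 2, sigma))

    planted <- round(slope * bin_depth * lognoise(n_samples))
    n_norm <- n_decoy_taxa - n_low_decoys
    decoy <- matrix(round(log_uniform(n_norm * n_samples, 10, 4e4)),
                    nrow = n_norm,
                    dimnames = list(sprintf("decoy_taxon_%03d", seq_len(n_norm)),
                                    samples))
    low <- matrix(0, nrow = n_low_decoys, ncol = n_samples,
                  dimnames = list(sprintf("low_taxon_%02d", seq_len(n_low_decoys)),
                                  samples))
    for (i in seq_len(n_low_decoys)) {
      tot <- sample.int(decoy_read_floor, 1) - 1L       # 0 .. floor-1 reads
      if (tot) {
        w <- sample.int(n_samples, tot, replace = TRUE)
        low[i, ] <- tabulate(w, n_samples)
      }
    }
    taxa <- rbind(planted = matrix(planted, nrow = 1,
                                   dimnames = list("taxon_planted", samples)),
                  decoy, low)

    cov_truth <- list(planted_taxon = "taxon_planted", slope = slope,
                      noise_cv = noise_cv, bin_depth = as.list(bin_depth),
                      low_decoys = rownames(low), seed = seed)
    out <- list(depth_table = depth_table, taxa_counts = taxa,
                sample_totals = totals, truth = cov_truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(depth_table, file.path(out_dir, "depth.tsv"))
      write_tsv(data.frame(taxon = rownames(taxa), taxa, check.names = FALSE),
                file.path(out_dir, "taxa_counts.tsv"))
      write_tsv(data.frame(sample = samples, total = as.numeric(totals)),
                file.path(out_dir, "sample_totals.tsv"))
      jsonlite::write_json(cov_truth, file.path(out_dir, "coverage_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

#' Simulate SNV records under a strain-diversity or diploid regime
#'
#' Draws alternate-allele frequencies either uniformly on (0.05, 0.95)
#' (a population of closely related strains) or normally around 0.5 with
#' sd 0.05 truncated to (0, 1) (a diploid / two-haplotype signal), places
#' the SNVs uniformly over the contigs, and emits read-depth pairs whose
#' ratio realises the frequency.
#'
#' @param seed Integer RNG seed.
#' @param regime `"strain-uniform"` or `"diploid-central"`.
#' @param n_snvs Number of SNVs (>= 1).
#' @param contigs Named vector of contig lengths in bp; default 50 contigs
#'   of 5 kbp.
#' @param mean_depth Mean read depth at SNV sites (default 200).
#' @param out_dir Optional directory; writes `snvs.tsv` and
#'   `snv_truth.json`.
#' @return List with `snvs` (data.frame `contig`, `pos`, `ref_depth`,
#'   `alt_depth`, `freq`) and `truth`.
#' @export
gen_snvs <- function(seed, regime = c("strain-uniform", "diploid-central"),
                     n_snvs = 1000, contigs = NULL, mean_depth = 200,
                     out_dir = NULL) {
  regime <- match.arg(regime)
  if (n_snvs <= 0) stop_arg("n_snvs must be >= 1")
  if (is.null(contigs))
    contigs <- stats::setNames(rep(5000, 50), sprintf("contig_%02d", 1:50))
  with_seed(seed, {
    freq <- if (regime == "strain-uniform") {
      stats::runif(n_snvs, 0.05, 0.95)
    } else {
      f <- stats::rnorm(n_snvs, 0.5, 0.05)
      while (any(bad <- f <= 0 | f >= 1))
        f[bad] <- stats::rnorm(sum(bad), 0.5, 0.05)
      f
    }
    ctg <- sample(names(contigs), n_snvs, replace = TRUE,
                  prob = contigs / sum(contigs))
    pos <- floor(stats::runif(n_snvs) * contigs[ctg]) + 1
    depth <- stats::rpois(n_snvs, mean_depth) + 2L
    alt <- pmin(pmax(round(freq * depth), 1L), depth - 1L)
    snvs <- data.frame(contig = ctg, pos = as.numeric(pos),
                       ref_depth = depth - alt, alt_depth = alt,
                       freq = alt / depth, stringsAsFactors = FALSE)
    truth <- list(regime = regime, n_snvs = n_snvs, seed = seed)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(snvs[, c("contig", "pos", "ref_depth", "alt_depth")],
                file.path(out_dir, "snvs.tsv"))
      jsonlite::write_json(truth, file.path(out_dir, "snv_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(snvs = snvs, truth = truth)
  })
}

#' Default lifestyle design for the annotation generator
#'
#' Group sizes and per-category count means for the five lifestyles the
#' comparative figures centre on. Where a group mean is published it is
#' used directly (e.g. CAZymes 175/240/629 for G-AMF/ECM/ERM, transporters
#' 3900 for G-AMF); the remaining means are fixed once at values consistent
#' with the published group ordering.
#'
#' @return Named list: lifestyle -> list(`n`, `means` (per category),
#'   `substrate_means` (per transporter substrate)).
#' @export
default_annotation_design <- function() {
  list(
    "G-AMF" = list(n = 12,
                   means = c(CAZyme = 175, lipase = 189, protease = 305,
                             transporter = 3900, SSP = 15),
                   substrate_means = c(phosphate = 18, calcium = 55,
                                       copper = 15, nitrate = 7,
                                       ammonium = 9, glycine = 3)),
    "ECM" = list(n = 42,
                 means = c(CAZyme = 240, lipase = 238, protease = 286,
                           transporter = 2500, SSP = 15),
                 substrate_means = c(phosphate = 14, calcium = 30,
                                     copper = 15, nitrate = 2,
                                     ammonium = 4, glycine = 1)),
    "ERM" = list(n = 4,
                 means = c(CAZyme = 629, lipase = 400, protease = 457,
                           transporter = 3600, SSP = 20),
                 substrate_means = c(phosphate = 25, calcium = 35,
                                     copper = 16, nitrate = 3,
                                     ammonium = 11, glycine = 5)),
    "OCM" = list(n = 3,
                 means = c(CAZyme = 300, lipase = 268, protease = 300,
                           transporter = 2500, SSP = 15),
                 substrate_means = c(phosphate = 15, calcium = 30,
                                     copper = 14, nitrate = 1,
                                     ammonium = 4, glycine = 1)),
    "SAP" = list(n = 146,
                 means = c(CAZyme = 400, lipase = 263, protease = 271,
                           transporter = 2500, SSP = 25),
                 substrate_means = c(phosphate = 15, calcium = 33,
                                     copper = 16, nitrate = 1,
                                     ammonium = 6, glycine = 4))
  )
}

rcount <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = dispersion)
}

#' Simulate lifestyle-stratified functional annotation tables
#'
#' Draws per-genome category counts around lifestyle group means
#' (negative-binomial with common `dispersion`; `Inf` gives the Poisson
#' limit), emits one annotation row per protein with CAZy families sampled
#' from the shipped substrate map and transporter substrates drawn around
#' lifestyle substrate means, and plants pathway truth: every genome
#' carries the cellulose, chitin and vitamin-B6 role identifiers except
#' G-AMF genomes, which omit beta-glucosidase (EC 3.2.1.21) and pyridoxine
#' kinase (EC 2.7.1.35) by construction; no genome carries thiamine or
#' cytosolic fatty-acid synthesis identifiers.
#'
#' @param seed Integer RNG seed.
#' @param design Lifestyle design ([default_annotation_design()]).
#' @param dispersion Negative-binomial size parameter (default 10; `Inf`
#'   for Poisson).
#' @param out_dir Optional directory; writes `annotations.tsv`,
#'   `lifestyles.tsv`, `annotation_truth.json`.
#' @return List with `annotations` (data.frame), `lifestyles` (data.frame),
#'   and `truth` (per-genome planted pathway status).
#' @export
gen_annotations <- function(seed, design = default_annotation_design(),
                            dispersion = 10, out_dir = NULL) {
  bad <- setdiff(names(design), lifestyle_vocabulary())
  if (length(bad))
    stop_arg("unknown lifestyle label(s) in design: ", paste(bad, collapse = ", "))
  for (ls in names(design))
    if (any(design[[ls]]$means <= 0)) stop_arg("design means must be > 0")
  with_seed(seed, {
    fam_pool <- names(default_substrate_map())
    cats <- annotation_categories()
    subs <- transporter_substrates()
    ann <- vector("list", 0)
    life <- vector("list", 0)
    truth_rows <- vector("list", 0)
    for (ls in names(design)) {
      d <- design[[ls]]
      for (gi in seq_len(d$n)) {
        gname <- sprintf("%s_g%03d", gsub("-", "", ls), gi)
        counts <- stats::setNames(
          vapply(cats, function(cc) rcount(1, d$means[[cc]], dispersion),
                 numeric(1)), cats)
        counts <- pmax(counts, 1)
        # transporter substrate split
        smeans <- d$substrate_means
        scounts <- stats::setNames(
          vapply(subs, function(s) rcount(1, smeans[[s]], dispersion),
                 numeric(1)), subs)
        n_tr <- max(counts[["transporter"]], sum(scounts) + 1)
        sub_lab <- c(rep(subs, times = scounts),
                     rep("other", n_tr - sum(scounts)))
        n_caz <- counts[["CAZyme"]]
        fam <- sample(fam_pool, n_caz, replace = TRUE)
        # plant the cellulose-role families so completeness has known truth
        is_gamf <- ls == "G-AMF"
        fam[1] <- "GH9"                                  # endoglucanase
        if (n_caz >= 2) fam[2] <- "GH18"                 # chitinase
        if (n_caz >= 3) fam[3] <- "CE4"                  # chitin deacetylase
        ecs <- rep(NA_character_, n_caz)
        ecs[1] <- "3.2.1.4"
        if (n_caz >= 2) ecs[2] <- "3.2.1.14;3.2.1.52"
        if (n_caz >= 4) ecs[4] <- "3.2.1.91"             # exoglucanase
        if (!is_gamf && n_caz >= 5) ecs[5] <- "3.2.1.21" # beta-glucosidase
        n_prot <- counts[["protease"]]
        pecs <- rep(NA_character_, n_prot)
        pecs[1] <- "1.4.3.5;1.1.1.65"                    # B6 partners
        if (!is_gamf && n_prot >= 2) pecs[2] <- "2.7.1.35"
        gann <- data.frame(
          genome = gname,
          protein = sprintf("%s_p%05d", gname, seq_len(sum(c(
            n_caz, counts[["lipase"]], n_prot, n_tr, counts[["SSP"]])))),
          category = rep(c("CAZyme", "lipase", "protease", "transporter",
                           "SSP"),
                         times = c(n_caz, counts[["lipase"]], n_prot, n_tr,
                                   counts[["SSP"]])),
          cazy_family = c(fam, rep(NA_character_,
                                   counts[["lipase"]] + n_prot + n_tr +
                                     counts[["SSP"]])),
          ec_numbers = c(ecs, rep(NA_character_, counts[["lipase"]]), pecs,
                         rep(NA_character_, n_tr + counts[["SSP"]])),
          transporter_substrate = c(rep(NA_character_,
                                        n_caz + counts[["lipase"]] + n_prot),
                                    sub_lab,
                                    rep(NA_character_, counts[["SSP"]])),
          stringsAsFactors = FALSE)
        ann[[length(ann) + 1L]] <- gann
        life[[length(life) + 1L]] <- data.frame(genome = gname, lifestyle = ls,
                                                stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          genome = gname, lifestyle = ls,
          cellulose_complete = !is_gamf && n_caz >= 5,
          vitamin_b6_complete = !is_gamf && n_prot >= 2,
          pyridoxine_kinase = !is_gamf && n_prot >= 2,
          stringsAsFactors = FALSE)
      }
    }
    annotations <- do.call(rbind, ann)
    lifestyles <- do.call(rbind, life)
    truth <- list(design = lapply(design, function(d)
      list(n = d$n, means = as.list(d$means))),
      dispersion = dispersion, seed = seed,
      genomes = do.call(rbind, truth_rows))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(annotations, file.path(out_dir, "annotations.tsv"))
      write_tsv(lifestyles, file.path(out_dir, "lifestyles.tsv"))
      jsonlite::write_json(truth, file.path(out_dir, "annotation_truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    list(annotations = annotations, lifestyles = lifestyles, truth = truth)
  })
}
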