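test_that("generators are byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_assembly(seed = 31, genome_length = 6e4, n_decoy_genomes = 1,
               decoy_length = 2e4, out_dir = d1)
  gen_assembly(seed = 31, genome_length = 6e4, n_decoy_genomes = 1,
               decoy_length = 2e4, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  a <- gen_coverage(seed = 32, gen_assembly(seed = 31, genome_length = 6e4)$truth,
                    unitig_lengths(gen_assembly(seed = 31, genome_length = 6e4)$graph))
  b <- gen_coverage(seed = 32, gen_assembly(seed = 31, genome_length = 6e4)$truth,
                    unitig_lengths(gen_assembly(seed = 31, genome_length = 6e4)$graph))
  expect_identical(a$taxa_counts, b$taxa_counts)
})

test_that("realized fragment N50 lands near the requested value", {
  n50s <- vapply(1:15, function(s) {
    sim <- gen_assembly(seed = 1200 + s, genome_length = 1e6,
                        fragment_n50 = 5000, n_decoy_genomes = 0)
    lens <- unitig_lengths(sim$graph)
    assembly_stats(as.numeric(lens))$n50
  }, numeric(1))
  expect_true(all(n50s >= 2500 & n50s <= 10000))
})

test_that("planted operon copies are split and recoverable at identity 1", {
  sim <- gen_assembly(seed = 33, rdna_copies = 3)
  expect_equal(nrow(sim$truth$operon_placements), 3L)
  split_ok <- tapply(sim$truth$marker_unitigs$unitig_id,
                     sim$truth$marker_unitigs$copy,
                     function(u) length(unique(u)) >= 2)
  expect_true(all(split_ok))
  hits <- flag_marker_unitigs(sim$graph, truth_alignments(sim$truth),
                              min_identity = 1.0, min_aln_len = 0,
                              ref_length = sim$truth$operon_length)
  expect_equal(hits$breadth, 1.0)
  expect_setequal(unique(hits$hits$unitig_id),
                  unique(sim$truth$marker_unitigs$unitig_id))
  # the planted intervals really carry the reference sequence
  mk <- sim$truth$marker_unitigs
  seqs <- stats::setNames(sim$graph$unitigs$sequence, sim$graph$unitigs$id)
  for (k in sample(nrow(mk), 3)) {
    ref_piece <- substr(sim$reference, mk$ref_start[k] + 1, mk$ref_end[k])
    expect_true(grepl(ref_piece, seqs[mk$unitig_id[k]], fixed = TRUE))
  }
  expect_error(gen_assembly(seed = 1, genome_length = 1e4, operon_length = 4500,
                            rdna_copies = 3), "infeasible")
})

test_that("noise-free coverage links the planted taxon with r = 1 and exact slope", {
  sim <- gen_assembly(seed = 34, genome_length = 8e4, n_decoy_genomes = 1,
                      decoy_length = 2e4)
  lens <- unitig_lengths(sim$graph)
  cov <- gen_coverage(seed = 35, sim$truth, lens, noise_cv = 0)
  bp <- bin_coverage_profile(cov$depth_table, sim$bins, lens, cov$sample_totals)
  taxa <- filter_and_normalise_taxa(cov$taxa_counts, 10, cov$sample_totals)
  links <- link_bin_to_taxa(bp$norm[sim$truth$target_bin, ], taxa)
  expect_equal(links$taxon[1], cov$truth$planted_taxon)
  expect_equal(links$r[1], 1.0, tolerance = 1e-3)   # counts are rounded reads
  expect_equal(links$slope[1], 63, tolerance = 0.01)
})

test_that("the read floor removes exactly the planted low-count decoys", {
  sim <- gen_assembly(seed = 36, genome_length = 6e4, n_decoy_genomes = 0)
  cov <- gen_coverage(seed = 37, sim$truth, unitig_lengths(sim$graph))
  taxa <- filter_and_normalise_taxa(cov$taxa_counts, 10, cov$sample_totals)
  expect_setequal(setdiff(rownames(cov$taxa_counts), rownames(taxa$norm)),
                  cov$truth$low_decoys)
  expect_equal(nrow(taxa$norm), 251 - 20)
})

test_that("SNV regimes close the loop through the spectrum classifier", {
  d <- gen_snvs(seed = 38, "diploid-central", 1000)
  expect_equal(snv_spectrum(d$snvs)$label, "haplotype-like")
  u <- gen_snvs(seed = 39, "strain-uniform", 1000)
  expect_equal(snv_spectrum(u$snvs)$label, "strain-diversity-like")
  one <- gen_snvs(seed = 40, "strain-uniform", 1)
  expect_equal(nrow(one$snvs), 1L)
  expect_true(all(one$snvs$freq > 0 & one$snvs$freq < 1))
  expect_error(gen_snvs(seed = 1, "strain-uniform", 0), "n_snvs")
  # positions stay within their contigs
  ctg <- c(c1 = 1000, c2 = 300)
  s <- gen_snvs(seed = 41, "strain-uniform", 200, contigs = ctg)
  expect_true(all(s$snvs$pos >= 1 & s$snvs$pos <= ctg[s$snvs$contig]))
})

test_that("emitted files validate against the package readers", {
  d <- withr::local_tempdir()
  sim <- gen_assembly(seed = 42, genome_length = 6e4, n_decoy_genomes = 1,
                      decoy_length = 2e4, out_dir = d)
  expect_no_warning(g <- parse_gfa(file.path(d, "assembly.gfa")))
  expect_equal(nrow(g$unitigs), nrow(sim$graph$unitigs))
  tab <- read_bin_table(file.path(d, "bins.tsv"))
  expect_equal(nrow(tab), nrow(sim$bins))
  gen_snvs(seed = 43, "strain-uniform", 50, out_dir = d)
  expect_equal(nrow(read_snvs(file.path(d, "snvs.tsv"))), 50L)
  small <- list("G-AMF" = list(n = 2,
                               means = c(CAZyme = 30, lipase = 10, protease = 10,
                                         transporter = 40, SSP = 3),
                               substrate_means = c(phosphate = 3, calcium = 6,
                                                   copper = 2, nitrate = 1,
                                                   ammonium = 1, glycine = 1)))
  gen_annotations(seed = 44, design = small, out_dir = d)
  ann <- load_annotations(file.path(d, "annotations.tsv"))
  expect_true(all(ann$category %in% annotation_categories()))
  expect_equal(nrow(load_lifestyles(file.path(d, "lifestyles.tsv"))), 2L)
})

test_that("annotation counts recover the design mean in the Poisson limit", {
  design <- list("SAP" = list(n = 200,
                              means = c(CAZyme = 175, lipase = 50, protease = 50,
                                        transporter = 100, SSP = 5),
                              substrate_means = c(phosphate = 5, calcium = 5,
                                                  copper = 5, nitrate = 2,
                                                  ammonium = 2, glycine = 2)))
  g <- gen_annotations(seed = 45, design = design, dispersion = Inf)
  cc <- count_categories(g$annotations)
  expect_equal(mean(cc$CAZyme), 175, tolerance = 0.05)
  expect_error(gen_annotations(seed = 1, design = list(XXX = list(n = 1))),
               "unknown lifestyle")
})

test_that("G-AMF-like genomes lack beta-glucosidase and pyridoxine kinase by design", {
  design <- default_annotation_design()[c("G-AMF", "ERM")]
  design$`G-AMF`$n <- 4
  design$ERM$n <- 4
  g <- gen_annotations(seed = 46, design = design)
  ids <- genome_identifiers(g$annotations)
  pc <- pathway_completeness(ids)
  cel <- pc[pc$pathway == "cellulose", ]
  b6 <- pc[pc$pathway == "vitamin_b6", ]
  gamf <- g$lifestyles$genome[g$lifestyles$lifestyle == "G-AMF"]
  expect_true(all(!cel$complete[cel$genome %in% gamf]))
  expect_true(all(cel$complete[!(cel$genome %in% gamf)]))
  expect_true(all(!b6$complete[b6$genome %in% gamf]))
  expect_true(all(b6$complete[!(b6$genome %in% gamf)]))
})

test_that("contrasting group means separate with distinct letters", {
  design <- list(
    "G-AMF" = list(n = 10,
                   means = c(CAZyme = 175, lipase = 20, protease = 20,
                             transporter = 50, SSP = 3),
                   substrate_means = c(phosphate = 3, calcium = 6, copper = 2,
                                       nitrate = 1, ammonium = 1, glycine = 1)),
    "ERM" = list(n = 10,
                 means = c(CAZyme = 629, lipase = 20, protease = 20,
                           transporter = 50, SSP = 3),
                 substrate_means = c(phosphate = 3, calcium = 6, copper = 2,
                                     nitrate = 1, ammonium = 1, glycine = 1)))
  g <- gen_annotations(seed = 47, design = design)
  res <- group_compare(count_categories(g$annotations), g$lifestyles, "CAZyme")
  expect_false(res$letters[["G-AMF"]] == res$letters[["ERM"]])
})
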