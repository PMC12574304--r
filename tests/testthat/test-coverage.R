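test_that("bin coverage is length-weighted depth, normalized per million", {
  bins <- bin_assignment("c1", "binA")
  dt <- data.frame(contig = "c1", sample = "S1", mapped_bases = 50000)
  cm <- bin_coverage_profile(dt, bins, c(c1 = 1000), c(S1 = 1e6))
  expect_equal(unname(cm$raw["binA", "S1"]), 50)
  expect_equal(unname(cm$norm["binA", "S1"]), 50)

  # two contigs: (60*1000 + 20*3000) / 4000 = 30
  bins2 <- bin_assignment(c("c1", "c2"), c("binA", "binA"))
  dt2 <- data.frame(contig = c("c1", "c2"), sample = "S1",
                    mapped_bases = c(60 * 1000, 20 * 3000))
  cm2 <- bin_coverage_profile(dt2, bins2, c(c1 = 1000, c2 = 3000), c(S1 = 1e6))
  expect_equal(unname(cm2$raw["binA", "S1"]), 30)

  # all-zero mapped bases -> zero row, no error
  dt3 <- data.frame(contig = "c1", sample = c("S1", "S2"), mapped_bases = 0)
  cm3 <- bin_coverage_profile(dt3, bins, c(c1 = 1000), c(S1 = 1e6, S2 = 1e6))
  expect_equal(unname(cm3$norm["binA", ]), c(0, 0))

  expect_error(bin_coverage_profile(dt, bins2, c(c1 = 1000), c(S1 = 1e6)),
               "length for binned contig")
  expect_warning(
    bin_coverage_profile(dt, bin_assignment(c("c1", "c2"), c("binA", "binB")),
                         c(c1 = 1000, c2 = 0), c(S1 = 1e6)),
    "zero total contig length")
})

test_that("taxa with fewer than the read floor are removed, boundary retained", {
  m <- rbind(t9 = c(4, 5, 0), t10 = c(5, 5, 0), t250 = c(100, 100, 50))
  colnames(m) <- c("S1", "S2", "S3")
  tot <- c(S1 = 1e6, S2 = 1e6, S3 = 1e6)
  cm <- filter_and_normalise_taxa(m, 10, tot)
  expect_setequal(rownames(cm$norm), c("t10", "t250"))
  expect_equal(attr(cm, "filter_report")$removed, 1L)
  expect_error(filter_and_normalise_taxa(m, -1, tot), "min_total_reads")
})

test_that("random count matrices filter exactly as the brute-force row-sum rule", {
  set.seed(601)
  for (case in 1:20) {
    m <- matrix(rpois(300 * 6, lambda = 2), nrow = 300,
                dimnames = list(sprintf("t%03d", 1:300), sprintf("S%d", 1:6)))
    thr <- sample(5:20, 1)
    cm <- filter_and_normalise_taxa(m, thr, setNames(rep(1e6, 6), colnames(m)))
    expect_setequal(rownames(cm$norm), rownames(m)[rowSums(m) >= thr])
  }
})

test_that("normalization is scale-equivariant in sample totals", {
  set.seed(602)
  m <- matrix(rpois(40, 50), nrow = 8,
              dimnames = list(paste0("t", 1:8), sprintf("S%d", 1:5)))
  tot <- setNames(runif(5, 1e5, 1e6), colnames(m))
  a <- coverage_matrix(m, tot)
  m2 <- m; m2[, "S3"] <- m2[, "S3"] * 7
  tot2 <- tot; tot2["S3"] <- tot2["S3"] * 7
  b <- coverage_matrix(m2, tot2)
  expect_equal(a$norm, b$norm)
  expect_equal(a$norm[rowSums(m) == 0, ], b$norm[rowSums(m) == 0, ])
})

test_that("a perfectly proportional taxon links with r = 1 at the top", {
  set.seed(603)
  x <- setNames(exp(runif(12, 0, 6)), sprintf("S%02d", 1:12))
  taxa_raw <- rbind(good = 63 * x,
                    noise1 = runif(12, 1, 100),
                    noise2 = runif(12, 1, 100))
  taxa <- coverage_matrix(taxa_raw, setNames(rep(1e6, 12), names(x)))
  res <- link_bin_to_taxa(x, taxa)
  expect_equal(res$taxon[1], "good")
  expect_equal(res$r[1], 1.0, tolerance = 1e-12)
  expect_equal(res$slope[1], 63, tolerance = 1e-9)
  expect_equal(res$rank, 1:3)
})

test_that("Pearson r matches the direct formula and BH keeps p-value order", {
  set.seed(604)
  x <- setNames(rnorm(10, 50, 20), paste0("S", 1:10))
  taxa_raw <- matrix(abs(rnorm(200 * 10, 50, 20)), nrow = 200,
                     dimnames = list(paste0("t", 1:200), names(x)))
  taxa <- coverage_matrix(taxa_raw, setNames(rep(1e6, 10), names(x)))
  res <- link_bin_to_taxa(abs(x), taxa)
  for (i in sample(nrow(res), 25)) {
    y <- taxa$norm[res$taxon[i], ]
    expect_equal(res$r[i], oracle_pearson(abs(x), y), tolerance = 1e-12)
  }
  expect_true(all(res$p_adj >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))     # monotone in raw-p rank
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})

test_that("degenerate profiles are rejected or excluded as specified", {
  x <- setNames(c(1, 2, 3, 4), paste0("S", 1:4))
  taxa <- coverage_matrix(
    matrix(c(5, 5, 5, 5, 1, 2, 3, 5), nrow = 2, byrow = TRUE,
           dimnames = list(c("flat", "ok"), names(x))),
    setNames(rep(1e6, 4), names(x)))
  expect_message(res <- link_bin_to_taxa(x, taxa), "zero-variance")
  expect_equal(attr(res, "excluded"), "flat")
  expect_equal(res$taxon, "ok")
  expect_error(link_bin_to_taxa(setNames(rep(1, 4), names(x)), taxa),
               "zero variance")
  expect_error(link_bin_to_taxa(x[1:2], taxa), "3 shared samples")
})

test_that("copy number is exact on proportional data and bootstrap is seeded", {
  x <- setNames(c(2, 10, 50, 250, 30, 7), paste0("S", 1:6))
  est <- estimate_copy_number(63 * x, x, seed = 9)
  expect_equal(est$slope, 63, tolerance = 1e-12)
  expect_equal(est$copies, 63)
  expect_equal(est$ci[1], 63, tolerance = 1e-9)   # no noise: degenerate CI
  est2 <- estimate_copy_number(63 * x, x, seed = 9)
  expect_identical(est$ci, est2$ci)
  expect_error(estimate_copy_number(x, setNames(rep(0, 6), names(x))),
               "all zero")
})

test_that("noisy planted slopes are recovered within tolerance", {
  set.seed(605)
  hits <- 0L
  for (i in 1:30) {
    x <- setNames(exp(runif(12, log(1), log(568))), sprintf("S%02d", 1:12))
    sigma <- sqrt(log(1 + 0.1^2))
    y <- 63 * x * exp(rnorm(12, -sigma^2 / 2, sigma))
    est <- estimate_copy_number(y, x, n_boot = 200, seed = i)
    if (abs(est$slope - 63) / 63 <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 27L)
  # free-intercept variant reports an intercept
  x <- setNames(1:6, paste0("S", 1:6))
  est <- estimate_copy_number(10 + 5 * x, x, intercept = TRUE, n_boot = 50)
  expect_equal(est$slope, 5, tolerance = 1e-9)
  expect_equal(est$intercept, 10, tolerance = 1e-9)
})
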