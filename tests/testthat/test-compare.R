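toy_annotations <- function() {
  fams <- c(rep("AA9", 6), rep("GH9", 3), rep("AA1", 2), "AA1_2", "AA2",
            rep("CE4", 16), rep("GH18", 13))
  n <- length(fams)
  data.frame(genome = "MAG",
             protein = sprintf("p%03d", seq_len(n + 4)),
             category = c(rep("CAZyme", n), "lipase", "protease",
                          "transporter", "SSP"),
             cazy_family = c(fams, rep(NA, 4)),
             ec_numbers = NA_character_,
             transporter_substrate = c(rep(NA, n), NA, NA, "copper", NA),
             stringsAsFactors = FALSE)
}

test_that("category counts tally per genome and sum to the annotated total", {
  tab <- toy_annotations()
  cc <- count_categories(tab)
  expect_equal(cc$CAZyme, 42L)
  expect_equal(cc$lipase, 1L)
  expect_equal(cc$total, 46L)

  empty <- tab[0, ]
  expect_equal(nrow(count_categories(empty)), 0L)

  dup <- rbind(tab, tab[1, ])
  expect_error(count_categories(dup), "duplicate")
})

test_that("substrate classification reproduces the hand tally", {
  prof <- classify_substrates(toy_annotations())
  expect_equal(prof$cellulose, 9L)       # 6 AA9 + 3 GH9
  expect_equal(prof$lignin, 4L)          # 2 AA1 + 1 AA1_2 + 1 AA2
  expect_equal(prof$chitin, 29L)         # 16 CE4 + 13 GH18
  expect_equal(prof$PCWDE, 13L)
  expect_equal(prof$MCWDE, 29L)
  expect_equal(prof$unclassified, 0L)
})

test_that("unmapped families route to unclassified without touching totals", {
  tab <- toy_annotations()
  tab$cazy_family[tab$cazy_family == "AA2"] <- "GH151"
  prof <- classify_substrates(tab)
  expect_equal(prof$unclassified, 1L)
  expect_equal(prof$lignin, 3L)
  expect_equal(prof$PCWDE, 12L)
  expect_equal(attr(prof, "unmapped_families"), "GH151")
})

test_that("multi-group families count once per side under unique-protein totals", {
  tab <- data.frame(genome = "g", protein = c("p1", "p2"),
                    category = "CAZyme", cazy_family = c("X1", "X1"),
                    stringsAsFactors = FALSE)
  map <- list(X1 = c("cellulose", "pectin"))
  uni <- classify_substrates(tab, map)
  expect_equal(uni$cellulose, 2L)
  expect_equal(uni$pectin, 2L)
  expect_equal(uni$PCWDE, 2L)            # each protein once per side
  per <- classify_substrates(tab, map, side_totals = "per-group")
  expect_equal(per$PCWDE, 4L)
})

test_that("classification is idempotent and invariant to row order", {
  tab <- toy_annotations()
  set.seed(801)
  shuf <- tab[sample(nrow(tab)), ]
  a <- classify_substrates(tab)
  b <- classify_substrates(shuf)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("pathway completeness requires every role, reports the missing ones", {
  mag <- c("3.2.1.4", "3.2.1.21", "3.2.1.91", "GH18", "CE4", "3.2.1.52",
           "2.7.1.35", "1.4.3.5", "1.1.1.65")
  pc <- pathway_completeness(mag)
  pc <- setNames(pc$complete, pc$pathway)
  expect_true(pc[["cellulose"]])
  expect_true(pc[["chitin"]])
  expect_true(pc[["vitamin_b6"]])
  expect_false(pc[["thiamine"]])
  expect_false(pc[["fatty_acid"]])

  gamf <- setdiff(mag, c("3.2.1.21", "2.7.1.35"))
  pg <- pathway_completeness(gamf)
  cel <- pg[pg$pathway == "cellulose", ]
  expect_false(cel$complete)
  expect_equal(cel$missing_roles, "beta_glucosidase")
  expect_equal(cel$fraction, 2 / 3)

  pe <- pathway_completeness(character())
  expect_true(all(pe$fraction == 0))
  expect_error(pathway_completeness(mag, list()), "empty")
})

test_that("EC wildcards and bypass groups satisfy roles", {
  # trailing-dash wildcard in the genome's annotation matches the full EC
  expect_true(pathway_completeness(c("3.2.1.-", "3.2.1.21", "GH7"))$complete[1])
  # bypass group: all three members needed
  defs <- list(p = list(role1 = list(any_of = character(),
                                     groups = list(c("1.1.1.1", "2.2.2.2")))))
  expect_false(pathway_completeness("1.1.1.1", defs)$complete)
  expect_true(pathway_completeness(c("1.1.1.1", "2.2.2.2"), defs)$complete)
})

test_that("completeness is monotone under added identifiers", {
  set.seed(802)
  pool <- c("3.2.1.4", "3.2.1.21", "3.2.1.91", "GH18", "CE4", "3.2.1.52",
            "2.5.1.3", "2.7.1.49", "2.3.1.86", "2.7.1.35", "1.4.3.5",
            "1.1.1.65", "GH9", "GH3")
  for (i in 1:25) {
    base <- sample(pool, sample(0:10, 1))
    more <- union(base, sample(pool, sample(1:4, 1)))
    a <- pathway_completeness(base)
    b <- pathway_completeness(more)
    expect_true(all(b$fraction >= a$fraction - 1e-12))
    expect_true(all(!a$complete | b$complete))
  }
})

test_that("transporter substrates count per category with other aggregated", {
  set.seed(803)
  subs <- c(transporter_substrates(), "iron", "")
  n <- 50
  tab <- data.frame(genome = "g", protein = sprintf("p%02d", 1:n),
                    category = "transporter",
                    transporter_substrate = sample(subs, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  res <- count_transporter_substrates(tab)
  for (s in transporter_substrates())
    expect_equal(res[[s]], sum(tab$transporter_substrate == s))
  expect_equal(res$other, sum(!(tab$transporter_substrate %in%
                                  transporter_substrates())))
  expect_equal(sum(unlist(res[, -1])), n)
})

test_that("Dunn z-statistics and letters agree with the pairwise matrix", {
  set.seed(804)
  for (case in 1:10) {
    k <- sample(3:5, 1)
    vals <- rnorm(8 * k, mean = rep(sample(0:3, k, TRUE), each = 8))
    grp <- rep(LETTERS[1:k], each = 8)
    dn <- dunn_test(vals, grp)
    expect_true(isSymmetric(dn$p_adj))
    expect_true(all(dn$p_adj >= dn$p_raw - 1e-12, na.rm = TRUE))
    med <- tapply(vals, grp, median)
    let <- compact_letters(dn$p_adj, alpha = 0.05, order_stat = med)
    # exhaustive pair audit: sharing a letter <=> not significant
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      share <- length(intersect(strsplit(let[i], "")[[1]],
                                strsplit(let[j], "")[[1]])) > 0
      signif <- dn$p_adj[i, j] < 0.05
      expect_equal(share, !signif)
    }
  }
})

test_that("non-overlapping groups get distinct letters, identical data one letter", {
  prof <- data.frame(genome = sprintf("g%02d", 1:12),
                     CAZyme = c(1:6, 101:106))
  ls <- data.frame(genome = prof$genome,
                   lifestyle = rep(c("G-AMF", "ERM"), each = 6))
  res <- group_compare(prof, ls, "CAZyme", alpha_kw = 0.01)
  expect_lt(res$kw$p, 0.01)
  expect_false(res$letters[["G-AMF"]] == res$letters[["ERM"]])
  expect_equal(res$letters[["ERM"]], "a")      # higher median gets 'a'

  prof$CAZyme <- 7
  res2 <- group_compare(prof, ls, "CAZyme")
  expect_equal(res2$kw$statistic, 0)
  expect_true(all(res2$letters == "a"))

  expect_error(group_compare(prof, ls, "nope"), "absent")
})

test_that("loaders validate vocabularies and round-trip cleanly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(genome = "g1", lifestyle = "AMF"), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_lifestyles(f), "G-AMF")     # message lists the vocabulary

  write.table(data.frame(genome = paste0("g", 1:10),
                         lifestyle = lifestyle_vocabulary()),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  ls <- load_lifestyles(f)
  expect_equal(nrow(ls), 10L)

  fa <- withr::local_tempfile(fileext = ".tsv")
  tab <- toy_annotations()
  write.table(tab, fa, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  back <- load_annotations(fa)
  expect_equal(count_categories(back), count_categories(tab))
  expect_equal(classify_substrates(back), classify_substrates(tab),
               ignore_attr = TRUE)

  # substrate map and pathway defs from JSON
  fm <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(AA9 = "cellulose",
                                   X1 = c("cellulose", "pectin"))), fm)
  m <- load_substrate_map(fm)
  expect_equal(m$X1, c("cellulose", "pectin"))
  writeLines(jsonlite::toJSON(list(AA9 = "plastic")), fm)
  expect_error(load_substrate_map(fm), "unknown substrate")

  fp <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(
    list(cellulose = list(endo = list(any_of = c("3.2.1.4")))),
    auto_unbox = FALSE), fp)
  defs <- load_pathway_defs(fp)
  expect_true(pathway_completeness("3.2.1.4", defs)$complete)
})
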