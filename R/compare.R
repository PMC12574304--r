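#' Controlled vocabularies for comparative profiling
#'
#' Lifestyle labels, annotation categories, transporter substrates, and the
#' substrate-group to cell-wall-side assignment used throughout the
#' comparative module.
#'
#' @return `lifestyle_vocabulary()`: character vector of the ten lifestyle
#'   labels; `annotation_categories()`: the five annotation categories;
#'   `transporter_substrates()`: the six scored transporter substrates;
#'   `substrate_sides()`: named vector mapping substrate group -> side
#'   (PCWDE or MCWDE).
#' @export
lifestyle_vocabulary <- function() {
  c("G-AMF", "ECM", "ERM", "OCM", "SAP", "PAT", "PAR", "END", "LIC", "MIX")
}

#' @rdname lifestyle_vocabulary
#' @export
annotation_categories <- function() {
  c("CAZyme", "lipase", "protease", "transporter", "SSP")
}

#' @rdname lifestyle_vocabulary
#' @export
transporter_substrates <- function() {
  c("phosphate", "calcium", "copper", "nitrate", "ammonium", "glycine")
}

#' @rdname lifestyle_vocabulary
#' @export
substrate_sides <- function() {
  c(cellulose = "PCWDE", hemicellulose = "PCWDE", lignin = "PCWDE",
    pectin = "PCWDE",
    chitin = "MCWDE", glycan = "MCWDE", mannan = "MCWDE",
    peptidoglycan = "MCWDE")
}

#' Default CAZy family -> substrate group map
#'
#' Seeded with every family-to-substrate pairing used in the shipped
#' analyses: AA9/GH9/AA3 cellulose; GH31/GH5_7/GH29/GH95 hemicellulose;
#' AA1/AA1_2/AA2 lignin; GH35/GH2/PL1_7/GH28 pectin; CE4/GH18 chitin;
#' GH92/GH125/GH76/CE17 mannan. GH151 (a poorly described
#' alpha-L-fucosidase family) is deliberately unmapped so it routes to
#' "unclassified". Family-to-substrate assignments drift with CAZy
#' releases, so the map is a plain named list that can be replaced wholesale
#' via [load_substrate_map()].
#'
#' @return Named list, family -> character vector of substrate groups.
#' @export
default_substrate_map <- function() {
  list(
    AA9 = "cellulose", GH9 = "cellulose", AA3 = "cellulose",
    GH31 = "hemicellulose", GH5_7 = "hemicellulose", GH29 = "hemicellulose",
    GH95 = "hemicellulose",
    AA1 = "lignin", AA1_2 = "lignin", AA2 = "lignin",
    GH35 = "pectin", GH2 = "pectin", PL1_7 = "pectin", GH28 = "pectin",
    CE4 = "chitin", GH18 = "chitin",
    GH92 = "mannan", GH125 = "mannan", GH76 = "mannan", CE17 = "mannan"
  )
}

#' Load a substrate map from JSON
#'
#' @param path JSON object mapping CAZy family to a substrate group or an
#'   array of groups.
#' @return Named list, family -> character vector of substrate groups.
#' @export
load_substrate_map <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  m <- lapply(m, function(v) as.character(unlist(v)))
  bad <- setdiff(unique(unlist(m)), names(substrate_sides()))
  if (length(bad))
    stop_arg("unknown substrate group(s) in map: ", paste(bad, collapse = ", "),
             "; allowed: ", paste(names(substrate_sides()), collapse = ", "))
  m
}

#' Load a genome -> lifestyle table
#'
#' @param path TSV with columns `genome` and `lifestyle` (header required).
#'   Lifestyle labels are validated against [lifestyle_vocabulary()].
#' @return data.frame with columns `genome`, `lifestyle`.
#' @export
load_lifestyles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("genome", "lifestyle") %in% names(df)))
    stop_arg("lifestyle table needs columns `genome` and `lifestyle`")
  bad <- which(!(df$lifestyle %in% lifestyle_vocabulary()))
  if (length(bad))
    stop_arg("unknown lifestyle label(s) at row(s) ",
             paste(bad, collapse = ", "), ": ",
             paste(unique(df$lifestyle[bad]), collapse = ", "),
             "; allowed: ", paste(lifestyle_vocabulary(), collapse = ", "))
  df[, c("genome", "lifestyle")]
}

validate_annotations <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("genome", "protein", "category")
  if (!all(need %in% names(df)))
    stop_arg("annotation table needs columns ", paste(need, collapse = ", "))
  bad <- which(!(df$category %in% annotation_categories()))
  if (length(bad))
    stop_arg("unknown category at row(s) ", paste(utils::head(bad, 10), collapse = ", "),
             ": ", paste(unique(df$category[bad]), collapse = ", "))
  if (is.null(df$cazy_family)) df$cazy_family <- NA_character_
  df$cazy_family[df$cazy_family %in% ""] <- NA_character_
  caz <- df$category == "CAZyme"
  orphan <- which(!is.na(df$cazy_family) & !caz)
  if (length(orphan))
    stop_arg("cazy_family set on non-CAZyme row(s): ",
             paste(utils::head(orphan, 10), collapse = ", "))
  if (any(caz & is.na(df$cazy_family)))
    stop_arg("CAZyme row(s) without cazy_family: ",
             paste(utils::head(which(caz & is.na(df$cazy_family)), 10), collapse = ", "))
  if (is.null(df$ec_numbers)) df$ec_numbers <- NA_character_
  if (is.null(df$transporter_substrate))
    df$transporter_substrate <- NA_character_
  df$transporter_substrate[df$transporter_substrate %in% ""] <- NA_character_
  dup <- duplicated(df[, c("genome", "protein", "category")])
  if (any(dup))
    stop_arg("duplicate (genome, protein, category) row(s): ",
             paste(utils::head(which(dup), 10), collapse = ", "))
  df
}

#' Load a per-genome functional annotation table
#'
#' @param path TSV with header columns `genome`, `protein`, `category`
#'   (one of `r paste(annotation_categories(), collapse = ", ")`), and
#'   optionally `cazy_family` (required for CAZyme rows, forbidden
#'   elsewhere), `ec_numbers` (semicolon-joined) and
#'   `transporter_substrate`.
#' @return Validated data.frame.
#' @export
load_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_annotations(df)
}

#' Per-genome annotation category counts
#'
#' @param table Annotation table ([load_annotations()] or an equivalent
#'   data.frame).
#' @return data.frame with one row per genome, one column per category
#'   plus `total` (the total number of annotated proteins).
#' @export
count_categories <- function(table) {
  df <- validate_annotations(as.data.frame(table, stringsAsFactors = FALSE))
  cats <- annotation_categories()
  genomes <- sort(unique(df$genome))
  m <- matrix(0L, nrow = length(genomes), ncol = length(cats),
              dimnames = list(genomes, cats))
  if (nrow(df)) {
    tab <- table(df$genome, df$category)
    m[rownames(tab), colnames(tab)] <- tab
  }
  out <- data.frame(genome = genomes, m, total = rowSums(m),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  out
}

#' Substrate-group classification of CAZyme repertoires
#'
#' Maps each CAZyme to substrate groups through a family map and tallies
#' per-genome copy counts per group (a protein whose family maps to k
#' groups contributes to each of the k groups). PCWDE and MCWDE totals
#' count unique proteins per side by default (`side_totals =
#' "unique-protein"`), so a protein mapping to two plant-wall groups is
#' counted once toward PCWDE; `side_totals = "per-group"` sums the group
#' counts instead. Families absent from the map are tallied under
#' `unclassified` and do not enter the side totals.
#'
#' @param table Annotation table.
#' @param map Family -> substrate-group map ([default_substrate_map()]).
#' @param side_totals `"unique-protein"` (default) or `"per-group"`.
#' @return data.frame, one row per genome: one column per substrate group,
#'   `unclassified`, `PCWDE`, `MCWDE`. Attribute `unmapped_families` lists
#'   families not in the map.
#' @export
classify_substrates <- function(table, map = default_substrate_map(),
                                side_totals = c("unique-protein", "per-group")) {
  side_totals <- match.arg(side_totals)
  df <- validate_annotations(as.data.frame(table, stringsAsFactors = FALSE))
  df <- df[df$category == "CAZyme", , drop = FALSE]
  sides <- substrate_sides()
  groups <- names(sides)
  genomes <- sort(unique(df$genome))
  out <- matrix(0L, nrow = length(genomes),
                ncol = length(groups) + 3L,
                dimnames = list(genomes, c(groups, "unclassified",
                                           "PCWDE", "MCWDE")))
  unmapped <- character()
  for (g in genomes) {
    sub <- df[df$genome == g, , drop = FALSE]
    fam_groups <- map[sub$cazy_family]
    known <- sub$cazy_family %in% names(map)
    unmapped <- union(unmapped, unique(sub$cazy_family[!known]))
    out[g, "unclassified"] <- sum(!known)
    for (grp in groups)
      out[g, grp] <- sum(vapply(fam_groups[known],
                                function(v) grp %in% v, TRUE))
    per_side <- function(side) {
      in_side <- vapply(fam_groups[known],
                        function(v) any(sides[v] == side), TRUE)
      if (side_totals == "unique-protein") sum(in_side)
      else sum(out[g, groups[sides == side]])
    }
    out[g, "PCWDE"] <- per_side("PCWDE")
    out[g, "MCWDE"] <- per_side("MCWDE")
  }
  res <- data.frame(genome = genomes, out, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  attr(res, "unmapped_families") <- unmapped
  res
}

#' Per-genome transporter substrate counts
#'
#' @param table Annotation table.
#' @return data.frame, one row per genome, one column per substrate in
#'   [transporter_substrates()] plus `other` (any other or missing
#'   substrate label on transporter rows).
#' @export
count_transporter_substrates <- function(table) {
  df <- validate_annotations(as.data.frame(table, stringsAsFactors = FALSE))
  df <- df[df$category == "transporter", , drop = FALSE]
  subs <- transporter_substrates()
  genomes <- sort(unique(df$genome))
  lab <- ifelse(df$transporter_substrate %in% subs,
                df$transporter_substrate, "other")
  m <- matrix(0L, nrow = length(genomes), ncol = length(subs) + 1L,
              dimnames = list(genomes, c(subs, "other")))
  if (nrow(df)) {
    tab <- table(df$genome, factor(lab, levels = c(subs, "other")))
    m[rownames(tab), ] <- tab
  }
  data.frame(genome = genomes, m, stringsAsFactors = FALSE,
             check.names = FALSE, row.names = NULL)
}

normalize_ec <- function(x) sub("(\\.-)+$", "", trimws(x))

ec_matches <- function(have, id) {
  id <- normalize_ec(id)
  if (id %in% have) return(TRUE)
  # trailing-dash wildcards: a stored partial EC matches any completion
  any(startsWith(have, paste0(id, ".")) | startsWith(paste0(id, "."),
                                                     paste0(have, ".")))
}

#' Default pathway definitions
#'
#' Pathway-completeness panels used as biotrophy hallmarks. Each pathway is
#' a list of roles; a role is satisfied by any single identifier in
#' `any_of` (EC numbers, with trailing dashes as wildcards, or CAZy family
#' codes), or by all members of one of its `groups` (multi-step bypasses).
#' Shipped panels: cellulose degradation (endoglucanase, beta-glucosidase,
#' exoglucanase), chitin degradation (chitinase, chitin deacetylase,
#' beta-N-acetylhexosaminidase), thiamine biosynthesis (thiamine phosphate
#' synthase, hydroxymethylpyrimidine kinase), cytosolic fatty-acid
#' synthesis, and vitamin B6 metabolism (pyridoxine kinase EC 2.7.1.35,
#' pyridoxine 5'-phosphate oxidase, and pyridoxal-to-pyridoxine conversion
#' satisfied either directly by pyridoxine 4-dehydrogenase EC 1.1.1.65 or
#' by a three-step phosphorylation bypass group). The role identifiers are
#' a config, replaceable via [load_pathway_defs()].
#'
#' @return Named list of pathway definitions.
#' @export
default_pathway_defs <- function() {
  list(
    cellulose = list(
      endoglucanase = list(any_of = c("3.2.1.4", "GH9", "AA9")),
      beta_glucosidase = list(any_of = c("3.2.1.21", "GH3")),
      exoglucanase = list(any_of = c("3.2.1.91", "3.2.1.176", "GH7", "GH6"))
    ),
    chitin = list(
      chitinase = list(any_of = c("3.2.1.14", "GH18")),
      chitin_deacetylase = list(any_of = c("3.5.1.41", "CE4")),
      hexosaminidase = list(any_of = c("3.2.1.52", "GH20"))
    ),
    thiamine = list(
      thiamine_phosphate_synthase = list(any_of = "2.5.1.3"),
      hydroxymethylpyrimidine_kinase = list(any_of = "2.7.1.49")
    ),
    fatty_acid = list(
      cytosolic_fatty_acid_synthase = list(any_of = c("2.3.1.86", "2.3.1.85"))
    ),
    vitamin_b6 = list(
      pyridoxine_kinase = list(any_of = "2.7.1.35"),
      pnp_oxidase = list(any_of = "1.4.3.5"),
      pyridoxal_to_pyridoxine = list(
        any_of = "1.1.1.65",
        groups = list(c("2.7.1.35", "3.1.3.74", "1.4.3.5"))
      )
    )
  )
}

#' Load pathway definitions from JSON
#'
#' @param path JSON: object pathway -> object role -> object with `any_of`
#'   (array) and optional `groups` (array of arrays).
#' @return Named list of pathway definitions in [default_pathway_defs()]
#'   form.
#' @export
load_pathway_defs <- function(path) {
  defs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  defs <- lapply(defs, function(p) lapply(p, function(role) {
    list(any_of = as.character(unlist(role$any_of)),
         groups = lapply(role$groups %||% list(),
                         function(g) as.character(unlist(g))))
  }))
  validate_pathway_defs(defs)
  defs
}

validate_pathway_defs <- function(defs) {
  if (!length(defs)) stop_arg("empty pathway definitions")
  for (pw in names(defs)) {
    if (!length(defs[[pw]])) stop_arg("pathway '", pw, "' has no roles")
    for (role in names(defs[[pw]])) {
      r <- defs[[pw]][[role]]
      ids <- c(r$any_of, unlist(r$groups %||% list()))
      if (!length(ids))
        stop_arg("role '", role, "' of pathway '", pw, "' has no identifiers")
    }
  }
  invisible(defs)
}

role_present <- function(role, have) {
  if (any(vapply(role$any_of %||% character(), ec_matches, TRUE, have = have)))
    return(TRUE)
  for (g in role$groups %||% list())
    if (all(vapply(g, ec_matches, TRUE, have = have))) return(TRUE)
  FALSE
}

#' Pathway-completeness scoring
#'
#' A pathway is complete when every role has at least one satisfying
#' identifier present in the genome's identifier set (EC numbers and/or
#' CAZy family codes). EC matching is exact on normalized ECs with trailing
#' dashes treated as wildcards on either side.
#'
#' @param identifiers Character vector of identifiers present in one
#'   genome, or a named list of such vectors (one per genome).
#' @param defs Pathway definitions ([default_pathway_defs()]).
#' @return data.frame with columns `genome` (`"genome"` when a bare vector
#'   was given), `pathway`, `complete`, `fraction`, `missing_roles`
#'   (comma-joined).
#' @export
pathway_completeness <- function(identifiers, defs = default_pathway_defs()) {
  validate_pathway_defs(defs)
  if (!is.list(identifiers)) identifiers <- list(genome = identifiers)
  rows <- list()
  for (g in names(identifiers)) {
    have <- normalize_ec(as.character(identifiers[[g]]))
    for (pw in names(defs)) {
      pres <- vapply(defs[[pw]], role_present, TRUE, have = have)
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, pathway = pw, complete = all(pres),
        fraction = mean(pres),
        missing_roles = paste(names(pres)[!pres], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Identifier sets per genome from an annotation table
#'
#' Collects, for each genome, the EC numbers (splitting semicolon-joined
#' fields) and CAZy family codes present, for use with
#' [pathway_completeness()].
#'
#' @param table Annotation table.
#' @return Named list, genome -> character vector of identifiers.
#' @export
genome_identifiers <- function(table) {
  df <- validate_annotations(as.data.frame(table, stringsAsFactors = FALSE))
  out <- lapply(split(df, df$genome), function(g) {
    ecs <- unlist(strsplit(g$ec_numbers[!is.na(g$ec_numbers)], ";",
                           fixed = TRUE))
    unique(c(normalize_ec(ecs), g$cazy_family[!is.na(g$cazy_family)]))
  })
  out
}

#' Dunn's post-hoc test on ranks
#'
#' All pairwise z-statistics on mean ranks after a Kruskal-Wallis omnibus
#' test, with the usual tie correction
#' `sigma2 = (N(N+1)/12 - sum(t^3 - t)/(12(N-1)))` and two-sided normal
#' p-values adjusted across all pairs.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector, same length.
#' @param adjust Adjustment method for [stats::p.adjust()] (default
#'   `"BH"`; `"holm"` available).
#' @return List with `z` and `p_adj` (symmetric matrices over groups),
#'   `p_raw`, and `mean_ranks`.
#' @export
dunn_test <- function(values, groups, adjust = "BH") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_arg("need >= 2 groups")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lv <- levels(groups)
  z <- p <- matrix(NA_real_, nlevels(groups), nlevels(groups),
                   dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    se <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    zij <- (rbar[i] - rbar[j]) / se
    z[i, j] <- z[j, i] <- zij
    p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(zij))
  }
  praw <- p[upper.tri(p)]
  padj <- stats::p.adjust(praw, method = adjust)
  p_adj <- p
  p_adj[upper.tri(p_adj)] <- padj
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(z = z, p_raw = p, p_adj = p_adj, mean_ranks = rbar)
}

# maximal cliques of an undirected adjacency matrix (Bron-Kerbosch);
# group counts here are small (<= 10 lifestyles)
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- R
      return()
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  out
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Groups sharing a letter are not significantly different: every maximal
#' clique of the non-significant-pair graph receives one letter, assigned
#' in descending order of the clique's best group statistic (typically the
#' group median) so that `"a"` marks the top group.
#'
#' @param p_adj Symmetric matrix of adjusted pairwise p-values.
#' @param alpha Significance level (default 0.05).
#' @param order_stat Named vector (e.g. group medians) used to order the
#'   letters; defaults to reverse alphabetical rank.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(p_adj, alpha = 0.05, order_stat = NULL) {
  gn <- rownames(p_adj)
  k <- length(gn)
  if (is.null(order_stat)) order_stat <- stats::setNames(rev(seq_len(k)), gn)
  adj <- p_adj >= alpha
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE  # a vertex is not its own neighbour for clique search
  cl <- maximal_cliques(adj)
  best <- vapply(cl, function(m) max(order_stat[gn[m]]), numeric(1))
  cl <- cl[order(-best)]
  letters_out <- stats::setNames(rep("", k), gn)
  for (i in seq_along(cl)) {
    l <- letters[(i - 1L) %% 26L + 1L]
    if (i > 26L) l <- paste0(l, (i - 1L) %/% 26L)
    m <- gn[cl[[i]]]
    letters_out[m] <- paste0(letters_out[m], l)
  }
  letters_out
}

#' Lifestyle group comparison of a functional metric
#'
#' Kruskal-Wallis omnibus test of a per-genome metric across ecological
#' lifestyles, followed (when the omnibus test is significant at
#' `alpha_kw`) by Dunn's pairwise post-hoc test and a compact letter
#' display at `alpha_dunn`. When the omnibus test is not significant all
#' groups share the letter `"a"`.
#'
#' @param profiles data.frame with a `genome` column and one column per
#'   metric (e.g. from [count_categories()], [classify_substrates()] or
#'   [count_transporter_substrates()]).
#' @param lifestyles data.frame from [load_lifestyles()].
#' @param metric Name of the metric column to compare.
#' @param alpha_kw Omnibus significance level (default 0.01).
#' @param alpha_dunn Post-hoc significance level (default 0.05).
#' @param adjust Dunn adjustment method (default `"BH"`).
#' @param min_group_size Groups with fewer members are dropped with a
#'   message (default 2).
#' @return List of class `group_test`: `metric`, `kw` (statistic, df, p),
#'   `dunn` (or `NULL`), `letters`, `medians`, `n`, the alphas.
#' @export
group_compare <- function(profiles, lifestyles, metric, alpha_kw = 0.01,
                          alpha_dunn = 0.05, adjust = "BH",
                          min_group_size = 2) {
  if (!(metric %in% names(profiles)))
    stop_arg("metric '", metric, "' absent from profiles; available: ",
             paste(setdiff(names(profiles), "genome"), collapse = ", "))
  df <- merge(profiles[, c("genome", metric)], lifestyles, by = "genome")
  sizes <- table(df$lifestyle)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    message("dropping lifestyle group(s) with < ", min_group_size,
            " members: ", paste(small, collapse = ", "))
    df <- df[!(df$lifestyle %in% small), , drop = FALSE]
  }
  if (length(unique(df$lifestyle)) < 2L)
    stop_arg("need >= 2 lifestyle groups with >= ", min_group_size, " members")
  vals <- df[[metric]]
  grp <- factor(df$lifestyle)
  kw <- stats::kruskal.test(vals, grp)
  if (is.nan(kw$statistic)) {  # all values tied: no evidence of difference
    kw$statistic <- 0
    kw$p.value <- 1
  }
  medians <- tapply(vals, grp, stats::median)
  dunn <- NULL
  if (!is.na(kw$p.value) && kw$p.value < alpha_kw) {
    dunn <- dunn_test(vals, grp, adjust = adjust)
    letters_out <- compact_letters(dunn$p_adj, alpha = alpha_dunn,
                                   order_stat = medians)
  } else {
    letters_out <- stats::setNames(rep("a", nlevels(grp)), levels(grp))
  }
  structure(list(metric = metric,
                 kw = list(statistic = unname(kw$statistic),
                           df = unname(kw$parameter), p = kw$p.value),
                 dunn = dunn, letters = letters_out, medians = medians,
                 n = table(grp), alpha_kw = alpha_kw, alpha_dunn = alpha_dunn),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("group_test[%s]: Kruskal-Wallis H = %.3f (df %d), p = %.3g\n",
              x$metric, x$kw$statistic, x$kw$df, x$kw$p))
  tab <- data.frame(lifestyle = names(x$letters),
                    n = as.integer(x$n[names(x$letters)]),
                    median = as.numeric(x$medians[names(x$letters)]),
                    letters = unname(x$letters))
  print(tab, row.names = FALSE)
  invisible(x)
}
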