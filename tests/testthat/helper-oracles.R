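# Independent brute-force oracles. These deliberately use different
# algorithms from the package implementations they check.

# breadth of coverage by marking reference bases one by one
oracle_breadth <- function(ref_start, ref_end, ref_length) {
  covered <- logical(ref_length)
  for (k in seq_along(ref_start)) {
    lo <- max(ref_start[k] + 1, 1)
    hi <- min(ref_end[k], ref_length)
    if (hi >= lo) covered[lo:hi] <- TRUE
  }
  sum(covered) / ref_length
}

# N50 as the largest length L whose at-least-L contigs hold half the total
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= half) return(L)
  min(lengths)
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# context-subgraph distances by Floyd-Warshall on the transformed directed
# graph: leaving node u via a link with overlap o costs 0 when u is a seed,
# max(0, len(u) - o) otherwise
oracle_subgraph_distances <- function(graph, seeds) {
  ids <- graph$unitigs$id
  n <- length(ids)
  len <- stats::setNames(graph$unitigs$length, ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  lk <- graph$links
  if (nrow(lk)) for (k in seq_len(nrow(lk))) {
    u <- lk$from[k]; v <- lk$to[k]; o <- lk$overlap[k]
    cu <- if (u %in% seeds) 0 else max(0, len[u] - o)
    cv <- if (v %in% seeds) 0 else max(0, len[v] - o)
    D[u, v] <- min(D[u, v], cu)
    D[v, u] <- min(D[v, u], cv)
  }
  for (m in ids) D <- pmin(D, outer(D[, m], D[m, ], `+`))
  d <- apply(D[seeds, , drop = FALSE], 2, min)
  d[seeds] <- 0
  d
}

# semi-global alignment score by Gotoh DP (pattern global, subject local);
# a gap of length L costs open + L * ext, matching the aligner's convention
oracle_align_score <- function(pattern, subject, match = 1, mismatch = -1,
                               open = 4, ext = 1) {
  p <- strsplit(pattern, "")[[1]]; s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)
  Iy <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  for (i in 2:(m + 1)) {
    Ix[i, 1] <- max(M[i - 1, 1] - open - ext, Ix[i - 1, 1] - ext)
    for (j in 2:(n + 1)) {
      sc <- if (p[i - 1] == s[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + sc
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[m + 1, ], Ix[m + 1, ])
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# random small assembly graph with random overlaps
rand_graph <- function(n_nodes, p_link = 0.3, max_len = 5000) {
  ids <- sprintf("u%02d", seq_len(n_nodes))
  len <- sample(500:max_len, n_nodes, replace = TRUE)
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  pick <- pairs[stats::runif(nrow(pairs)) < p_link, , drop = FALSE]
  links <- if (nrow(pick)) {
    ov <- vapply(seq_len(nrow(pick)), function(k) {
      sample.int(min(len[pick[k, 1]], len[pick[k, 2]]), 1) - 1L
    }, integer(1))
    data.frame(from = ids[pick[, 1]], from_orient = "+",
               to = ids[pick[, 2]], to_orient = "+", overlap = ov,
               stringsAsFactors = FALSE)
  } else NULL
  assembly_graph(data.frame(id = ids, length = len,
                            stringsAsFactors = FALSE), links)
}

# chain graph helper: ids linked consecutively, zero overlaps
chain_graph <- function(ids, len) {
  assembly_graph(
    data.frame(id = ids, length = rep_len(len, length(ids)),
               stringsAsFactors = FALSE),
    data.frame(from = ids[-length(ids)], from_orient = "+",
               to = ids[-1], to_orient = "+", overlap = 0L,
               stringsAsFactors = FALSE))
}
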