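#' Bin assignment tables
#'
#' Represents the contig/unitig -> bin mapping produced by a binning tool.
#' When contig lengths are supplied, contigs shorter than `min_contig_len`
#' are excluded, mirroring the minimum-contig-length cutoff binning tools
#' apply.
#'
#' @param contigs Character vector of contig/unitig ids.
#' @param bins Character vector of bin ids, same length.
#' @param lengths Optional named vector of contig lengths in bp.
#' @param min_contig_len Minimum contig length in bp (default 1000); applied
#'   only when `lengths` is supplied.
#' @return data.frame with columns `contig`, `bin`, class `bin_assignment`.
#' @export
bin_assignment <- function(contigs, bins, lengths = NULL, min_contig_len = 1000) {
  if (length(contigs) != length(bins))
    stop_arg("`contigs` and `bins` must have equal length")
  if (anyDuplicated(contigs))
    stop_arg("each contig may map to at most one bin; duplicated: ",
             paste(unique(contigs[duplicated(contigs)]), collapse = ", "))
  df <- data.frame(contig = as.character(contigs), bin = as.character(bins),
                   stringsAsFactors = FALSE)
  if (!is.null(lengths)) {
    known <- df$contig %in% names(lengths)
    drop <- known & lengths[df$contig] < min_contig_len
    df <- df[!drop, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("bin_assignment", "data.frame")
  df
}

#' Read a contig -> bin table
#'
#' @param path TSV with two columns, `contig_id<TAB>bin_id` (no header, or a
#'   header line starting with `contig`).
#' @inheritParams bin_assignment
#' @return A [bin_assignment()].
#' @export
read_bin_table <- function(path, lengths = NULL, min_contig_len = 1000) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) && grepl("^contig", df[1, 1], ignore.case = TRUE))
    df <- df[-1, , drop = FALSE]
  bin_assignment(df[[1]], df[[2]], lengths = lengths,
                 min_contig_len = min_contig_len)
}

#' Extract the graph neighbourhood within a bp radius of seed unitigs
#'
#' Walks the assembly graph outward from the seed unitigs and keeps every
#' unitig whose distance is at most `radius`, where the distance of a
#' candidate is the minimum over paths of the summed, overlap-adjusted
#' lengths of the intervening unitigs between a seed and the candidate's
#' near end: each intervening unitig contributes `max(0, length - overlap of
#' the link leaving it toward the candidate)`, seeds contribute 0, and the
#' candidate's own length is not counted. Seeds and their direct neighbours
#' are therefore at distance 0. Links are traversed undirected.
#'
#' @param graph An [assembly_graph()].
#' @param seeds Character vector of seed unitig ids (non-empty, all present
#'   in the graph).
#' @param radius Radius in bp (>= 0).
#' @return Object of class `context_subgraph`: list with `member_ids`,
#'   `seed_ids`, `radius`, `distances` (named vector, bp) and `lengths`
#'   (member unitig lengths, bp).
#' @export
extract_context_subgraph <- function(graph, seeds, radius) {
  assert_scalar_number(radius, "radius", min = 0)
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop_arg("empty seed set")
  unknown <- setdiff(seeds, graph$unitigs$id)
  if (length(unknown))
    stop_arg("unknown seed id(s): ", paste(unknown, collapse = ", "))

  ids <- graph$unitigs$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  len <- graph$unitigs$length
  is_seed <- ids %in% seeds

  # adjacency with per-edge overlap, undirected
  adj <- vector("list", n)
  if (nrow(graph$links)) {
    fr <- idx[graph$links$from]; to <- idx[graph$links$to]
    ov <- graph$links$overlap
    for (k in seq_along(fr)) {
      adj[[fr[k]]] <- rbind(adj[[fr[k]]], c(to[k], ov[k]))
      adj[[to[k]]] <- rbind(adj[[to[k]]], c(fr[k], ov[k]))
    }
  }

  # Dijkstra from all seeds; cost of leaving node u via a link with overlap o
  # is 0 for seeds, max(0, len(u) - o) otherwise
  dist <- rep(Inf, n)
  dist[is_seed] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || is.infinite(dist[u]) || all(done)) break
    u <- u[1]
    if (done[u]) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      step <- if (is_seed[u]) rep(0, nrow(nb)) else pmax(0, len[u] - nb[, 2])
      nd <- dist[u] + step
      upd <- nd < dist[nb[, 1]]
      dist[nb[, 1][upd]] <- nd[upd]
    }
  }

  member <- dist <= radius
  members <- ids[member]
  ord <- order(dist[member], members)
  members <- members[ord]
  structure(list(member_ids = members,
                 seed_ids = seeds,
                 radius = radius,
                 distances = stats::setNames(dist[member][ord], members),
                 lengths = stats::setNames(len[member][ord], members)),
            class = "context_subgraph")
}

#' @export
print.context_subgraph <- function(x, ...) {
  cat(sprintf("context_subgraph: %d member(s) within %g bp of %d seed(s)\n",
              length(x$member_ids), x$radius, length(x$seed_ids)))
  invisible(x)
}

#' Colocate candidate bins on a context subgraph
#'
#' Tallies, for each bin with at least one member unitig inside the
#' subgraph, the number of member unitigs and their total length. Rows are
#' sorted by member bp descending (ties by bin id). Member unitigs with no
#' bin assignment are reported in the `unbinned` attribute, not as a row.
#'
#' @param subgraph A `context_subgraph` from [extract_context_subgraph()].
#' @param bins A [bin_assignment()].
#' @return data.frame with columns `bin`, `n_members`, `member_bp`;
#'   attribute `unbinned` is a list with `n_members` and `member_bp`.
#' @export
colocate_bins <- function(subgraph, bins) {
  members <- subgraph$member_ids
  map <- stats::setNames(bins$bin, bins$contig)
  bin_of <- map[members]
  binned <- !is.na(bin_of)
  if (!any(binned)) {
    out <- data.frame(bin = character(), n_members = integer(),
                      member_bp = numeric(), stringsAsFactors = FALSE)
  } else {
    bp <- tapply(subgraph$lengths[binned], bin_of[binned], sum)
    nm <- tapply(rep(1L, sum(binned)), bin_of[binned], sum)
    out <- data.frame(bin = names(bp), n_members = as.integer(nm),
                      member_bp = as.numeric(bp), stringsAsFactors = FALSE)
    out <- out[order(-out$member_bp, out$bin), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unbinned") <- list(n_members = sum(!binned),
                                member_bp = sum(subgraph$lengths[!binned]))
  out
}
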