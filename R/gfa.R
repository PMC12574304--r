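#' Assembly graphs from GFA1
#'
#' An `assembly_graph` holds the unitigs (segments) and overlap links of a
#' GFA1 assembly graph. Unitigs carry an id, a length in bp, optionally the
#' nucleotide sequence and a mean-depth tag; links carry the two endpoint
#' ids, their orientations and the overlap length in bp. Orientation is kept
#' for export, but traversal treats the graph as undirected.
#'
#' @param unitigs data.frame with columns `id`, `length`, and optionally
#'   `sequence` (NA when absent) and `depth` (mean depth from dp/KC tags).
#' @param links data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient`, `overlap`.
#' @return An object of class `assembly_graph`.
#' @export
assembly_graph <- function(unitigs, links = NULL) {
  unitigs <- as.data.frame(unitigs, stringsAsFactors = FALSE)
  if (!all(c("id", "length") %in% names(unitigs)))
    stop_arg("`unitigs` needs columns `id` and `length`")
  if (anyDuplicated(unitigs$id))
    stop_arg("unitig ids must be unique: ",
             paste(unique(unitigs$id[duplicated(unitigs$id)]), collapse = ", "))
  if (any(unitigs$length < 1))
    stop_arg("unitig lengths must be >= 1")
  if (is.null(unitigs$sequence)) unitigs$sequence <- NA_character_
  if (is.null(unitigs$depth)) unitigs$depth <- NA_real_
  has_seq <- !is.na(unitigs$sequence)
  if (any(nchar(unitigs$sequence[has_seq]) != unitigs$length[has_seq]))
    stop_arg("sequence length disagrees with the `length` field")
  if (is.null(links)) {
    links <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character(),
                        overlap = integer(), stringsAsFactors = FALSE)
  }
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  bad <- setdiff(c(links$from, links$to), unitigs$id)
  if (length(bad))
    stop("links reference unknown unitig ids: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  len <- stats::setNames(unitigs$length, unitigs$id)
  if (nrow(links)) {
    over <- pmin(len[links$from], len[links$to])
    if (any(links$overlap < 0 | links$overlap >= over))
      stop_arg("link overlap must satisfy 0 <= overlap < min(endpoint lengths)")
  }
  structure(list(unitigs = unitigs, links = links), class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf("assembly_graph: %d unitigs (%.0f bp), %d links\n",
              nrow(x$unitigs), sum(x$unitigs$length), nrow(x$links)))
  invisible(x)
}

#' Unitig lengths of an assembly graph
#' @param graph An `assembly_graph`.
#' @return Named numeric vector of lengths in bp.
#' @export
unitig_lengths <- function(graph) {
  stats::setNames(graph$unitigs$length, graph$unitigs$id)
}

gfa_tag <- function(fields, name, type) {
  pat <- paste0("^", name, ":", type, ":")
  hit <- grep(pat, fields, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(pat, "", hit[1])
}

#' Parse a GFA1 assembly graph
#'
#' Reads S (segment) and L (link) records of a GFA1 file into an
#' [assembly_graph()]. Segment lengths come from the sequence, or from the
#' `LN:i:` tag when the sequence is `*`; mean depth is taken from a `dp:f:`
#' or `DP:f:` tag, or computed as `KC:i:` k-mer count / length. H lines are
#' tolerated; any other record type is skipped with a warning. Link overlaps
#' are read from simple `<n>M` CIGAR strings (`*` or `0M` mean no overlap).
#'
#' @param path Path to a GFA1 file.
#' @param load_sequences Keep segment sequences? Default `TRUE`; with
#'   `FALSE` sequences are dropped to save memory.
#' @return An [assembly_graph()].
#' @export
parse_gfa <- function(path, load_sequences = TRUE) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  type <- substr(lines, 1, 1)
  unknown <- !(type %in% c("H", "S", "L", "#"))
  if (any(unknown))
    warning(sprintf("skipping %d non-S/L/H GFA record(s) (types: %s)",
                    sum(unknown), paste(unique(type[unknown]), collapse = ", ")))

  parse_s <- function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed S line at line %d: fewer than 3 fields", lineno[i]),
           call. = FALSE)
    seq <- f[3]
    if (identical(seq, "*")) {
      ln <- gfa_tag(f[-(1:3)], "LN", "i")
      if (is.na(ln))
        stop(sprintf("malformed S line at line %d: sequence '*' without LN tag",
                     lineno[i]), call. = FALSE)
      len <- as.numeric(ln)
      seq <- NA_character_
    } else {
      len <- nchar(seq)
      if (!load_sequences) seq <- NA_character_
    }
    dp <- gfa_tag(f[-(1:3)], "dp", "f")
    if (is.na(dp)) dp <- gfa_tag(f[-(1:3)], "DP", "f")
    depth <- if (!is.na(dp)) as.numeric(dp) else {
      kc <- gfa_tag(f[-(1:3)], "KC", "i")
      if (!is.na(kc)) as.numeric(kc) / len else NA_real_
    }
    list(id = f[2], length = len, sequence = seq, depth = depth)
  }

  parse_l <- function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L || !(f[3] %in% c("+", "-")) || !(f[5] %in% c("+", "-")))
      stop(sprintf("malformed L line at line %d", lineno[i]), call. = FALSE)
    cig <- f[6]
    overlap <- if (cig %in% c("*", "")) 0L else {
      if (!grepl("^[0-9]+M$", cig))
        stop(sprintf("malformed L line at line %d: unsupported CIGAR '%s'",
                     lineno[i], cig), call. = FALSE)
      as.integer(sub("M$", "", cig))
    }
    list(from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
         overlap = overlap)
  }

  s_idx <- which(type == "S")
  l_idx <- which(type == "L")
  unitigs <- if (length(s_idx)) {
    do.call(rbind, lapply(lapply(s_idx, parse_s), as.data.frame,
                          stringsAsFactors = FALSE))
  } else {
    data.frame(id = character(), length = numeric(), sequence = character(),
               depth = numeric(), stringsAsFactors = FALSE)
  }
  links <- if (length(l_idx)) {
    do.call(rbind, lapply(lapply(l_idx, parse_l), as.data.frame,
                          stringsAsFactors = FALSE))
  } else NULL
  assembly_graph(unitigs, links)
}

#' Write an assembly graph (or a context subgraph) as GFA1
#'
#' Writes the graph, or the subgraph induced by a [extract_context_subgraph()]
#' result, as GFA1: one H line, one S line per unitig (sequence `*` with an
#' `LN:i:` tag when sequences are absent) and one L line per induced link.
#' Optional per-unitig colours are written as `CL:z:` tags, which
#' Bandage-style viewers use for display.
#'
#' @param graph An [assembly_graph()].
#' @param path Output file path.
#' @param subgraph Optional `context_subgraph`; restricts output to its
#'   members and the links among them.
#' @param colors Optional named character vector, unitig id -> colour string.
#' @return `path`, invisibly.
#' @export
export_gfa <- function(graph, path, subgraph = NULL, colors = NULL) {
  uni <- graph$unitigs
  lnk <- graph$links
  if (!is.null(subgraph)) {
    members <- if (inherits(subgraph, "context_subgraph")) subgraph$member_ids
               else as.character(subgraph)
    bad <- setdiff(members, uni$id)
    if (length(bad))
      stop_arg("subgraph members absent from graph: ", paste(bad, collapse = ", "))
    uni <- uni[uni$id %in% members, , drop = FALSE]
    lnk <- lnk[lnk$from %in% members & lnk$to %in% members, , drop = FALSE]
  }
  out <- "H\tVN:Z:1.0"
  if (nrow(uni)) {
    seqs <- ifelse(is.na(uni$sequence), "*", uni$sequence)
    s <- paste("S", uni$id, seqs, sep = "\t")
    need_ln <- is.na(uni$sequence)
    s[need_ln] <- paste0(s[need_ln], "\tLN:i:", format(uni$length[need_ln],
                                                       scientific = FALSE))
    if (!is.null(colors)) {
      has_col <- uni$id %in% names(colors)
      s[has_col] <- paste0(s[has_col], "\tCL:z:", colors[uni$id[has_col]])
    }
    out <- c(out, s)
  }
  if (nrow(lnk)) {
    out <- c(out, paste("L", lnk$from, lnk$from_orient, lnk$to, lnk$to_orient,
                        paste0(format(lnk$overlap, scientific = FALSE), "M"),
                        sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}
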