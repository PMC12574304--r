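#' Read alignment records from PAF
#'
#' Reads the 12 standard PAF columns and returns one record per alignment
#' with identity computed as residue matches / alignment block length
#' (columns 10 and 11). Reference (target) coordinates are PAF-native
#' 0-based half-open. Alignments on either strand are accepted; intervals
#' are always reported on the forward reference.
#'
#' @param path Path to a PAF file.
#' @return data.frame with columns `unitig_id`, `identity`, `ref_start`,
#'   `ref_end`, `aln_len`, `strand`.
#' @export
read_paf <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 12L) stop_arg("PAF needs >= 12 columns, got ", ncol(raw))
  data.frame(
    unitig_id = raw[[1]],
    identity  = as.numeric(raw[[10]]) / as.numeric(raw[[11]]),
    ref_start = as.numeric(raw[[8]]),
    ref_end   = as.numeric(raw[[9]]),
    aln_len   = as.numeric(raw[[11]]),
    strand    = raw[[5]],
    stringsAsFactors = FALSE
  )
}

cigar_ref_len <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.numeric(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  list(ref = sum(n[op %in% c("M", "D", "N", "=", "X")]),
       cols = sum(n[op %in% c("M", "I", "D", "=", "X")]))
}

#' Read alignment records from SAM text
#'
#' Minimal SAM reader for alignments of genome fragments against a single
#' reference sequence: the query name is taken as the unitig id, the
#' reference interval from POS and the CIGAR reference length (converted to
#' 0-based half-open), alignment columns from the CIGAR (M/I/D/=/X), and
#' identity as `(columns - NM) / columns` from the `NM:i:` edit-distance
#' tag. Unmapped records and records without NM are dropped with a warning.
#'
#' @param path Path to a SAM text file.
#' @return data.frame in the same shape as [read_paf()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  recs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop_arg("malformed SAM record: ", substr(ln, 1, 60))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L) return(NULL)           # unmapped
    nm <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (!length(nm)) return(NA)                          # no NM tag
    cg <- cigar_ref_len(f[6])
    start0 <- as.numeric(f[4]) - 1                       # SAM POS is 1-based
    data.frame(unitig_id = f[1],
               identity = (cg$cols - as.numeric(sub("^NM:i:", "", nm[1]))) / cg$cols,
               ref_start = start0, ref_end = start0 + cg$ref,
               aln_len = cg$cols,
               strand = if (bitwAnd(flag, 16L) == 16L) "-" else "+",
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(recs, function(r) !is.null(r) && !is.data.frame(r), TRUE))
  if (dropped) warning(dropped, " SAM record(s) without NM tag dropped")
  recs <- Filter(is.data.frame, recs)
  if (!length(recs))
    return(data.frame(unitig_id = character(), identity = numeric(),
                      ref_start = numeric(), ref_end = numeric(),
                      aln_len = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Align query fragments against a reference sequence
#'
#' Semi-global alignment (queries global, reference local) of short
#' nucleotide fragments against a reference, intended for operon-scale
#' sequences (<= ~20 kbp). Identity is matches / alignment columns, columns
#' counting matches, mismatches and gap positions. Reference intervals are
#' 0-based half-open on the forward reference; each query is also tried
#' reverse-complemented and the better-scoring strand is reported.
#'
#' @param reference Reference nucleotide string (A/C/G/T/N).
#' @param queries Character vector of query sequences, optionally named.
#' @param match,mismatch Match score and mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return data.frame with columns `unitig_id`, `identity`, `ref_start`,
#'   `ref_end`, `aln_len`, `strand`.
#' @export
align_fragments <- function(reference, queries, match = 1, mismatch = -1,
                            gap_open = 4, gap_extend = 1) {
  if (!nzchar(reference)) stop_arg("empty reference sequence")
  if (!length(queries) || any(!nzchar(queries))) stop_arg("empty query sequence")
  ids <- names(queries) %||% paste0("query", seq_along(queries))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  one <- function(q) {
    sub <- Biostrings::DNAString(reference)
    best <- NULL
    for (strand in c("+", "-")) {
      pat <- Biostrings::DNAString(q)
      if (strand == "-") pat <- Biostrings::reverseComplement(pat)
      aln <- Biostrings::pairwiseAlignment(pat, sub, type = "global-local",
                                           substitutionMatrix = mat,
                                           gapOpening = gap_open,
                                           gapExtension = gap_extend)
      if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best$aln))
        best <- list(aln = aln, strand = strand)
    }
    aln <- best$aln
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    s <- Biostrings::subject(aln)
    data.frame(identity = Biostrings::nmatch(aln) / cols,
               ref_start = Biostrings::start(s) - 1,
               ref_end = Biostrings::end(s),
               aln_len = cols, strand = best$strand,
               score = Biostrings::score(aln),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(queries, one))
  cbind(data.frame(unitig_id = ids, stringsAsFactors = FALSE), out)
}

#' Flag unitigs matching a reference ribosomal operon
#'
#' Filters alignment records to those at or above an identity threshold and
#' a minimum alignment length, checks that every record names a unitig
#' present in the graph, and computes the breadth of reference coverage as
#' the length of the union of the reference intervals divided by the
#' reference length (overlapping intervals are not double-counted).
#'
#' @param graph An [assembly_graph()].
#' @param alignments data.frame of alignment records as returned by
#'   [read_paf()], [read_sam()] or [align_fragments()].
#' @param min_identity Identity threshold, fraction (default 0.98).
#' @param min_aln_len Minimum alignment length in bp (default 500).
#' @param ref_length Reference operon length in bp.
#' @return An object of class `marker_hits`: list with `hits` (records at or
#'   above the thresholds, sorted by `ref_start` then id), `ref_length`, and
#'   `breadth`.
#' @export
flag_marker_unitigs <- function(graph, alignments, min_identity = 0.98,
                                min_aln_len = 500, ref_length) {
  assert_scalar_number(ref_length, "ref_length", min = 1)
  alignments <- as.data.frame(alignments, stringsAsFactors = FALSE)
  missing_ids <- setdiff(alignments$unitig_id, graph$unitigs$id)
  if (length(missing_ids))
    stop("alignment records name unitigs absent from the graph: ",
         paste(unique(missing_ids), collapse = ", "), call. = FALSE)
  keep <- alignments$identity >= min_identity & alignments$aln_len >= min_aln_len
  hits <- alignments[keep, , drop = FALSE]
  ord <- order(hits$ref_start, hits$unitig_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  breadth <- if (nrow(hits)) {
    ir <- IRanges::IRanges(start = hits$ref_start + 1, end = hits$ref_end)
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(ref_length))
    sum(IRanges::width(IRanges::reduce(ir))) / ref_length
  } else 0
  structure(list(hits = hits, ref_length = ref_length, breadth = breadth,
                 min_identity = min_identity, min_aln_len = min_aln_len),
            class = "marker_hits")
}

#' @export
print.marker_hits <- function(x, ...) {
  cat(sprintf("marker_hits: %d hit(s) at identity >= %.3f, breadth %.3f of %d bp reference\n",
              nrow(x$hits), x$min_identity, x$breadth, round(x$ref_length)))
  invisible(x)
}
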