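# Circular-scaffold detection ------------------------------------------------
#
# A scaffold is called a complete circular plasmid when all three criteria
# hold: (i) scaffold length strictly greater than min_scaffold_bp;
# (ii) a terminal direct repeat: local alignment between the first and last
# search_window_bp, forward vs forward, longer than min_overlap_bp with
# Karlin-Altschul E-value at most max_evalue; (iii) at least
# min_junction_pairs read pairs with one mate wholly inside each terminal
# end_window_bp window (outward-facing orientation by default).

nucleotide_matrix <- function(match, mismatch) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N is always scored as a mismatch
  m
}

as_one_scaffold <- function(scaffold) {
  if (inherits(scaffold, "scaffold_set")) {
    stopifnot(nrow(scaffold) == 1L)
    return(scaffold)
  }
  if (is.character(scaffold) && length(scaffold) == 1L) {
    return(scaffold_set("scaffold", scaffold))
  }
  stop("scaffold must be a one-row scaffold_set or a single DNA string",
       call. = FALSE)
}

#' Find the terminal direct repeat of a scaffold
#'
#' Computes the best local alignment between the first and the last
#' `search_window_bp` bases of the scaffold (forward vs forward orientation
#' only; windows are truncated to floor(L/2) for short scaffolds). The
#' alignment score S is converted to an E-value with the Karlin-Altschul
#' form E = K * m * n * exp(-lambda * S), m and n being the window lengths.
#'
#' @param scaffold a one-row [scaffold_set()] or a single DNA string.
#' @param params a [detection_params()] list.
#' @return An `end_overlap` list (fields `length` = alignment columns,
#'   `identity` percent, `score`, `evalue`, `prefix_range` and
#'   `suffix_range` as 0-based half-open intervals on the scaffold), or
#'   `NULL` when no alignment reaches `max_evalue`. Absence is a value, not
#'   an error.
#' @export
find_end_overlap <- function(scaffold, params = detection_params()) {
  sc <- as_one_scaffold(scaffold)
  L <- sc$length
  w <- min(params$search_window_bp, L %/% 2L)
  if (w < 1L) return(NULL)
  prefix <- substr(sc$seq, 1L, w)
  suffix <- substr(sc$seq, L - w + 1L, L)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(prefix), Biostrings::DNAString(suffix),
    type = "local",
    substitutionMatrix = nucleotide_matrix(params$match, params$mismatch),
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
  s <- Biostrings::score(aln)
  if (s <= 0) return(NULL)
  evalue <- params$K * as.numeric(w) * as.numeric(w) * exp(-params$lambda * s)
  if (evalue > params$max_evalue) return(NULL)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  columns <- nchar(as.character(pat))
  structure(list(
    length = columns,
    identity = 100 * Biostrings::nmatch(aln) / columns,
    score = s,
    evalue = evalue,
    prefix_range = c(Biostrings::start(pat) - 1L, Biostrings::end(pat)),
    suffix_range = c(L - w + Biostrings::start(sub) - 1L,
                     L - w + Biostrings::end(sub))
  ), class = "end_overlap")
}

#' Count junction-spanning read pairs for one scaffold
#'
#' A pair supports the circular junction when one mate lies wholly within
#' the first `end_window_bp` bases and the other wholly within the last
#' `end_window_bp` bases of the scaffold. With `require_orientation = TRUE`
#' (default) the start-proximal mate must map on "-" and the end-proximal
#' mate on "+", the pattern produced by a fragment spanning the circular
#' origin under FR paired-end sequencing. Each pair is counted at most once.
#'
#' @param pairs a `paired_alignments` table; every row must reference the
#'   scaffold.
#' @param scaffold a one-row [scaffold_set()].
#' @param params a [detection_params()] list.
#' @return integer count.
#' @export
count_junction_pairs <- function(pairs, scaffold, params = detection_params()) {
  sc <- as_one_scaffold(scaffold)
  if (nrow(pairs) == 0L) return(0L)
  if (!all(pairs$scaffold_id == sc$id)) {
    stop(sprintf("pairs reference scaffold(s) other than '%s'", sc$id),
         call. = FALSE)
  }
  L <- sc$length
  if (any(pairs$m1_end > L | pairs$m2_end > L)) {
    stop(sprintf("mate interval exceeds scaffold '%s' length %d", sc$id, L),
         call. = FALSE)
  }
  W <- params$end_window_bp
  in_start <- function(s, e) s >= 0L & e <= W
  in_end <- function(s, e) s >= L - W & e <= L
  ok_orient <- function(strand_start, strand_end) {
    if (!params$require_orientation) rep(TRUE, length(strand_start))
    else strand_start == "-" & strand_end == "+"
  }
  # mate1 near start / mate2 near end, or the reverse
  a <- in_start(pairs$m1_start, pairs$m1_end) & in_end(pairs$m2_start, pairs$m2_end) &
    ok_orient(pairs$m1_strand, pairs$m2_strand)
  b <- in_start(pairs$m2_start, pairs$m2_end) & in_end(pairs$m1_start, pairs$m1_end) &
    ok_orient(pairs$m2_strand, pairs$m1_strand)
  sum(a | b)
}

#' Trim the terminal repeat to produce the circular sequence
#'
#' Removes the suffix copy of the terminal direct repeat, returning one full
#' monomer of the underlying circle. The result has length
#' `scaffold length - (suffix span)`.
#'
#' @param scaffold a one-row [scaffold_set()] or DNA string.
#' @param overlap an `end_overlap` from [find_end_overlap()].
#' @return DNA string of the circular unit.
#' @export
circularize <- function(scaffold, overlap) {
  sc <- as_one_scaffold(scaffold)
  if (is.null(overlap)) stop("overlap is absent; nothing to trim", call. = FALSE)
  L <- sc$length
  s0 <- overlap$suffix_range[1L]
  s1 <- overlap$suffix_range[2L]
  if (s0 < 0L || s1 > L || s0 >= s1) {
    stop(sprintf("overlap suffix range [%d,%d) inconsistent with scaffold length %d",
                 s0, s1, L), call. = FALSE)
  }
  if (s1 - s0 >= L) {
    stop("scaffold consists entirely of its own repeat; nothing would remain",
         call. = FALSE)
  }
  paste0(substr(sc$seq, 1L, s0), substr(sc$seq, s1 + 1L, L))
}

#' Apply the three circularity criteria to one scaffold
#'
#' @param scaffold a one-row [scaffold_set()].
#' @param overlap output of [find_end_overlap()] (may be `NULL`).
#' @param n_junction_pairs output of [count_junction_pairs()].
#' @param params a [detection_params()] list.
#' @return a `circular_call` list: scaffold_id, length, coverage,
#'   passed_length / passed_overlap / passed_pairs, overlap,
#'   n_junction_pairs, is_circular, and `circular_seq` when circular.
#' @export
call_circular <- function(scaffold, overlap, n_junction_pairs,
                          params = detection_params()) {
  sc <- as_one_scaffold(scaffold)
  passed_length <- sc$length > params$min_scaffold_bp
  passed_overlap <- !is.null(overlap) &&
    overlap$length > params$min_overlap_bp &&
    overlap$evalue <= params$max_evalue
  passed_pairs <- n_junction_pairs >= params$min_junction_pairs
  is_circular <- passed_length && passed_overlap && passed_pairs
  structure(list(
    scaffold_id = sc$id,
    length = sc$length,
    coverage = sc$coverage,
    passed_length = passed_length,
    passed_overlap = passed_overlap,
    passed_pairs = passed_pairs,
    overlap = overlap,
    n_junction_pairs = as.integer(n_junction_pairs),
    is_circular = is_circular,
    circular_seq = if (is_circular) circularize(sc, overlap) else NULL
  ), class = "circular_call")
}

#' Detect circular plasmids across a scaffold set
#'
#' Runs [find_end_overlap()], [count_junction_pairs()] and [call_circular()]
#' on every scaffold, order-preserving.
#'
#' @param scaffolds a [scaffold_set()].
#' @param alignments a `paired_alignments` table over those scaffolds (pairs
#'   on unknown scaffolds are an error).
#' @param params a [detection_params()] list.
#' @return a `circular_calls` object (list of `circular_call`); see
#'   [calls_table()] and [circular_sequences()].
#' @export
detect_all <- function(scaffolds, alignments = NULL, params = detection_params()) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  if (is.null(alignments)) alignments <- empty_pairs()
  if (nrow(alignments) && !all(alignments$scaffold_id %in% scaffolds$id)) {
    bad <- setdiff(unique(alignments$scaffold_id), scaffolds$id)
    stop(sprintf("alignments reference unknown scaffold(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  by_scaffold <- split(seq_len(nrow(alignments)), alignments$scaffold_id)
  calls <- vector("list", nrow(scaffolds))
  for (i in seq_len(nrow(scaffolds))) {
    sc <- scaffolds[i, , drop = FALSE]
    class(sc) <- class(scaffolds)
    idx <- by_scaffold[[sc$id]]
    sub <- if (length(idx)) alignments[idx, , drop = FALSE] else empty_pairs()
    class(sub) <- c("paired_alignments", "data.frame")
    ov <- find_end_overlap(sc, params)
    n <- count_junction_pairs(sub, sc, params)
    calls[[i]] <- call_circular(sc, ov, n, params)
  }
  structure(calls, class = "circular_calls")
}

#' Tabulate circular calls
#'
#' @param calls a `circular_calls` object from [detect_all()].
#' @return data.frame with one row per scaffold: scaffold_id, length,
#'   coverage, the three criterion flags, overlap_len, overlap_evalue,
#'   n_junction_pairs, is_circular, circular_len.
#' @export
calls_table <- function(calls) {
  stopifnot(inherits(calls, "circular_calls"))
  rows <- lapply(calls, function(cc) {
    data.frame(scaffold_id = cc$scaffold_id,
               length = cc$length,
               coverage = cc$coverage,
               passed_length = cc$passed_length,
               passed_overlap = cc$passed_overlap,
               passed_pairs = cc$passed_pairs,
               overlap_len = if (is.null(cc$overlap)) NA_integer_ else cc$overlap$length,
               overlap_evalue = if (is.null(cc$overlap)) NA_real_ else cc$overlap$evalue,
               n_junction_pairs = cc$n_junction_pairs,
               is_circular = cc$is_circular,
               circular_len = if (cc$is_circular) nchar(cc$circular_seq) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(scaffold_id = character(), length = integer(),
                      coverage = numeric(), passed_length = logical(),
                      passed_overlap = logical(), passed_pairs = logical(),
                      overlap_len = integer(), overlap_evalue = numeric(),
                      n_junction_pairs = integer(), is_circular = logical(),
                      circular_len = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Extract circularized sequences from calls
#'
#' @param calls a `circular_calls` object.
#' @return a [scaffold_set()] of trimmed circular plasmid sequences
#'   (coverage carried through).
#' @export
circular_sequences <- function(calls) {
  stopifnot(inherits(calls, "circular_calls"))
  circ <- Filter(function(cc) cc$is_circular, calls)
  if (!length(circ)) return(scaffold_set(character(), character()))
  scaffold_set(vapply(circ, `[[`, "", "scaffold_id"),
               vapply(circ, `[[`, "", "circular_seq"),
               vapply(circ, function(cc) as.numeric(cc$coverage), numeric(1L)))
}

#' @export
print.circular_calls <- function(x, ...) {
  tab <- calls_table(x)
  cat(sprintf("circular_calls: %d scaffold(s), %d called circular\n",
              nrow(tab), sum(tab$is_circular)))
  if (any(tab$is_circular)) {
    print.data.frame(
      tab[tab$is_circular, c("scaffold_id", "length", "coverage",
                             "overlap_len", "n_junction_pairs", "circular_len")],
      row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.circular_call <- function(x, ...) {
  cat(sprintf("scaffold %s: length=%d, overlap=%s, junction_pairs=%d -> %s\n",
              x$scaffold_id, x$length,
              if (is.null(x$overlap)) "absent" else sprintf("%d bp (E=%.3g)",
                                                            x$overlap$length,
                                                            x$overlap$evalue),
              x$n_junction_pairs,
              if (x$is_circular) "CIRCULAR" else "not circular"))
  invisible(x)
}
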