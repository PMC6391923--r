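# Scaffold-level decontamination ---------------------------------------------
#
# Two filters, both operating on externally produced alignment hit tables
# (the searches themselves, e.g. against SILVA or the spiked control
# plasmids, are the caller's job):
#   * 16S filter: any hit with alignment length strictly greater than
#     min_identity_len_bp removes the whole scaffold.
#   * control filter: any hit with percent identity strictly greater than
#     min_pct_identity AND alignment length at least min_aln_len_bp removes
#     the scaffold.
# Whole scaffolds are removed, never masked, to purge chromosomal or
# spike-in contamination entirely.

filter_outcome <- function(scaffolds, removed_idx, reason, hits_trigger) {
  removed_ids <- scaffolds$id[removed_idx]
  removed <- if (length(removed_ids)) {
    cbind(data.frame(scaffold_id = removed_ids, reason = reason,
                     stringsAsFactors = FALSE),
          hits_trigger)
  } else {
    cbind(data.frame(scaffold_id = character(), reason = character(),
                     stringsAsFactors = FALSE),
          hits_trigger)
  }
  out <- list(kept = setdiff(scaffolds$id, removed_ids),
              removed = removed,
              reads_on_removed_fraction = NULL)
  class(out) <- "filter_outcome"
  out
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf("filter_outcome: %d kept, %d removed\n",
              length(x$kept), nrow(x$removed)))
  if (!is.null(x$reads_on_removed_fraction)) {
    cat(sprintf("  reads on removed scaffolds: %.4f%%\n",
                100 * x$reads_on_removed_fraction))
  }
  invisible(x)
}

check_hits_known <- function(hits, scaffolds) {
  if (nrow(hits) && !all(hits$query_id %in% scaffolds$id)) {
    bad <- setdiff(unique(hits$query_id), scaffolds$id)
    stop(sprintf("hit(s) reference unknown scaffold(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

best_trigger <- function(hits, ids) {
  # one triggering hit per removed scaffold: highest bitscore, then first row
  pick <- vapply(ids, function(id) {
    idx <- which(hits$query_id == id)
    idx[order(-hits$bitscore[idx], idx)][1L]
  }, integer(1L))
  hits[pick, , drop = FALSE]
}

#' Remove scaffolds carrying 16S rRNA sequence
#'
#' A scaffold is removed when it has at least one 16S hit with alignment
#' length strictly greater than `min_identity_len_bp` (default 200 bp). The
#' hit's percent identity is not thresholded; the sentence defining the
#' filter constrains only the length of the identical stretch.
#'
#' @param scaffolds a [scaffold_set()].
#' @param rrna_hits hit table ([hit_table()]) of scaffold-vs-16S-reference
#'   alignments, `query_id` = scaffold id.
#' @param min_identity_len_bp removal threshold on alignment length,
#'   exclusive (default 200).
#' @return a `filter_outcome`: `kept` ids, `removed` data.frame (scaffold_id,
#'   reason, triggering hit columns).
#' @export
filter_rrna_scaffolds <- function(scaffolds, rrna_hits,
                                  min_identity_len_bp = 200L) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  rrna_hits <- validate_hits(rrna_hits)
  check_hits_known(rrna_hits, scaffolds)
  trig <- rrna_hits[rrna_hits$aln_len > min_identity_len_bp, , drop = FALSE]
  removed_ids <- unique(trig$query_id)
  removed_idx <- which(scaffolds$id %in% removed_ids)
  filter_outcome(scaffolds, removed_idx, "16S_rRNA",
                 best_trigger(trig, scaffolds$id[removed_idx]))
}

#' Remove scaffolds matching spiked control plasmids
#'
#' A scaffold is removed when it has at least one control-plasmid hit with
#' percent identity strictly greater than `min_pct_identity` (default 95)
#' and alignment length of at least `min_aln_len_bp` (default 1000,
#' inclusive).
#'
#' @param scaffolds a [scaffold_set()].
#' @param control_hits hit table of scaffold-vs-control-plasmid alignments.
#' @param min_pct_identity identity threshold, exclusive (default 95).
#' @param min_aln_len_bp minimum alignment length, inclusive (default 1000).
#' @return a `filter_outcome`.
#' @export
filter_control_plasmids <- function(scaffolds, control_hits,
                                    min_pct_identity = 95,
                                    min_aln_len_bp = 1000L) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  control_hits <- validate_hits(control_hits)
  check_hits_known(control_hits, scaffolds)
  trig <- control_hits[control_hits$pct_identity > min_pct_identity &
                         control_hits$aln_len >= min_aln_len_bp, , drop = FALSE]
  removed_ids <- unique(trig$query_id)
  removed_idx <- which(scaffolds$id %in% removed_ids)
  filter_outcome(scaffolds, removed_idx, "control_plasmid",
                 best_trigger(trig, scaffolds$id[removed_idx]))
}

#' Fraction of mapped reads on removed scaffolds
#'
#' Read-level proportion: each mate of each pair counts as one read; the
#' numerator is reads whose scaffold was removed, the denominator all mapped
#' reads in `pairs`.
#'
#' @param pairs a `paired_alignments` table mapped to the pre-filter
#'   scaffold set.
#' @param removed_ids character vector of removed scaffold ids.
#' @return a fraction in \[0, 1\].
#' @export
fraction_reads_on_removed <- function(pairs, removed_ids) {
  if (nrow(pairs) == 0L) {
    stop("no mapped reads: fraction of reads on removed scaffolds is undefined",
         call. = FALSE)
  }
  on_removed <- pairs$scaffold_id %in% removed_ids
  sum(2L * on_removed) / (2L * nrow(pairs))
}
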