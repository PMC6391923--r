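# Pipeline orchestration -----------------------------------------------------
#
# One run = decontamination (16S scaffolds, then control-plasmid sequence)
# -> circular detection -> typing -> machine-readable report. Inputs may be
# file paths (FASTA / SAM subset / internal TSV / 12-column tabular) or the
# in-memory objects the module functions consume.

REPORT_SCHEMA_VERSION <- "1.0"

resolve_scaffolds <- function(x) {
  if (inherits(x, "scaffold_set")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_fasta(x))
  stop("scaffolds must be a scaffold_set or a FASTA path", call. = FALSE)
}

resolve_hits <- function(x, what) {
  if (is.null(x)) return(hit_table(character(), character(), numeric(), integer()))
  if (is.data.frame(x)) return(validate_hits(x))
  if (is.character(x) && length(x) == 1L) return(parse_tabular_hits(x))
  stop(sprintf("%s must be a hit table or a tabular file path", what),
       call. = FALSE)
}

resolve_pairs <- function(x, dialect) {
  if (inherits(x, "paired_alignments")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(parse_paired_alignments(x, dialect))
  }
  stop("alignments must be a paired_alignments table or a file path",
       call. = FALSE)
}

#' Run the full plasmidome pipeline
#'
#' Stages, in order: remove 16S rRNA-carrying scaffolds; remove spiked
#' control-plasmid scaffolds; detect circular plasmids among the kept
#' scaffolds; type them (when a marker table is supplied); summarize.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{scaffolds}{FASTA path or [scaffold_set()] (required).}
#'     \item{alignments}{SAM-subset / internal-TSV path or
#'       `paired_alignments` (required).}
#'     \item{alignments_dialect}{`"sam-subset"` (default) or
#'       `"internal-tsv"`.}
#'     \item{rrna_hits, control_hits}{tabular hit files or hit tables
#'       (optional; stage is a no-op without them).}
#'     \item{markers}{long-format marker table or TSV path (optional).}
#'     \item{params}{list of [detection_params()] overrides.}
#'     \item{min_bitscore}{marker presence threshold (default 50).}
#'     \item{outdir}{if set, artifacts are written there: kept.fasta,
#'       circular.fasta, calls.tsv, type_calls.tsv, report.json.}
#'   }
#' @return a `run_report` list: stage counts, the calls table, circular
#'   sequences, type calls, summary tables and provenance (parameters and
#'   input checksums). Deterministic for a fixed config.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (required in c("scaffolds", "alignments")) {
    if (is.null(config[[required]])) {
      stop(sprintf("config is missing required input '%s'", required),
           call. = FALSE)
    }
  }
  params <- do.call(detection_params, as.list(config$params))
  dialect <- if (is.null(config$alignments_dialect)) "sam-subset"
             else config$alignments_dialect

  checksums <- list()
  for (f in c("scaffolds", "alignments", "rrna_hits", "control_hits", "markers")) {
    if (is.character(config[[f]]) && length(config[[f]]) == 1L &&
        file.exists(config[[f]])) {
      checksums[[f]] <- unname(tools::md5sum(config[[f]]))
    }
  }

  stage <- "read inputs"
  res <- tryCatch({
    scaffolds <- resolve_scaffolds(config$scaffolds)
    pairs <- resolve_pairs(config$alignments, dialect)
    rrna_hits <- resolve_hits(config$rrna_hits, "rrna_hits")
    control_hits <- resolve_hits(config$control_hits, "control_hits")

    stage <- "decontam (16S)"
    f1 <- filter_rrna_scaffolds(scaffolds, rrna_hits)
    stage <- "decontam (controls)"
    kept1 <- scaffolds[scaffolds$id %in% f1$kept, , drop = FALSE]
    class(kept1) <- class(scaffolds)
    f2 <- filter_control_plasmids(kept1, control_hits[
      control_hits$query_id %in% kept1$id, , drop = FALSE])
    removed_ids <- c(f1$removed$scaffold_id, f2$removed$scaffold_id)
    kept <- scaffolds[!(scaffolds$id %in% removed_ids), , drop = FALSE]
    class(kept) <- class(scaffolds)
    reads_removed_frac <- if (nrow(pairs)) {
      fraction_reads_on_removed(pairs, removed_ids)
    } else NA_real_

    stage <- "circular detection"
    kept_pairs <- pairs[pairs$scaffold_id %in% kept$id, , drop = FALSE]
    class(kept_pairs) <- class(pairs)
    if (all(is.na(kept$coverage)) && nrow(kept_pairs)) {
      kept$coverage <- coverage_from_alignments(kept_pairs, kept)
    }
    calls <- detect_all(kept, kept_pairs, params)
    tab <- calls_table(calls)
    circ <- circular_sequences(calls)

    stage <- "classification"
    type_calls <- NULL
    summaries <- NULL
    if (!is.null(config$markers)) {
      min_bs <- if (is.null(config$min_bitscore)) 50 else config$min_bitscore
      profiles <- marker_profiles(config$markers, min_bitscore = min_bs,
                                  plasmid_ids = circ$id)
      profiles <- profiles[circ$id]
      type_calls <- classify_plasmids(profiles)
      summaries <- summarize_types(type_calls,
                                   stats::setNames(circ$length, circ$id))
    }

    report <- list(
      schema_version = REPORT_SCHEMA_VERSION,
      n_scaffolds_in = nrow(scaffolds),
      n_removed_rrna = nrow(f1$removed),
      n_removed_control = nrow(f2$removed),
      n_kept = nrow(kept),
      reads_on_removed_fraction = reads_removed_frac,
      n_circular = sum(tab$is_circular),
      size_coverage = tab[tab$is_circular,
                          c("scaffold_id", "circular_len", "coverage"),
                          drop = FALSE],
      calls = tab,
      circular = circ,
      removed = rbind(f1$removed, f2$removed),
      type_calls = type_calls,
      summaries = summaries,
      params = unclass(params),
      checksums = checksums)
    class(report) <- "run_report"
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    kept_set <- resolve_scaffolds(config$scaffolds)
    kept_set <- kept_set[!(kept_set$id %in% res$removed$scaffold_id), , drop = FALSE]
    class(kept_set) <- c("scaffold_set", "data.frame")
    write_fasta(kept_set, file.path(config$outdir, "kept.fasta"))
    write_fasta(res$circular, file.path(config$outdir, "circular.fasta"))
    utils::write.table(res$calls, file.path(config$outdir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$type_calls)) {
      utils::write.table(res$type_calls,
                         file.path(config$outdir, "type_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_report_json(res, file.path(config$outdir, "report.json"))
  }
  res
}

#' Serialize a run report as JSON
#'
#' Sequences are omitted; tables are serialized row-wise. Output contains no
#' timestamps, so reruns of the same configuration are byte-identical.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(
    schema_version = report$schema_version,
    counts = list(n_scaffolds_in = report$n_scaffolds_in,
                  n_removed_rrna = report$n_removed_rrna,
                  n_removed_control = report$n_removed_control,
                  n_kept = report$n_kept,
                  n_circular = report$n_circular),
    reads_on_removed_fraction = report$reads_on_removed_fraction,
    size_coverage = report$size_coverage,
    mobility = report$summaries$mobility,
    mob_counts = if (!is.null(report$summaries)) as.list(report$summaries$mob_counts),
    inc_counts = if (!is.null(report$summaries)) as.list(report$summaries$inc_counts),
    params = report$params,
    checksums = report$checksums)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("plasmidome pipeline report\n")
  cat(sprintf("  scaffolds in:        %d\n", x$n_scaffolds_in))
  cat(sprintf("  removed (16S):       %d\n", x$n_removed_rrna))
  cat(sprintf("  removed (controls):  %d\n", x$n_removed_control))
  if (!is.na(x$reads_on_removed_fraction)) {
    cat(sprintf("  reads on removed:    %.2f%%\n",
                100 * x$reads_on_removed_fraction))
  }
  cat(sprintf("  circular plasmids:   %d\n", x$n_circular))
  if (!is.null(x$summaries)) {
    m <- x$summaries$mobility
    cat(sprintf("  mobility: %s\n",
                paste(sprintf("%s %.1f%%", m$class, 100 * m$fraction),
                      collapse = ", ")))
  }
  invisible(x)
}

# Shared plasmids across samples ----------------------------------------------

align_stats <- function(query, subject_doubled, params) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject_doubled),
    type = "local",
    substitutionMatrix = nucleotide_matrix(params$match, params$mismatch),
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
  pat <- Biostrings::pattern(aln)
  cols <- nchar(as.character(pat))
  if (cols == 0L) return(c(score = -Inf, identity = 0, qcov = 0))
  c(score = Biostrings::score(aln),
    identity = 100 * Biostrings::nmatch(aln) / cols,
    qcov = 100 * (Biostrings::end(pat) - Biostrings::start(pat) + 1L) /
      nchar(query))
}

#' Identify plasmids shared between two samples
#'
#' Rotation-invariant reciprocal-best matching of two sets of circularized
#' plasmid sequences: each circle is aligned against the doubled partner, so
#' a shared plasmid is recovered regardless of where each assembly opened
#' the circle. A pair is reported when each sequence is the other's best
#' hit and both directions exceed the identity and query-coverage
#' thresholds (both strict).
#'
#' @param circulars_a,circulars_b [scaffold_set()]s of circularized
#'   sequences from the two samples.
#' @param min_pct_identity identity threshold, exclusive (default 99.8).
#' @param min_query_coverage query-coverage threshold in percent, exclusive
#'   (default 93.6). Coverage = aligned query span / query length.
#' @param params alignment scoring (a [detection_params()] list).
#' @return data.frame of matched pairs: id_a, id_b, identity, query
#'   coverage in each direction.
#' @export
shared_plasmids <- function(circulars_a, circulars_b,
                            min_pct_identity = 99.8,
                            min_query_coverage = 93.6,
                            params = detection_params()) {
  stopifnot(inherits(circulars_a, "scaffold_set"),
            inherits(circulars_b, "scaffold_set"))
  empty <- data.frame(id_a = character(), id_b = character(),
                      identity_ab = numeric(), qcov_ab = numeric(),
                      identity_ba = numeric(), qcov_ba = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(circulars_a) == 0L || nrow(circulars_b) == 0L) return(empty)
  na <- nrow(circulars_a); nb <- nrow(circulars_b)
  dbl_a <- strrep(circulars_a$seq, 2L)
  dbl_b <- strrep(circulars_b$seq, 2L)
  ab <- array(NA_real_, dim = c(na, nb, 3L))
  ba <- array(NA_real_, dim = c(na, nb, 3L))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      ab[i, j, ] <- align_stats(circulars_a$seq[i], dbl_b[j], params)
      ba[i, j, ] <- align_stats(circulars_b$seq[j], dbl_a[i], params)
    }
  }
  best_b_for_a <- apply(ab[, , 1L, drop = FALSE], 1L, which.max)
  best_a_for_b <- apply(ba[, , 1L, drop = FALSE], 2L, which.max)
  rows <- list()
  for (i in seq_len(na)) {
    j <- best_b_for_a[i]
    if (best_a_for_b[j] != i) next
    ok <- ab[i, j, 2L] > min_pct_identity && ab[i, j, 3L] > min_query_coverage &&
      ba[i, j, 2L] > min_pct_identity && ba[i, j, 3L] > min_query_coverage
    if (!ok) next
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = circulars_a$id[i], id_b = circulars_b$id[j],
      identity_ab = ab[i, j, 2L], qcov_ab = ab[i, j, 3L],
      identity_ba = ba[i, j, 2L], qcov_ba = ba[i, j, 3L],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
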