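# Shared data model ----------------------------------------------------------
#
# Coordinates are 0-based half-open everywhere inside the package. SAM
# (1-based) and BLAST tabular (1-based inclusive) are converted at the
# boundary, never downstream.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
IUPAC_AMBIG  <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize a DNA string
#'
#' Uppercases, maps U to T, collapses IUPAC ambiguity codes to N and rejects
#' anything outside the IUPAC nucleotide alphabet.
#'
#' @param x character vector of DNA sequences.
#' @param what label used in error messages.
#' @return character vector over the alphabet A, C, G, T, N.
#' @export
normalize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  x <- chartr(paste(IUPAC_AMBIG, collapse = ""),
              strrep("N", length(IUPAC_AMBIG)), x)
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s %s contains non-IUPAC characters",
                 what, paste(which(bad), collapse = ",")), call. = FALSE)
  }
  x
}

#' Build a scaffold set
#'
#' A scaffold set is the package's container for assembled sequences: a
#' data.frame with columns `id`, `seq`, `length` and `coverage` (mean
#' per-base read depth, `NA` when unknown).
#'
#' @param id unique scaffold identifiers.
#' @param seq DNA sequences (normalized via [normalize_dna()]).
#' @param coverage optional nonnegative mean read depth per scaffold.
#' @return a `scaffold_set` data.frame.
#' @export
scaffold_set <- function(id, seq, coverage = NA_real_) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate scaffold id: %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (length(seq) != length(id)) stop("id and seq lengths differ", call. = FALSE)
  seq <- normalize_dna(as.character(seq), what = "scaffold")
  len <- nchar(seq)
  if (any(len == 0L)) {
    stop(sprintf("empty sequence for scaffold: %s",
                 paste(id[len == 0L], collapse = ", ")), call. = FALSE)
  }
  coverage <- rep_len(as.numeric(coverage), length(id))
  if (any(!is.na(coverage) & coverage < 0)) {
    stop("coverage must be nonnegative", call. = FALSE)
  }
  out <- data.frame(id = id, seq = seq, length = as.integer(len),
                    coverage = coverage, stringsAsFactors = FALSE)
  class(out) <- c("scaffold_set", "data.frame")
  out
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("scaffold_set: %d sequence(s), %s bp total\n",
              nrow(x), format(sum(as.numeric(x$length)), big.mark = ",")))
  if (nrow(x)) {
    show <- utils::head(x[, c("id", "length", "coverage")], 10L)
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

# FASTA -----------------------------------------------------------------------

#' Read scaffolds from a FASTA file
#'
#' @param path FASTA file.
#' @return a [scaffold_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  # read raw (BString) so that U and ambiguity codes reach our own
  # normalization instead of being silently altered
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) {
                   stop(sprintf("malformed FASTA '%s': %s",
                                path, conditionMessage(e)), call. = FALSE)
                 })
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) {
    stop(sprintf("malformed header (empty id) at record %s of %s",
                 paste(which(!nzchar(ids)), collapse = ","), path),
         call. = FALSE)
  }
  if (any(Biostrings::width(ss) == 0L)) {
    stop(sprintf("empty sequence for record '%s' in %s",
                 ids[Biostrings::width(ss) == 0L][1L], path), call. = FALSE)
  }
  scaffold_set(ids, as.character(ss))
}

#' Write scaffolds to a FASTA file
#'
#' Records are written in input order.
#'
#' @param scaffolds a [scaffold_set()].
#' @param path output file.
#' @param line_width sequence characters per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(scaffolds, path, line_width = 70L) {
  stopifnot(inherits(scaffolds, "scaffold_set"), line_width >= 1L)
  if (nrow(scaffolds) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  ss <- Biostrings::DNAStringSet(scaffolds$seq)
  names(ss) <- scaffolds$id
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(line_width))
  invisible(path)
}

# BLAST tabular (outfmt-6 dialect) -------------------------------------------

HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Build a hit table
#'
#' The 12-column tabular alignment dialect (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, E-value, bitscore; start/end 1-based inclusive, as emitted by
#' BLASTN outfmt 6).
#'
#' @param query_id,subject_id identifiers.
#' @param pct_identity percent identity in \[0, 100\].
#' @param aln_len alignment length in bp (>= 1).
#' @param mismatches,gap_opens,q_start,q_end,s_start,s_end,evalue,bitscore
#'   remaining columns; defaulted for hand-built tables.
#' @return data.frame with the 12 canonical columns.
#' @export
hit_table <- function(query_id, subject_id, pct_identity, aln_len,
                      mismatches = 0L, gap_opens = 0L,
                      q_start = 1L, q_end = aln_len,
                      s_start = 1L, s_end = aln_len,
                      evalue = 0, bitscore = 2 * aln_len) {
  n <- length(query_id)
  subject_id <- rep_len(subject_id, n)
  pct_identity <- rep_len(pct_identity, n)
  aln_len <- rep_len(aln_len, n)
  mismatches <- rep_len(mismatches, n)
  gap_opens <- rep_len(gap_opens, n)
  q_start <- rep_len(q_start, n); q_end <- rep_len(q_end, n)
  s_start <- rep_len(s_start, n); s_end <- rep_len(s_end, n)
  evalue <- rep_len(evalue, n); bitscore <- rep_len(bitscore, n)
  out <- data.frame(query_id = as.character(query_id),
                    subject_id = as.character(subject_id),
                    pct_identity = as.numeric(pct_identity),
                    aln_len = as.integer(aln_len),
                    mismatches = as.integer(mismatches),
                    gap_opens = as.integer(gap_opens),
                    q_start = as.integer(q_start), q_end = as.integer(q_end),
                    s_start = as.integer(s_start), s_end = as.integer(s_end),
                    evalue = as.numeric(evalue),
                    bitscore = as.numeric(bitscore),
                    stringsAsFactors = FALSE)
  validate_hits(out)
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(HIT_COLUMNS %in% names(hits)))
  if (nrow(hits)) {
    if (any(hits$aln_len < 1L)) stop("aln_len must be >= 1", call. = FALSE)
    if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
      stop("pct_identity must lie in [0, 100]", call. = FALSE)
    }
    if (any(hits$evalue < 0)) stop("evalue must be >= 0", call. = FALSE)
  }
  hits[HIT_COLUMNS]
}

#' Parse a 12-column tabular alignment file
#'
#' @param path tab-separated file, 12 columns, no header. An empty file
#'   yields an empty table.
#' @return data.frame of typed hits (see [hit_table()]).
#' @export
parse_tabular_hits <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(hit_table(character(), character(), numeric(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  arity <- lengths(fields)
  if (any(arity != 12L)) {
    stop(sprintf("line %d of %s has %d columns, expected 12",
                 which(arity != 12L)[1L], path, arity[arity != 12L][1L]),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  num <- function(j, fn, what) {
    v <- suppressWarnings(fn(m[, j]))
    if (anyNA(v)) {
      stop(sprintf("line %d of %s: non-numeric value '%s' in %s column",
                   which(is.na(v))[1L], path, m[which(is.na(v))[1L], j], what),
           call. = FALSE)
    }
    v
  }
  hit_table(query_id = m[, 1L], subject_id = m[, 2L],
            pct_identity = num(3L, as.numeric, "pct_identity"),
            aln_len = num(4L, as.integer, "aln_len"),
            mismatches = num(5L, as.integer, "mismatches"),
            gap_opens = num(6L, as.integer, "gap_opens"),
            q_start = num(7L, as.integer, "q_start"),
            q_end = num(8L, as.integer, "q_end"),
            s_start = num(9L, as.integer, "s_start"),
            s_end = num(10L, as.integer, "s_end"),
            evalue = num(11L, as.numeric, "evalue"),
            bitscore = num(12L, as.numeric, "bitscore"))
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits data.frame as returned by [hit_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  hits <- validate_hits(hits)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Paired alignments ----------------------------------------------------------

PAIR_COLUMNS <- c("read_id", "scaffold_id", "m1_start", "m1_end", "m1_strand",
                  "m2_start", "m2_end", "m2_strand")

#' Build a paired-alignment table
#'
#' One row per read pair whose two mates map to the same scaffold.
#' Coordinates are 0-based half-open on the scaffold; strands are "+"/"-".
#'
#' @param read_id,scaffold_id identifiers.
#' @param m1_start,m1_end,m2_start,m2_end mate intervals, 0-based half-open.
#' @param m1_strand,m2_strand mate strands.
#' @return a `paired_alignments` data.frame.
#' @export
paired_alignments <- function(read_id, scaffold_id,
                              m1_start, m1_end, m1_strand,
                              m2_start, m2_end, m2_strand) {
  out <- data.frame(read_id = as.character(read_id),
                    scaffold_id = as.character(scaffold_id),
                    m1_start = as.integer(m1_start), m1_end = as.integer(m1_end),
                    m1_strand = as.character(m1_strand),
                    m2_start = as.integer(m2_start), m2_end = as.integer(m2_end),
                    m2_strand = as.character(m2_strand),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (!all(out$m1_strand %in% c("+", "-")) || !all(out$m2_strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'", call. = FALSE)
    }
    bad <- out$m1_start < 0L | out$m2_start < 0L |
      out$m1_start >= out$m1_end | out$m2_start >= out$m2_end
    if (any(bad)) {
      stop(sprintf("invalid mate interval for read(s): %s",
                   paste(utils::head(out$read_id[bad], 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  class(out) <- c("paired_alignments", "data.frame")
  out
}

empty_pairs <- function() {
  paired_alignments(character(), character(), integer(), integer(),
                    character(), integer(), integer(), character())
}

cigar_ref_span <- function(cigar) {
  ops <- gregexpr("(\\d+)([MIDS])", cigar, perl = TRUE)
  vapply(regmatches(cigar, ops), function(tok) {
    if (!length(tok)) return(NA_integer_)
    n <- as.integer(sub("[MIDS]$", "", tok))
    op <- sub("^\\d+", "", tok)
    sum(n[op %in% c("M", "D")])
  }, integer(1L))
}

parse_sam_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines)) {
    out <- empty_pairs()
    attr(out, "tallies") <- list(cross_scaffold = 0L, orphan = 0L, secondary = 0L)
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6L)) {
    stop(sprintf("SAM line %d has fewer than 6 mandatory fields",
                 which(lengths(f) < 6L)[1L]), call. = FALSE)
  }
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  if (anyNA(flag) || anyNA(pos)) stop("non-numeric FLAG or POS in SAM input", call. = FALSE)

  secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  unmapped <- bitwAnd(flag, 0x4L) != 0L | rname == "*" | cigar == "*"
  keep <- !secondary & !unmapped
  n_secondary <- sum(secondary)

  span <- rep(NA_integer_, length(qname))
  span[keep] <- cigar_ref_span(cigar[keep])
  if (anyNA(span[keep])) stop("unparseable CIGAR in SAM input", call. = FALSE)

  rec <- data.frame(qname = qname, rname = rname,
                    start = pos - 1L, end = pos - 1L + span,
                    strand = ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
                    mate1 = bitwAnd(flag, 0x40L) != 0L,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  grp <- split(seq_len(nrow(rec)), rec$qname)
  n_orphan <- 0L
  n_cross <- 0L
  rows <- vector("list", length(grp))
  for (i in seq_along(grp)) {
    idx <- grp[[i]]
    if (length(idx) != 2L) { n_orphan <- n_orphan + 1L; next }
    a <- rec[idx[1L], ]; b <- rec[idx[2L], ]
    if (a$rname != b$rname) { n_cross <- n_cross + 1L; next }
    if (b$mate1 && !a$mate1) { tmp <- a; a <- b; b <- tmp }
    rows[[i]] <- data.frame(read_id = a$qname, scaffold_id = a$rname,
                            m1_start = a$start, m1_end = a$end, m1_strand = a$strand,
                            m2_start = b$start, m2_end = b$end, m2_strand = b$strand,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) {
    d <- do.call(rbind, rows)
    paired_alignments(d$read_id, d$scaffold_id, d$m1_start, d$m1_end,
                      d$m1_strand, d$m2_start, d$m2_end, d$m2_strand)
  } else empty_pairs()
  attr(out, "tallies") <- list(cross_scaffold = n_cross, orphan = n_orphan,
                               secondary = n_secondary)
  out
}

parse_pairs_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(PAIR_COLUMNS, names(d))
  if (length(missing)) {
    stop(sprintf("internal TSV %s lacks column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- paired_alignments(d$read_id, d$scaffold_id, d$m1_start, d$m1_end,
                           d$m1_strand, d$m2_start, d$m2_end, d$m2_strand)
  attr(out, "tallies") <- list(cross_scaffold = 0L, orphan = 0L, secondary = 0L)
  out
}

#' Parse paired-read alignments
#'
#' Two dialects are supported. `"sam-subset"` is plain-text SAM restricted to
#' the mandatory fields with CIGAR operations M/I/D/S; mates are paired by
#' identical QNAME, only primary alignments are used, and SAM 1-based
#' positions are converted to 0-based half-open intervals. `"internal-tsv"`
#' is the package's own tabular dialect: a header line followed by columns
#' read_id, scaffold_id, m1_start, m1_end, m1_strand, m2_start, m2_end,
#' m2_strand (already 0-based half-open).
#'
#' Orphan mates and cross-scaffold pairs are excluded from the table and
#' tallied in `attr(x, "tallies")`; they never count as junction evidence.
#'
#' @param path alignment file.
#' @param dialect `"sam-subset"` or `"internal-tsv"`.
#' @return a `paired_alignments` data.frame with a `tallies` attribute.
#' @export
parse_paired_alignments <- function(path, dialect = c("sam-subset", "internal-tsv")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  dialect <- match.arg(dialect)
  switch(dialect,
         "sam-subset" = parse_sam_subset(path),
         "internal-tsv" = parse_pairs_tsv(path))
}

#' Write paired alignments in the internal TSV dialect
#'
#' @param pairs a `paired_alignments` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paired_tsv <- function(pairs, path) {
  stopifnot(inherits(pairs, "paired_alignments"))
  utils::write.table(as.data.frame(pairs)[, PAIR_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Detection parameters --------------------------------------------------------

#' Detection parameters for circular-scaffold calling
#'
#' Defaults encode the published criteria: scaffolds must be longer than
#' `min_scaffold_bp` (strict), carry a terminal direct repeat longer than
#' `min_overlap_bp` (strict) with E-value at most `max_evalue`, and be
#' supported by at least `min_junction_pairs` read pairs whose mates lie
#' wholly within the terminal `end_window_bp` windows.
#'
#' @param min_scaffold_bp minimum scaffold length, exclusive (default 2000).
#' @param min_overlap_bp minimum terminal-repeat alignment length, exclusive
#'   (default 34).
#' @param max_evalue maximum Karlin-Altschul E-value for the end overlap
#'   (default 1e-5).
#' @param end_window_bp terminal window for junction-pair evidence, inclusive
#'   (default 500).
#' @param min_junction_pairs minimum junction-spanning pairs, inclusive
#'   (default 2).
#' @param search_window_bp window at each scaffold end searched for the
#'   terminal repeat (default 1000; truncated to floor(L/2) on short
#'   scaffolds).
#' @param require_orientation require the junction-consistent mate
#'   orientation (start-proximal mate on "-", end-proximal on "+"); set
#'   `FALSE` for the permissive mode that only checks positions.
#' @param lambda,K Karlin-Altschul parameters for the E-value
#'   E = K * m * n * exp(-lambda * S).
#' @param match,mismatch,gap_open,gap_extend alignment scoring (E-value is
#'   computed from the score as if ungapped).
#' @return a `detection_params` list.
#' @export
detection_params <- function(min_scaffold_bp = 2000L,
                             min_overlap_bp = 34L,
                             max_evalue = 1e-5,
                             end_window_bp = 500L,
                             min_junction_pairs = 2L,
                             search_window_bp = 1000L,
                             require_orientation = TRUE,
                             lambda = 1.28, K = 0.46,
                             match = 1, mismatch = -2,
                             gap_open = -2, gap_extend = -2) {
  p <- list(min_scaffold_bp = as.integer(min_scaffold_bp),
            min_overlap_bp = as.integer(min_overlap_bp),
            max_evalue = as.numeric(max_evalue),
            end_window_bp = as.integer(end_window_bp),
            min_junction_pairs = as.integer(min_junction_pairs),
            search_window_bp = as.integer(search_window_bp),
            require_orientation = isTRUE(require_orientation),
            lambda = as.numeric(lambda), K = as.numeric(K),
            match = as.numeric(match), mismatch = as.numeric(mismatch),
            gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend))
  if (p$min_scaffold_bp <= 0L || p$min_overlap_bp <= 0L || p$max_evalue <= 0 ||
      p$end_window_bp <= 0L || p$min_junction_pairs <= 0L ||
      p$search_window_bp <= 0L || p$lambda <= 0 || p$K <= 0) {
    stop("detection parameters must be positive", call. = FALSE)
  }
  if (p$search_window_bp < p$min_overlap_bp) {
    stop("search_window_bp must be >= min_overlap_bp", call. = FALSE)
  }
  class(p) <- "detection_params"
  p
}
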