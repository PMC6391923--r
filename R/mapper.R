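# Naive exact-seed read mapper -----------------------------------------------
#
# Stand-in for an external short-read mapper so synthetic communities run
# end to end with no downloads: exact k-mer seeding on the read's leading
# k-mer (both strands) followed by ungapped full-length verification. Reads
# with no acceptable placement are dropped with a tally; reads with two or
# more equally good placements are dropped as ambiguous. Suitable for
# error-free or low-error synthetic reads only.

utils::globalVariables(c("kmer", "sid", "pos", "qi", "mm", "J", ".N", ".SD"))

count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Map simulated read pairs to scaffolds
#'
#' @param reads data.frame (read_id, r1, r2) as produced by
#'   [simulate_read_pairs()] / [generate_community()].
#' @param scaffolds a [scaffold_set()].
#' @param k seed k-mer length (must not exceed the read length).
#' @param max_mismatch maximum substitutions tolerated in the full-length
#'   ungapped verification (default 2).
#' @return a `paired_alignments` table (0-based half-open mate intervals),
#'   with `attr(x, "tallies")`: unmapped mates, ambiguous mates, orphan
#'   pairs (one mate unplaced) and cross_scaffold pairs.
#' @export
map_reads_naive <- function(reads, scaffolds, k = 31L, max_mismatch = 2L) {
  stopifnot(inherits(scaffolds, "scaffold_set"),
            all(c("read_id", "r1", "r2") %in% names(reads)))
  k <- as.integer(k)
  n_reads <- nrow(reads)
  if (n_reads == 0L) {
    out <- empty_pairs()
    attr(out, "tallies") <- list(unmapped = 0L, ambiguous = 0L,
                                 orphan = 0L, cross_scaffold = 0L)
    return(out)
  }
  if (k > min(nchar(c(reads$r1, reads$r2)))) {
    stop("k exceeds the read length", call. = FALSE)
  }

  # k-mer index over all scaffold positions
  idx <- data.table::rbindlist(lapply(seq_len(nrow(scaffolds)), function(i) {
    L <- scaffolds$length[i]
    n <- L - k + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(kmer = substring(scaffolds$seq[i], 1:n, k:(k + n - 1L)),
                           sid = i, pos = 1:n)
  }))
  if (!nrow(idx)) stop("no scaffold is at least k bases long", call. = FALSE)
  data.table::setkey(idx, kmer)

  # long mate table with forward and reverse-complement query strings
  mates <- data.table::data.table(
    qi = seq_len(2L * n_reads),
    ridx = rep(seq_len(n_reads), 2L),
    mate = rep(1:2, each = n_reads),
    fwd = c(reads$r1, reads$r2))
  mates$rc <- revcomp(mates$fwd)
  mates$len <- nchar(mates$fwd)

  seed_q <- data.table::data.table(
    qi = rep(mates$qi, 2L),
    strand = rep(c("+", "-"), each = nrow(mates)),
    kmer = c(substr(mates$fwd, 1L, k), substr(mates$rc, 1L, k)))
  cand <- idx[seed_q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  tallies <- list(unmapped = 0L, ambiguous = 0L, orphan = 0L, cross_scaffold = 0L)

  placed <- NULL
  if (nrow(cand)) {
    cand <- merge(cand, mates[, c("qi", "fwd", "rc", "len")], by = "qi")
    cand <- cand[cand$pos + cand$len - 1L <= scaffolds$length[cand$sid], ]
  }
  if (!is.null(cand) && nrow(cand)) {
    qseq <- ifelse(cand$strand == "+", cand$fwd, cand$rc)
    ref <- substring(scaffolds$seq[cand$sid], cand$pos, cand$pos + cand$len - 1L)
    cand$mm <- 0L
    ne <- which(ref != qseq)
    if (length(ne)) {
      if (max_mismatch > 0L) cand$mm[ne] <- count_mismatches(ref[ne], qseq[ne])
      else cand$mm[ne] <- max_mismatch + 1L
    }
    cand <- cand[cand$mm <= max_mismatch, ]
  }
  if (!is.null(cand) && nrow(cand)) {
    data.table::setorder(cand, qi, mm, sid, pos)
    first <- cand[!duplicated(cand$qi), ]
    # ambiguous: another placement with the same mismatch count
    dup <- cand[duplicated(cand$qi), ]
    second_best <- dup[!duplicated(dup$qi), ]
    tie <- second_best$qi[second_best$mm == first$mm[match(second_best$qi, first$qi)]]
    tallies$ambiguous <- length(tie)
    placed <- first[!(first$qi %in% tie), ]
  }

  if (is.null(placed) || nrow(placed) == 0L) {
    tallies$unmapped <- 2L * n_reads - tallies$ambiguous
    out <- empty_pairs()
    attr(out, "tallies") <- tallies
    return(out)
  }
  tallies$unmapped <- 2L * n_reads - tallies$ambiguous - nrow(placed)

  pl <- merge(mates[, c("qi", "ridx", "mate")], placed[, c("qi", "sid", "pos", "strand", "len")],
              by = "qi")
  m1 <- pl[pl$mate == 1L, ]
  m2 <- pl[pl$mate == 2L, ]
  common <- intersect(m1$ridx, m2$ridx)
  tallies$orphan <- length(union(m1$ridx, m2$ridx)) - length(common)
  m1 <- m1[match(common, m1$ridx), ]
  m2 <- m2[match(common, m2$ridx), ]
  same <- m1$sid == m2$sid
  tallies$cross_scaffold <- sum(!same)
  m1 <- m1[same, ]; m2 <- m2[same, ]

  out <- if (nrow(m1)) {
    paired_alignments(read_id = reads$read_id[m1$ridx],
                      scaffold_id = scaffolds$id[m1$sid],
                      m1_start = m1$pos - 1L, m1_end = m1$pos - 1L + m1$len,
                      m1_strand = m1$strand,
                      m2_start = m2$pos - 1L, m2_end = m2$pos - 1L + m2$len,
                      m2_strand = m2$strand)
  } else empty_pairs()
  attr(out, "tallies") <- tallies
  out
}

#' Mean mapped coverage per scaffold
#'
#' Total mapped read bases divided by scaffold length.
#'
#' @param pairs a `paired_alignments` table.
#' @param scaffolds a [scaffold_set()].
#' @return named numeric vector of mean depths, one per scaffold.
#' @export
coverage_from_alignments <- function(pairs, scaffolds) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  bases <- (pairs$m1_end - pairs$m1_start) + (pairs$m2_end - pairs$m2_start)
  tot <- tapply(bases, factor(pairs$scaffold_id, levels = scaffolds$id), sum,
                default = 0)
  stats::setNames(as.numeric(tot) / scaffolds$length, scaffolds$id)
}
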