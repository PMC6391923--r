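# Independent oracles and fixture builders used across the suite.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Longest exact terminal direct repeat: the largest k (up to floor(L/2)) with
# prefix(k) == suffix(k). Scans every k; terminal repeats are not
# prefix-closed, so no early exit.
longest_terminal_exact_repeat <- function(seq, max_k = nchar(seq) %/% 2L) {
  L <- nchar(seq)
  best <- 0L
  for (k in seq_len(max_k)) {
    if (substr(seq, 1L, k) == substr(seq, L - k + 1L, L)) best <- k
  }
  best
}

# Brute-force best local alignment score between two strings, linear gap
# penalty, via the canonical Smith-Waterman recurrence (row sweep; the
# within-row left-gap closure is the prefix-max identity
# H[j] = g*j + cummax(M[k] - g*k)).
brute_local_score <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  m <- length(bv)
  js <- seq_len(m)
  prev <- numeric(m + 1L)
  best <- 0
  for (i in seq_along(av)) {
    sub <- ifelse(av[i] == bv, match, mismatch)
    M <- pmax(0, prev[js] + sub, prev[js + 1L] + gap)
    H <- pmax(M, gap * js + cummax(M - gap * js))
    best <- max(best, H)
    prev <- c(0, H)
  }
  best
}

# Linear scaffold for a circular molecule: repeat || core || repeat, i.e. the
# circle core+repeat opened just after the repeat.
planted_circular_scaffold <- function(circ_len, overlap_len) {
  template <- rnd_dna(circ_len)
  paste0(template, substr(template, 1L, overlap_len))
}

# A canonical junction-consistent read pair: start-proximal mate on "-",
# end-proximal on "+", both wholly inside the terminal windows.
junction_pair <- function(scaffold_id, L, read_len = 100L, offset = 10L,
                          read_id = "jp1") {
  paired_alignments(
    read_id = read_id, scaffold_id = scaffold_id,
    m1_start = offset, m1_end = offset + read_len, m1_strand = "-",
    m2_start = L - offset - read_len, m2_end = L - offset, m2_strand = "+")
}

# n junction pairs with distinct ids
junction_pairs_n <- function(scaffold_id, L, n, read_len = 100L) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    junction_pair(scaffold_id, L, read_len, offset = 5L + i,
                  read_id = sprintf("jp%03d", i))
  })) -> d
  class(d) <- c("paired_alignments", "data.frame")
  d
}

# Apply the junction-pair criterion to simulator truth records (independent
# reimplementation used as the mapping/counting oracle). Truth rows give the
# fragment start s and insert i on the circular template of length L with a
# terminal repeat of ov bases; read length rl. Returns the number of pairs
# whose mates, placed contiguously on the linearized scaffold, fall wholly
# inside opposite terminal windows with outward-facing orientation.
junction_count_from_truth <- function(truth, L, ov, rl, W = 500L) {
  Ls <- L + ov
  n <- 0L
  for (r in seq_len(nrow(truth))) {
    s <- truth$frag_start[r]
    i <- truth$insert[r]
    # mate placements on the scaffold (NA when the read maps discontiguously)
    r1 <- c(s, s + rl)
    if (r1[2L] > Ls) next
    a2 <- s + i - rl
    b2 <- s + i
    if (b2 <= Ls) {
      r2 <- c(a2, b2)
    } else if (a2 >= L) {
      r2 <- c(a2 - L, b2 - L)
    } else next
    in_start <- function(x) x[1L] >= 0L && x[2L] <= W
    in_end <- function(x) x[1L] >= Ls - W && x[2L] <= Ls
    # r1 is forward ("+"), r2 reverse ("-") under FR simulation
    if (in_end(r1) && in_start(r2)) n <- n + 1L
  }
  n
}
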