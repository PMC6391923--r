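test_that("a planted exact terminal repeat is recovered with full identity", {
  set.seed(21)
  sc <- planted_circular_scaffold(10000L, 50L)
  ov <- find_end_overlap(sc)
  expect_equal(ov$length, 50L)
  expect_equal(ov$identity, 100)
  expect_equal(ov$score, 50)
  L <- nchar(sc)
  expect_equal(ov$prefix_range, c(0L, 50L))
  expect_equal(ov$suffix_range, c(L - 50L, L))
})

test_that("a random scaffold with no planted repeat yields no overlap", {
  set.seed(22)
  seq <- rnd_dna(10000L)
  expect_null(find_end_overlap(seq))
  # cross-check with the brute-force local alignment of the two windows:
  # the best random score must sit above the E <= 1e-5 threshold
  p <- detection_params()
  s <- brute_local_score(substr(seq, 1, 1000), substr(seq, 9001, 10000))
  expect_gt(p$K * 1000 * 1000 * exp(-p$lambda * s), p$max_evalue)
})

test_that("a 40-bp repeat with one central mismatch aligns full length", {
  set.seed(23)
  rep40 <- rnd_dna(40L)
  suffix_copy <- rep40
  old <- substr(suffix_copy, 20, 20)
  substr(suffix_copy, 20, 20) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  sc <- paste0(rep40, rnd_dna(9920L), suffix_copy)
  ov <- find_end_overlap(sc)
  expect_equal(ov$length, 40L)
  expect_equal(ov$identity, 97.5)
  # score agrees with the brute-force Smith-Waterman oracle on the windows
  L <- nchar(sc)
  expect_equal(ov$score,
               brute_local_score(substr(sc, 1, 1000), substr(sc, L - 999, L)))
})

test_that("overlap length equals the longest terminal exact repeat oracle", {
  set.seed(24)
  for (i in 1:40) {
    m <- sample(35:200, 1L)
    sc <- planted_circular_scaffold(sample(2000:6000, 1L), m)
    ov <- find_end_overlap(sc)
    expect_equal(ov$length, longest_terminal_exact_repeat(sc),
                 info = sprintf("construct %d (repeat %d)", i, m))
    expect_equal(ov$identity, 100)
  }
})

test_that("short scaffolds truncate the search windows instead of failing", {
  set.seed(25)
  sc <- planted_circular_scaffold(400L, 60L)  # scaffold 460 bp < 2 windows
  ov <- find_end_overlap(sc)
  expect_equal(ov$length, 60L)
  expect_null(find_end_overlap("AC"))
})

test_that("junction pairs require both mates wholly inside opposite windows", {
  set.seed(26)
  L <- 10000L
  sc <- scaffold_set("s1", rnd_dna(L))
  p <- detection_params()

  expect_equal(count_junction_pairs(junction_pair("s1", L), sc, p), 1L)

  # end-proximal mate sliding out of the terminal 500-bp window
  mk <- function(m2_start) {
    paired_alignments("r", "s1", 10L, 110L, "-", m2_start, m2_start + 100L, "+")
  }
  expect_equal(count_junction_pairs(mk(L - 500L), sc, p), 1L)  # ends 400 bp in
  expect_equal(count_junction_pairs(mk(L - 501L), sc, p), 0L)  # crosses boundary
  # mate order in the record must not matter
  flipped <- paired_alignments("r", "s1", L - 120L, L - 20L, "+", 10L, 110L, "-")
  expect_equal(count_junction_pairs(flipped, sc, p), 1L)

  # inward-facing (ordinary FR) orientation is rejected in strict mode
  wrong <- paired_alignments("r", "s1", 10L, 110L, "+", L - 120L, L - 20L, "-")
  expect_equal(count_junction_pairs(wrong, sc, p), 0L)
  permissive <- detection_params(require_orientation = FALSE)
  expect_equal(count_junction_pairs(wrong, sc, permissive), 1L)

  # contract violations
  alien <- paired_alignments("r", "s2", 10L, 110L, "-", 100L, 200L, "+")
  expect_error(count_junction_pairs(alien, sc, p), "other than 's1'")
  too_long <- paired_alignments("r", "s1", 10L, 110L, "-", L - 50L, L + 50L, "+")
  expect_error(count_junction_pairs(too_long, sc, p), "exceeds scaffold")
})

test_that("each criterion threshold sits exactly where documented", {
  set.seed(27)
  p <- detection_params()

  # (i) scaffold length strictly greater than 2 kb
  for (L in c(2000L, 2001L)) {
    sc <- scaffold_set("s", planted_circular_scaffold(L - 100L, 100L))
    stopifnot(sc$length == L)
    cc <- call_circular(sc, find_end_overlap(sc, p),
                        n_junction_pairs = 5L, params = p)
    expect_equal(cc$is_circular, L > 2000L)
    expect_equal(cc$passed_length, L > 2000L)
  }

  # (ii) overlap strictly longer than 34 bp
  for (m in c(34L, 35L)) {
    sc <- scaffold_set("s", planted_circular_scaffold(5000L, m))
    ov <- find_end_overlap(sc, p)
    cc <- call_circular(sc, ov, n_junction_pairs = 5L, params = p)
    expect_equal(ov$length, m)
    expect_equal(cc$is_circular, m > 34L)
  }

  # (iii) at least two junction pairs
  sc <- scaffold_set("s", planted_circular_scaffold(5000L, 100L))
  ov <- find_end_overlap(sc, p)
  expect_false(call_circular(sc, ov, 1L, p)$is_circular)
  expect_true(call_circular(sc, ov, 2L, p)$is_circular)
})

test_that("circularity is the strict conjunction of the three criteria", {
  set.seed(28)
  sc <- scaffold_set("s", planted_circular_scaffold(5000L, 100L))
  ov <- find_end_overlap(sc)
  base <- detection_params()
  expect_true(call_circular(sc, ov, 5L, base)$is_circular)
  # force exactly one criterion to fail at a time
  fail_len <- detection_params(min_scaffold_bp = 6000L)
  fail_ov <- detection_params(min_overlap_bp = 150L)
  fail_np <- detection_params(min_junction_pairs = 6L)
  for (p in list(fail_len, fail_ov, fail_np)) {
    cc <- call_circular(sc, find_end_overlap(sc, p), 5L, p)
    expect_false(cc$is_circular)
    expect_equal(sum(cc$passed_length, cc$passed_overlap, cc$passed_pairs), 2)
  }
})

test_that("circularize trims exactly the suffix copy of the repeat", {
  set.seed(29)
  X <- rnd_dna(50L)
  Y <- rnd_dna(3000L)
  sc <- scaffold_set("s", paste0(X, Y, X))
  ov <- find_end_overlap(sc)
  circ <- circularize(sc, ov)
  expect_equal(circ, paste0(X, Y))

  # doubling property: the doubled circle contains the original scaffold
  for (i in 1:10) {
    sc2 <- planted_circular_scaffold(sample(500:3000, 1L), sample(40:120, 1L))
    s2 <- scaffold_set("s", sc2)
    circ2 <- circularize(s2, find_end_overlap(s2))
    expect_true(grepl(sc2, paste0(circ2, circ2), fixed = TRUE))
  }

  # degenerate: trimming everything is a contract error
  fake <- structure(list(length = 100L, identity = 100, score = 100,
                         evalue = 0, prefix_range = c(0L, 100L),
                         suffix_range = c(0L, 3100L)), class = "end_overlap")
  expect_error(circularize(sc, fake), "nothing would remain")
  bad <- structure(list(suffix_range = c(3000L, 3200L)), class = "end_overlap")
  expect_error(circularize(sc, bad), "inconsistent")
  expect_error(circularize(sc, NULL), "absent")
})

test_that("detect_all separates circular plasmids from linear decoys", {
  set.seed(30)
  n_circ <- 6L
  ids <- c(sprintf("plasmid_%d", 1:n_circ), sprintf("decoy_%d", 1:4))
  seqs <- c(vapply(1:n_circ, function(i)
    planted_circular_scaffold(sample(3000:8000, 1L), 100L), ""),
    vapply(1:4, function(i) rnd_dna(sample(3000:8000, 1L)), ""))
  sc <- scaffold_set(ids, seqs)
  pairs <- do.call(rbind, lapply(seq_len(n_circ), function(i) {
    d <- junction_pairs_n(ids[i], sc$length[i], 5L)
    d$read_id <- paste0(ids[i], "_", d$read_id)
    d
  }))
  class(pairs) <- c("paired_alignments", "data.frame")
  calls <- detect_all(sc, pairs)
  tab <- calls_table(calls)
  expect_equal(tab$scaffold_id, ids)  # order preserved
  expect_equal(tab$is_circular, startsWith(ids, "plasmid"))

  # withholding read pairs kills every call (criterion iii necessary)
  tab0 <- calls_table(detect_all(sc, NULL))
  expect_equal(sum(tab0$is_circular), 0L)

  expect_length(detect_all(scaffold_set(character(), character()), NULL), 0L)
})

test_that("circular calls are monotone in the decision thresholds", {
  set.seed(31)
  ids <- sprintf("p%d", 1:6)
  seqs <- vapply(c(1500L, 2500L, 4000L, 6000L, 8000L, 10000L),
                 function(L) planted_circular_scaffold(L, sample(30:150, 1L)), "")
  sc <- scaffold_set(ids, seqs)
  pairs <- do.call(rbind, lapply(seq_along(ids), function(i) {
    d <- junction_pairs_n(ids[i], sc$length[i], i)  # 1..6 pairs
    d$read_id <- paste0(ids[i], "_", d$read_id)
    d
  }))
  class(pairs) <- c("paired_alignments", "data.frame")
  n_circ <- function(p) sum(calls_table(detect_all(sc, pairs, p))$is_circular)

  for (knob in c("min_scaffold_bp", "min_overlap_bp", "min_junction_pairs")) {
    grid <- switch(knob,
                   min_scaffold_bp = c(1000L, 2000L, 5000L, 9000L),
                   min_overlap_bp = c(10L, 34L, 80L, 200L),
                   min_junction_pairs = c(1L, 2L, 4L, 7L))
    counts <- vapply(grid, function(v) {
      n_circ(do.call(detection_params, stats::setNames(list(v), knob)))
    }, numeric(1L))
    expect_true(all(diff(counts) <= 0), info = knob)
  }
  counts_e <- vapply(c(1e-30, 1e-10, 1e-5, 1e-2),
                     function(e) n_circ(detection_params(max_evalue = e)),
                     numeric(1L))
  expect_true(all(diff(counts_e) >= 0))
})

test_that("detection is deterministic for identical inputs", {
  set.seed(32)
  sc <- scaffold_set("s", planted_circular_scaffold(4000L, 80L))
  pairs <- junction_pairs_n("s", sc$length, 3L)
  a <- calls_table(detect_all(sc, pairs))
  b <- calls_table(detect_all(sc, pairs))
  expect_identical(a, b)
})
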