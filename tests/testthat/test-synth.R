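small_spec <- function(seed = 1L, ...) {
  community_spec(
    plasmids = data.frame(length = c(3000L, 6000L), depth = 20, overlap_len = 100L),
    chromosomal_decoys = data.frame(length = 4000L, depth = 20),
    rrna_decoys = data.frame(length = 3000L, frag_len = 1500L, depth = 20),
    controls = data.frame(length = 5000L, depth = 40, overlap_len = 100L),
    seed = seed, ...)
}

test_that("linearized circular plasmids carry an exact terminal repeat", {
  com <- generate_community(small_spec())
  sc <- com$scaffolds
  p1 <- sc$seq[sc$id == "plasmid_01"]
  expect_equal(nchar(p1), 3100L)
  expect_equal(substr(p1, 1, 100), substr(p1, 3001, 3100))
  # decoys are linear (no planted repeat)
  d1 <- sc$seq[sc$id == "decoy_01"]
  expect_equal(nchar(d1), 4000L)

  set.seed(61)
  tpl <- rnd_dna(500)
  expect_equal(linearize_with_repeat(tpl, 0L), tpl)
  expect_error(linearize_with_repeat(tpl, 500L))
})

test_that("generation is deterministic in the seed and only in the seed", {
  a <- generate_community(small_spec(seed = 5L))
  b <- generate_community(small_spec(seed = 5L))
  c <- generate_community(small_spec(seed = 6L))
  expect_identical(a$scaffolds, b$scaffolds)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$scaffolds$seq, c$scaffolds$seq))
})

test_that("error-free reads are exact substrings of the doubled template", {
  set.seed(62)
  tpl <- rnd_dna(4000)
  sim <- simulate_read_pairs(tpl, circular = TRUE, n_pairs = 200L,
                             read_len = 100L, insert_mean = 350, insert_sd = 30)
  dbl <- paste0(tpl, tpl)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$reads$r2)))
  expect_true(all(vapply(sim$reads$r1, grepl, TRUE, x = dbl, fixed = TRUE)))
  expect_true(all(vapply(rc, grepl, TRUE, x = dbl, fixed = TRUE)))
  # and at the recorded truth positions
  expect_equal(substring(dbl, sim$truth$frag_start + 1L,
                         sim$truth$frag_start + 100L), sim$reads$r1,
               ignore_attr = TRUE)

  empty <- simulate_read_pairs(tpl, TRUE, 0L)
  expect_equal(nrow(empty$reads), 0L)
  expect_equal(nrow(empty$truth), 0L)
  expect_error(simulate_read_pairs(tpl, FALSE, 10L, insert_mean = 5000),
               "linear template")
})

test_that("substitution errors appear at the requested rate", {
  set.seed(63)
  tpl <- rnd_dna(2000)
  sim <- simulate_read_pairs(tpl, circular = FALSE, n_pairs = 500L,
                             read_len = 100L, insert_mean = 300, insert_sd = 0,
                             error_rate = 0.02)
  truth_r1 <- substring(tpl, sim$truth$frag_start + 1L, sim$truth$frag_start + 100L)
  mism <- sum(mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                     sim$reads$r1, truth_r1))
  n_bases <- 500 * 100
  expect_lt(abs(mism / n_bases - 0.02), 3 * sqrt(0.02 * 0.98 / n_bases))
})

test_that("junction-spanning fraction matches the analytic expectation", {
  set.seed(64)
  L <- 10000L
  tpl <- rnd_dna(L)
  ins <- 450
  sim <- simulate_read_pairs(tpl, circular = TRUE, n_pairs = 10000L,
                             read_len = 150L, insert_mean = ins, insert_sd = 50)
  p_expect <- (ins - 1) / L
  p_obs <- mean(sim$truth$junction_spanning)
  se <- sqrt(p_expect * (1 - p_expect) / 10000)
  expect_lt(abs(p_obs - p_expect), 3 * se)
})

test_that("mapped coverage matches nominal depth within sampling error", {
  set.seed(65)
  L <- 10000L
  depth <- 30
  read_len <- 150L
  tpl <- rnd_dna(L)
  scf <- scaffold_set("t1", linearize_with_repeat(tpl, 100L))
  n_pairs <- round(depth * L / (2 * read_len))
  sim <- simulate_read_pairs(tpl, circular = TRUE, n_pairs = n_pairs,
                             read_len = read_len, insert_mean = 450,
                             insert_sd = 50, template_id = "t1")
  pairs <- map_reads_naive(sim$reads, scf)
  cov <- coverage_from_alignments(pairs, scf)[["t1"]] * (L + 100) / L
  # effective number of independent read-length blocks along the circle
  se <- sqrt(depth / (L / read_len))
  expect_lt(abs(cov - depth), 3 * se)
})

test_that("the naive mapper recovers truth placements for error-free reads", {
  set.seed(66)
  tpl <- rnd_dna(5000)
  scf <- scaffold_set("s1", tpl)
  sim <- simulate_read_pairs(tpl, circular = FALSE, n_pairs = 300L,
                             read_len = 100L, insert_mean = 400, insert_sd = 30)
  pairs <- map_reads_naive(sim$reads, scf)
  expect_equal(nrow(pairs), 300L)  # 100% mapped
  tr <- sim$truth[match(pairs$read_id, sim$truth$read_id), ]
  expect_equal(pairs$m1_start, tr$frag_start)
  expect_equal(pairs$m1_end, tr$frag_start + 100L)
  expect_equal(pairs$m2_start, tr$frag_start + tr$insert - 100L)
  expect_equal(pairs$m2_end, tr$frag_start + tr$insert)
  expect_equal(unique(pairs$m1_strand), "+")
  expect_equal(unique(pairs$m2_strand), "-")

  # a read absent from every scaffold increments the unmapped tally
  alien <- sim$reads[1L, ]
  alien$read_id <- "alien"
  alien$r1 <- rnd_dna(100)
  res <- map_reads_naive(rbind(sim$reads, alien), scf)
  expect_equal(attr(res, "tallies")$unmapped, 1L)
  expect_equal(attr(res, "tallies")$orphan, 1L)

  # strand symmetry: a reverse-complemented read maps "-" on the same interval
  swap <- sim$reads[1:10, ]
  swap$r1 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(swap$r1)))
  res2 <- map_reads_naive(swap, scf)
  tr2 <- sim$truth[match(res2$read_id, sim$truth$read_id), ]
  expect_equal(res2$m1_start, tr2$frag_start)
  expect_equal(unique(res2$m1_strand), "-")

  expect_error(map_reads_naive(sim$reads, scf, k = 200L), "read length")
})

test_that("junction-pair counting agrees with a truth-position oracle", {
  set.seed(67)
  L <- 8000L
  ov <- 100L
  rl <- 150L
  tpl <- rnd_dna(L)
  scf <- scaffold_set("t1", linearize_with_repeat(tpl, ov))
  sim <- simulate_read_pairs(tpl, circular = TRUE, n_pairs = 2000L,
                             read_len = rl, insert_mean = 450, insert_sd = 50,
                             template_id = "t1")
  pairs <- map_reads_naive(sim$reads, scf)
  counted <- count_junction_pairs(pairs, scf)
  oracle <- junction_count_from_truth(sim$truth, L, ov, rl)
  expect_gt(oracle, 0L)
  expect_equal(counted, oracle)
})

test_that("criterion ablation removes exactly the intended plasmid", {
  # boundary overlap (34 bp) fails criterion (ii) for that plasmid only
  spec <- community_spec(
    plasmids = data.frame(length = c(4000L, 6000L), depth = 20,
                          overlap_len = c(34L, 100L)),
    chromosomal_decoys = data.frame(length = 4000L, depth = 20),
    rrna_decoys = data.frame(length = 3000L, frag_len = 1500L, depth = 20),
    controls = data.frame(length = 5000L, depth = 40, overlap_len = 100L),
    seed = 68L)
  com <- generate_community(spec)
  pairs <- map_reads_naive(com$reads, com$scaffolds)
  tab <- calls_table(detect_all(com$scaffolds, pairs))
  expect_false(tab$is_circular[tab$scaffold_id == "plasmid_01"])
  expect_true(tab$is_circular[tab$scaffold_id == "plasmid_02"])

  # starving one plasmid of depth fails criterion (iii) for it only
  spec2 <- community_spec(
    plasmids = data.frame(length = c(4000L, 6000L), depth = c(0.2, 20),
                          overlap_len = 100L),
    chromosomal_decoys = data.frame(length = 4000L, depth = 20),
    rrna_decoys = data.frame(length = 3000L, frag_len = 1500L, depth = 20),
    controls = data.frame(length = 5000L, depth = 40, overlap_len = 100L),
    seed = 69L)
  com2 <- generate_community(spec2)
  pairs2 <- map_reads_naive(com2$reads, com2$scaffolds)
  tab2 <- calls_table(detect_all(com2$scaffolds, pairs2))
  expect_false(tab2$is_circular[tab2$scaffold_id == "plasmid_01"])
  expect_lt(tab2$n_junction_pairs[tab2$scaffold_id == "plasmid_01"], 2L)
  expect_true(tab2$is_circular[tab2$scaffold_id == "plasmid_02"])

  # invariant spec checks
  expect_error(community_spec(read_len = 150L, insert_mean = 100), "insert_mean")
  expect_error(community_spec(error_rate = 1), "error_rate")
})

test_that("FASTQ output carries every read with constant qualities", {
  com <- generate_community(small_spec(seed = 70L))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(com$reads[1:50, ], f1, f2)
  l1 <- readLines(f1)
  expect_equal(length(l1), 200L)
  expect_equal(l1[1L], paste0("@", com$reads$read_id[1L], "/1"))
  expect_equal(l1[2L], com$reads$r1[1L])
  expect_equal(nchar(l1[4L]), nchar(l1[2L]))
  expect_true(all(grepl("^I+$", l1[seq(4, 200, by = 4)])))
})
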