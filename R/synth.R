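# Synthetic plasmidome communities -------------------------------------------
#
# Emulates the inputs the detector consumes: circular plasmids emitted as
# linear scaffolds carrying an exact terminal direct repeat, paired-end
# reads drawn from the circular template (so junction-spanning fragments
# exist), linear chromosomal decoys, 16S-carrying decoys, and spiked
# control plasmids mirroring a 5 / 48 / 202 kb model system. Hit tables for
# the decontamination filters are fabricated from the planted truth: the
# sequence searches themselves are out of scope, their outputs are what the
# pipeline consumes.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Random DNA sequence (uniform base composition)
#'
#' Uses the current RNG state; wrap in a seeded context for reproducibility.
#'
#' @param n length in bp.
#' @return a DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Linearize a circular template with a terminal direct repeat
#'
#' Appends the first `overlap_len` bases of the circular template to its
#' end, producing the linear scaffold an assembler emits for a circular
#' molecule.
#'
#' @param template circular template sequence (one full monomer).
#' @param overlap_len repeat length in bp (< template length).
#' @return linear scaffold string of length `nchar(template) + overlap_len`.
#' @export
linearize_with_repeat <- function(template, overlap_len) {
  stopifnot(overlap_len >= 0L, overlap_len < nchar(template))
  if (overlap_len == 0L) return(template)
  paste0(template, substr(template, 1L, overlap_len))
}

#' Specify a synthetic community
#'
#' Defaults describe the package's reference community: 20 circular
#' plasmids from 3 to 250 kb (including a 202-kb control-scale replicon) at
#' 20x depth with 100-bp exact terminal repeats, 10 linear chromosomal
#' decoys, 4 rRNA-carrying decoys with planted 1,500-bp 16S fragments, and
#' the three spiked control plasmids (5, 48 and 202 kb) at elevated depth.
#'
#' @param plasmids data.frame with columns `length` (circular length, bp),
#'   `depth`, `overlap_len` (terminal repeat, bp).
#' @param chromosomal_decoys data.frame with `length`, `depth`.
#' @param rrna_decoys data.frame with `length`, `frag_len` (planted 16S
#'   fragment length, bp), `depth`.
#' @param controls data.frame with `length`, `depth`, `overlap_len`
#'   (controls are circular plasmids too).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert-size model (bp); `insert_mean` must
#'   exceed `read_len`.
#' @param error_rate per-base substitution rate in reads, in \[0, 1).
#' @param seed integer RNG seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(
    plasmids = data.frame(
      length = c(3, 5, 8, 10, 12, 15, 20, 25, 30, 40, 50, 60, 75, 90,
                 110, 130, 150, 180, 202, 250) * 1000L,
      depth = 20, overlap_len = 100L),
    chromosomal_decoys = data.frame(
      length = c(5, 8, 10, 12, 15, 18, 20, 22, 25, 30) * 1000L, depth = 20),
    rrna_decoys = data.frame(length = 8000L, frag_len = 1500L, depth = 20)[rep(1L, 4L), ],
    controls = data.frame(length = c(5000L, 48000L, 202000L),
                          depth = 40, overlap_len = 100L),
    read_len = 150L, insert_mean = 450, insert_sd = 50,
    error_rate = 0, seed = 1L) {
  spec <- list(plasmids = plasmids, chromosomal_decoys = chromosomal_decoys,
               rrna_decoys = rrna_decoys, controls = controls,
               read_len = as.integer(read_len),
               insert_mean = as.numeric(insert_mean),
               insert_sd = as.numeric(insert_sd),
               error_rate = as.numeric(error_rate),
               seed = as.integer(seed))
  if (any(unlist(lapply(list(plasmids$length, plasmids$depth,
                             chromosomal_decoys$length, chromosomal_decoys$depth,
                             rrna_decoys$length, rrna_decoys$depth,
                             controls$length, controls$depth), `<=`, 0)))) {
    stop("lengths and depths must be positive", call. = FALSE)
  }
  if (spec$insert_mean <= spec$read_len) {
    stop("insert_mean must exceed read_len", call. = FALSE)
  }
  if (spec$error_rate < 0 || spec$error_rate >= 1) {
    stop("error_rate must lie in [0, 1)", call. = FALSE)
  }
  class(spec) <- "community_spec"
  spec
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    nmut <- stats::rbinom(1L, n, rate)
    if (nmut == 0L) next
    pos <- sample.int(n, nmut)
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from one template
#'
#' Fragments are uniform on the template (wrapping across the origin when
#' `circular = TRUE`), with FR orientation: read 1 is the fragment's 5' end
#' on the forward strand, read 2 the reverse complement of its 3' end.
#' Insert sizes are normal (`insert_mean`, `insert_sd`), rounded and clamped
#' below at `read_len`.
#'
#' @param template template sequence (the circular monomer when
#'   `circular = TRUE`).
#' @param circular logical; wrap fragments across the origin?
#' @param n_pairs number of read pairs.
#' @param read_len,insert_mean,insert_sd,error_rate see [community_spec()].
#' @param seed optional seed (NULL = use current RNG state).
#' @param template_id,read_prefix identifiers used in the truth table and
#'   read names.
#' @return list with `reads` (data.frame read_id, r1, r2) and `truth`
#'   (data.frame read_id, template_id, frag_start, insert,
#'   junction_spanning; `frag_start` 0-based on the template, mate 2
#'   occupies `[frag_start + insert - read_len, frag_start + insert)`,
#'   positions taken modulo the template length when circular).
#' @export
simulate_read_pairs <- function(template, circular, n_pairs, read_len = 150L,
                                insert_mean = 450, insert_sd = 50,
                                error_rate = 0, seed = NULL,
                                template_id = "template", read_prefix = template_id) {
  L <- nchar(template)
  stopifnot(read_len >= 1L, n_pairs >= 0L)
  if (!circular && insert_mean >= L) {
    stop("insert_mean must be smaller than a linear template", call. = FALSE)
  }
  if (n_pairs == 0L) {
    return(list(reads = data.frame(read_id = character(), r1 = character(),
                                   r2 = character(), stringsAsFactors = FALSE),
                truth = data.frame(read_id = character(), template_id = character(),
                                   frag_start = integer(), insert = integer(),
                                   junction_spanning = logical(),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    ins <- pmax(as.integer(read_len),
                as.integer(round(stats::rnorm(n_pairs, insert_mean, insert_sd))))
    ins <- pmin(ins, L)  # a fragment never exceeds one full monomer
    if (circular) {
      s <- sample.int(L, n_pairs, replace = TRUE) - 1L
    } else {
      s <- vapply(ins, function(i) sample.int(L - i + 1L, 1L) - 1L, integer(1L))
    }
    src <- if (circular) paste0(template, template) else template
    r1 <- substring(src, s + 1L, s + read_len)
    r2 <- revcomp(substring(src, s + ins - read_len + 1L, s + ins))
    r1 <- inject_errors(r1, error_rate)
    r2 <- inject_errors(r2, error_rate)
    read_id <- sprintf("%s_p%06d", read_prefix, seq_len(n_pairs))
    list(reads = data.frame(read_id = read_id, r1 = r1, r2 = r2,
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = read_id, template_id = template_id,
                            frag_start = s, insert = ins,
                            junction_spanning = circular & (s + ins > L),
                            stringsAsFactors = FALSE))
  })
}

plant_markers <- function(plasmid_ids) {
  # planted typing truth: mobility class, MOB family, Inc group per plasmid,
  # plus the long-format marker table the classifier consumes
  n <- length(plasmid_ids)
  mobility <- sample(c("nonmobilizable", "mobilizable", "conjugative"), n,
                     replace = TRUE, prob = c(0.6, 0.25, 0.15))
  mob <- ifelse(mobility == "nonmobilizable", "untyped",
                sample(MOB_FAMILIES, n, replace = TRUE,
                       prob = c(0.1, 0.3, 0.3, 0.1, 0.1, 0.05, 0.05)))
  inc_labels <- c("IncA/C cgPMLST", "IncF RST", "Inc HI1 MLST", "Inc HI2 DLST",
                  "IncI1 MLST", "IncN MLST")
  inc <- sample(c(inc_labels, "untyped"), n, replace = TRUE,
                prob = c(0.3, 0.1, 0.08, 0.08, 0.07, 0.07, 0.3))
  rows <- list()
  for (i in seq_len(n)) {
    id <- plasmid_ids[i]
    if (mobility[i] != "nonmobilizable") {
      rows[[length(rows) + 1L]] <- data.frame(
        plasmid_id = id, marker_class = "relaxase",
        subject_id = paste0(mob[i], "_ref"),
        bitscore = round(stats::runif(1L, 100, 400), 1), family = mob[i],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        plasmid_id = id, marker_class = "orit", subject_id = "oriT_ref",
        bitscore = round(stats::runif(1L, 60, 150), 1), family = "",
        stringsAsFactors = FALSE)
    }
    if (mobility[i] == "conjugative") {
      rows[[length(rows) + 1L]] <- data.frame(
        plasmid_id = id, marker_class = "t4ss", subject_id = "virB4_ref",
        bitscore = round(stats::runif(1L, 200, 600), 1), family = "",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        plasmid_id = id, marker_class = "t4cp", subject_id = "virD4_ref",
        bitscore = round(stats::runif(1L, 150, 400), 1), family = "",
        stringsAsFactors = FALSE)
    }
    if (inc[i] != "untyped") {
      rows[[length(rows) + 1L]] <- data.frame(
        plasmid_id = id, marker_class = "inc", subject_id = "inc_locus",
        bitscore = round(stats::runif(1L, 100, 400), 1), family = inc[i],
        stringsAsFactors = FALSE)
    }
  }
  markers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plasmid_id = character(), marker_class = character(),
               subject_id = character(), bitscore = numeric(),
               family = character(), stringsAsFactors = FALSE)
  list(markers = markers,
       truth = data.frame(plasmid_id = plasmid_ids, mobility = mobility,
                          mob_type = mob, inc_group = inc,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic plasmidome community
#'
#' Produces everything one pipeline run consumes: scaffolds (circular
#' members linearized with exact terminal repeats), paired-end reads drawn
#' from the circular templates, fabricated 16S and control-plasmid hit
#' tables, a planted marker table, and a truth table. Deterministic under
#' the spec's seed.
#'
#' @param spec a [community_spec()].
#' @return list with elements `scaffolds` ([scaffold_set()], coverage set to
#'   nominal depth), `reads` (data.frame read_id, r1, r2), `truth` (list
#'   `scaffolds` and `pairs` data.frames), `rrna_hits`, `control_hits`,
#'   `markers` (long-format marker table for community plasmids) and
#'   `marker_truth` (planted type labels).
#' @export
generate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    members <- list()
    add_member <- function(id, circ_len, overlap_len, depth, origin, frag_len = NA) {
      members[[length(members) + 1L]] <<- list(
        id = id, circ_len = as.integer(circ_len),
        overlap_len = as.integer(overlap_len), depth = depth,
        origin = origin, frag_len = frag_len)
    }
    for (i in seq_len(nrow(spec$plasmids))) {
      add_member(sprintf("plasmid_%02d", i), spec$plasmids$length[i],
                 spec$plasmids$overlap_len[i], spec$plasmids$depth[i], "plasmid")
    }
    for (i in seq_len(nrow(spec$chromosomal_decoys))) {
      add_member(sprintf("decoy_%02d", i), spec$chromosomal_decoys$length[i],
                 0L, spec$chromosomal_decoys$depth[i], "chromosome")
    }
    for (i in seq_len(nrow(spec$rrna_decoys))) {
      add_member(sprintf("rrna_decoy_%02d", i), spec$rrna_decoys$length[i],
                 0L, spec$rrna_decoys$depth[i], "rrna_decoy",
                 frag_len = spec$rrna_decoys$frag_len[i])
    }
    for (i in seq_len(nrow(spec$controls))) {
      add_member(sprintf("control_%dkb", round(spec$controls$length[i] / 1000)),
                 spec$controls$length[i], spec$controls$overlap_len[i],
                 spec$controls$depth[i], "control")
    }

    ids <- vapply(members, `[[`, "", "id")
    seqs <- character(length(members))
    reads_list <- vector("list", length(members))
    truth_pairs <- vector("list", length(members))
    for (i in seq_along(members)) {
      m <- members[[i]]
      circular <- m$overlap_len > 0L
      template <- random_dna(m$circ_len)
      seqs[i] <- if (circular) linearize_with_repeat(template, m$overlap_len)
                 else template
      n_pairs <- as.integer(round(m$depth * m$circ_len / (2 * spec$read_len)))
      sim <- simulate_read_pairs(template, circular = circular,
                                 n_pairs = n_pairs, read_len = spec$read_len,
                                 insert_mean = spec$insert_mean,
                                 insert_sd = spec$insert_sd,
                                 error_rate = spec$error_rate,
                                 template_id = m$id, read_prefix = m$id)
      reads_list[[i]] <- sim$reads
      truth_pairs[[i]] <- sim$truth
    }

    scaffolds <- scaffold_set(ids, seqs,
                              coverage = vapply(members, `[[`, numeric(1L), "depth"))
    truth_scaffolds <- data.frame(
      scaffold_id = ids,
      origin = vapply(members, `[[`, "", "origin"),
      is_circular = vapply(members, function(m) m$overlap_len > 0L, logical(1L)),
      circular_len = vapply(members, `[[`, integer(1L), "circ_len"),
      overlap_len = vapply(members, `[[`, integer(1L), "overlap_len"),
      depth = vapply(members, `[[`, numeric(1L), "depth"),
      stringsAsFactors = FALSE)

    rrna_idx <- which(truth_scaffolds$origin == "rrna_decoy")
    rrna_hits <- hit_table(
      query_id = ids[rrna_idx], subject_id = "16S_SILVA_ref",
      pct_identity = 97.5,
      aln_len = vapply(members[rrna_idx], function(m) as.integer(m$frag_len),
                       integer(1L)),
      evalue = 1e-50)
    ctrl_idx <- which(truth_scaffolds$origin == "control")
    control_hits <- hit_table(
      query_id = ids[ctrl_idx],
      subject_id = paste0(ids[ctrl_idx], "_ref"),
      pct_identity = 100,
      aln_len = scaffolds$length[ctrl_idx],
      evalue = 0)

    plas_ids <- ids[truth_scaffolds$origin == "plasmid"]
    planted <- plant_markers(plas_ids)

    list(scaffolds = scaffolds,
         reads = do.call(rbind, reads_list),
         truth = list(scaffolds = truth_scaffolds,
                      pairs = do.call(rbind, truth_pairs)),
         rrna_hits = rrna_hits,
         control_hits = control_hits,
         markers = planted$markers,
         marker_truth = planted$truth)
  })
}

#' Write simulated reads as paired FASTQ files
#'
#' Qualities are constant ("I" for every base).
#'
#' @param reads data.frame (read_id, r1, r2) from the simulator.
#' @param path_r1,path_r2 output FASTQ files for mates 1 and 2.
#' @return invisibly, `c(path_r1, path_r2)`.
#' @export
write_fastq <- function(reads, path_r1, path_r2) {
  fq <- function(ids, seqs, path) {
    qual <- strrep("I", nchar(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  fq(paste0(reads$read_id, "/1"), reads$r1, path_r1)
  fq(paste0(reads$read_id, "/2"), reads$r2, path_r2)
  invisible(c(path_r1, path_r2))
}
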