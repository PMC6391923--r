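# Plasmid typing -------------------------------------------------------------
#
# Mobility follows the operational scheme: a plasmid is conjugative
# (self-transmissible) when it encodes both a relaxase and a type IV
# secretion system (T4SS); mobilizable when it encodes a relaxase but no
# T4SS; nonmobilizable otherwise. T4CP and the oriT/oriV origins are carried
# in the profile for reporting but never change the class: origins are
# rarely detectable by homology and T4CP is optional in mobilizable
# plasmids. MOB family and incompatibility group are best-bitscore-hit
# assignments over the profile's relaxase and Inc-scheme hits.

#' Relaxase MOB families, in tie-break priority order
#' @export
MOB_FAMILIES <- c("MOBF", "MOBP", "MOBQ", "MOBC", "MOBV", "MOBB", "MOBT")

MOBILITY_CLASSES <- c("conjugative", "mobilizable", "nonmobilizable")

#' Incompatibility-group label for the cgPMLST/PMLST two-scheme ambiguity
INC_AC_COMBINED <- "IncA/C cgPMLST or IncA/C PMLST"

#' Build a marker profile for one plasmid
#'
#' @param plasmid_id plasmid identifier.
#' @param relaxase_hits data.frame with columns `family` (one of
#'   [MOB_FAMILIES]), `bitscore`, and optionally `subject_id`; zero rows
#'   when no relaxase was found.
#' @param has_t4ss,has_t4cp,has_orit,has_oriv marker presence flags.
#' @param inc_hits data.frame with columns `label` (Inc scheme label) and
#'   `bitscore`.
#' @return a `marker_profile` list.
#' @export
marker_profile <- function(plasmid_id,
                           relaxase_hits = NULL,
                           has_t4ss = FALSE, has_t4cp = FALSE,
                           has_orit = FALSE, has_oriv = FALSE,
                           inc_hits = NULL) {
  rel <- if (is.null(relaxase_hits)) {
    data.frame(family = character(), bitscore = numeric(),
               subject_id = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("family", "bitscore") %in% names(relaxase_hits)))
    if (is.null(relaxase_hits$subject_id)) relaxase_hits$subject_id <- ""
    if (!all(relaxase_hits$family %in% MOB_FAMILIES)) {
      stop(sprintf("unknown MOB family: %s",
                   paste(setdiff(relaxase_hits$family, MOB_FAMILIES),
                         collapse = ", ")), call. = FALSE)
    }
    if (any(relaxase_hits$bitscore < 0)) stop("bitscores must be >= 0", call. = FALSE)
    relaxase_hits[, c("family", "bitscore", "subject_id")]
  }
  inc <- if (is.null(inc_hits)) {
    data.frame(label = character(), bitscore = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("label", "bitscore") %in% names(inc_hits)))
    if (any(inc_hits$bitscore < 0)) stop("bitscores must be >= 0", call. = FALSE)
    inc_hits[, c("label", "bitscore")]
  }
  structure(list(plasmid_id = as.character(plasmid_id),
                 relaxase_hits = rel,
                 has_t4ss = isTRUE(has_t4ss), has_t4cp = isTRUE(has_t4cp),
                 has_orit = isTRUE(has_orit), has_oriv = isTRUE(has_oriv),
                 inc_hits = inc),
            class = "marker_profile")
}

#' Read marker profiles from a long-format marker table
#'
#' One row per marker hit: columns `plasmid_id`, `marker_class` (one of
#' relaxase, t4ss, t4cp, orit, oriv, inc), `subject_id`, `bitscore`, and
#' `family` (MOB family for relaxase rows, Inc scheme label for inc rows).
#' Hits below `min_bitscore` do not establish marker presence.
#'
#' @param markers data.frame (or TSV path) in the long format above.
#' @param min_bitscore minimum bitscore for a marker to count as present
#'   (default 50).
#' @param plasmid_ids optional ids to guarantee a (possibly empty) profile
#'   for every plasmid, hits or not.
#' @return named list of [marker_profile()] objects.
#' @export
marker_profiles <- function(markers, min_bitscore = 50, plasmid_ids = NULL) {
  if (is.character(markers) && length(markers) == 1L) {
    markers <- utils::read.delim(markers, header = TRUE, stringsAsFactors = FALSE)
  }
  need <- c("plasmid_id", "marker_class", "subject_id", "bitscore", "family")
  missing <- setdiff(need, names(markers))
  if (length(missing)) {
    stop(sprintf("marker table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  known <- c("relaxase", "t4ss", "t4cp", "orit", "oriv", "inc")
  if (nrow(markers) && !all(markers$marker_class %in% known)) {
    stop(sprintf("unknown marker_class: %s",
                 paste(setdiff(markers$marker_class, known), collapse = ", ")),
         call. = FALSE)
  }
  markers <- markers[markers$bitscore >= min_bitscore, , drop = FALSE]
  ids <- unique(c(as.character(plasmid_ids), markers$plasmid_id))
  out <- lapply(ids, function(id) {
    m <- markers[markers$plasmid_id == id, , drop = FALSE]
    rel <- m[m$marker_class == "relaxase", , drop = FALSE]
    inc <- m[m$marker_class == "inc", , drop = FALSE]
    marker_profile(
      id,
      relaxase_hits = if (nrow(rel)) data.frame(family = rel$family,
                                                bitscore = rel$bitscore,
                                                subject_id = rel$subject_id,
                                                stringsAsFactors = FALSE),
      has_t4ss = any(m$marker_class == "t4ss"),
      has_t4cp = any(m$marker_class == "t4cp"),
      has_orit = any(m$marker_class == "orit"),
      has_oriv = any(m$marker_class == "oriv"),
      inc_hits = if (nrow(inc)) data.frame(label = inc$family,
                                           bitscore = inc$bitscore,
                                           stringsAsFactors = FALSE))
  })
  stats::setNames(out, ids)
}

#' Classify plasmid mobility
#'
#' Conjugative = relaxase and T4SS present; mobilizable = relaxase without
#' T4SS; nonmobilizable otherwise. T4CP never changes the class.
#'
#' @param profile a [marker_profile()].
#' @return one of `"conjugative"`, `"mobilizable"`, `"nonmobilizable"`.
#' @export
classify_mobility <- function(profile) {
  stopifnot(inherits(profile, "marker_profile"))
  has_relaxase <- nrow(profile$relaxase_hits) > 0L
  if (has_relaxase && profile$has_t4ss) "conjugative"
  else if (has_relaxase) "mobilizable"
  else "nonmobilizable"
}

#' Assign the relaxase MOB family
#'
#' Family of the highest-bitscore relaxase hit; ties are broken by the fixed
#' family order MOBF > MOBP > MOBQ > MOBC > MOBV > MOBB > MOBT, then by
#' lexical subject id.
#'
#' @param profile a [marker_profile()].
#' @return a MOB family or `"untyped"`.
#' @export
assign_mob_type <- function(profile) {
  stopifnot(inherits(profile, "marker_profile"))
  h <- profile$relaxase_hits
  if (nrow(h) == 0L) return("untyped")
  ord <- order(-h$bitscore, match(h$family, MOB_FAMILIES), h$subject_id)
  h$family[ord[1L]]
}

#' Assign the incompatibility group
#'
#' Label of the highest-bitscore Inc-scheme hit; when the IncA/C cgPMLST and
#' IncA/C PMLST schemes tie at the top score the combined label
#' `"IncA/C cgPMLST or IncA/C PMLST"` is reported; other ties resolve to the
#' lexically first label.
#'
#' @param profile a [marker_profile()].
#' @return an Inc label or `"untyped"`.
#' @export
assign_inc_group <- function(profile) {
  stopifnot(inherits(profile, "marker_profile"))
  h <- profile$inc_hits
  if (nrow(h) == 0L) return("untyped")
  top <- sort(unique(h$label[h$bitscore == max(h$bitscore)]))
  if (length(top) == 1L) return(top)
  if (setequal(top, c("IncA/C PMLST", "IncA/C cgPMLST"))) return(INC_AC_COMBINED)
  top[1L]
}

#' Type a set of plasmids
#'
#' @param profiles a list of [marker_profile()] objects (e.g. from
#'   [marker_profiles()]).
#' @return data.frame of type calls: plasmid_id, mobility, mob_type,
#'   inc_group.
#' @export
classify_plasmids <- function(profiles) {
  if (inherits(profiles, "marker_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(plasmid_id = p$plasmid_id,
               mobility = classify_mobility(p),
               mob_type = assign_mob_type(p),
               inc_group = assign_inc_group(p),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(plasmid_id = character(), mobility = character(),
                      mob_type = character(), inc_group = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize plasmid type calls
#'
#' @param calls data.frame from [classify_plasmids()].
#' @param sizes named numeric vector of plasmid sizes in bp, keyed by
#'   plasmid id (must cover every call).
#' @param size_breaks_kb bin edges in kb for the MOB-by-size table.
#' @return list with `mobility` (class, n, fraction; fractions sum to 1 on
#'   nonempty input), `mob_counts`, `mob_by_size` (family x size-bin counts)
#'   and `inc_counts`.
#' @export
summarize_types <- function(calls, sizes,
                            size_breaks_kb = c(0, 10, 25, 50, 100, 250, Inf)) {
  stopifnot(is.data.frame(calls),
            all(c("plasmid_id", "mobility", "mob_type", "inc_group") %in% names(calls)))
  if (nrow(calls) && !all(calls$plasmid_id %in% names(sizes))) {
    bad <- setdiff(calls$plasmid_id, names(sizes))
    stop(sprintf("no size for plasmid(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  n_total <- nrow(calls)
  mob_n <- vapply(MOBILITY_CLASSES, function(cl) sum(calls$mobility == cl),
                  integer(1L))
  mobility <- data.frame(class = MOBILITY_CLASSES, n = mob_n,
                         fraction = if (n_total > 0L) mob_n / n_total else
                           rep(0, length(MOBILITY_CLASSES)),
                         stringsAsFactors = FALSE)
  fam_levels <- c(MOB_FAMILIES, "untyped")
  mob_counts <- table(factor(calls$mob_type, levels = fam_levels))
  inc_counts <- table(calls$inc_group)
  size_kb <- if (n_total > 0L) as.numeric(sizes[calls$plasmid_id]) / 1000 else numeric()
  bins <- cut(size_kb, breaks = size_breaks_kb, include.lowest = TRUE)
  mob_by_size <- table(factor(calls$mob_type, levels = fam_levels), bins,
                       dnn = c("mob_type", "size_kb"))
  list(mobility = mobility,
       mob_counts = mob_counts,
       mob_by_size = mob_by_size,
       inc_counts = inc_counts)
}
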