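SCORE_TYPES <- c("fold_ratio", "z_score", "p_value", "rank", "binary", "tiered")
CONTINUOUS_SCORE_TYPES <- c("fold_ratio", "z_score", "p_value", "rank")
LIBRARY_TYPES <- c("homozygous", "heterozygous")
PROFILE_CLASSES <- c("chemical_genetic", "genetic_genetic")
POLARITIES <- c("low_is_defect", "high_is_defect")
SEVERITY_LEVELS <- c("SL", "SD", "PE") # decreasing severity
TIE_RULES <- c("lexicographic", "input_order")

#' Fitness profile
#'
#' A raw strain-to-score table from one fitness experiment (one compound
#' treatment or one gene perturbation assayed across a deletion collection),
#' together with the metadata needed to interpret the scores: the scoring
#' scheme and its polarity, the library type (homozygous deletions probe
#' pathways, heterozygous ones probe direct drug targets via
#' haploinsufficiency), and the profile class.
#'
#' @param profile_id Unique profile identifier.
#' @param scores Named numeric vector, one score per deletion strain. Names
#'   are strain identifiers (ORF names or arbitrary tokens) and must be
#'   unique; values must be finite.
#' @param treatment Compound name or gene perturbation.
#' @param score_type One of `"fold_ratio"`, `"z_score"`, `"p_value"`,
#'   `"rank"`, `"binary"`, `"tiered"`.
#' @param polarity `"low_is_defect"` if a low score means a strong growth
#'   defect (p-values, fold-ratios), `"high_is_defect"` otherwise. Polarity
#'   is explicit because score semantics differ by platform; it is never
#'   auto-detected.
#' @param library_type `"homozygous"` or `"heterozygous"`.
#' @param profile_class `"chemical_genetic"` or `"genetic_genetic"`.
#' @param dose Optional dose string.
#' @param platform Free-text platform description.
#' @param metadata Named list of extra metadata carried through untouched.
#' @return An object of class `fitness_profile`.
#' @seealso [to_rank_profile()], [read_profile_yaml()]
#' @export
fitness_profile <- function(profile_id, scores, treatment = "",
                            score_type = "z_score",
                            polarity = "low_is_defect",
                            library_type = "homozygous",
                            profile_class = "chemical_genetic",
                            dose = NULL, platform = "", metadata = list()) {
  stopifnot(is.character(profile_id), length(profile_id) == 1L,
            nzchar(profile_id))
  score_type <- match.arg(score_type, SCORE_TYPES)
  polarity <- match.arg(polarity, POLARITIES)
  library_type <- match.arg(library_type, LIBRARY_TYPES)
  profile_class <- match.arg(profile_class, PROFILE_CLASSES)
  if (length(scores) == 0L)
    stop("profile '", profile_id, "': scores must be non-empty")
  strains <- names(scores)
  if (is.null(strains) || any(!nzchar(strains)))
    stop("profile '", profile_id, "': all scores must be named by strain id")
  if (anyDuplicated(strains))
    stop("profile '", profile_id, "': duplicate strain id(s): ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "))
  if (is.numeric(scores) && any(!is.finite(scores))) {
    bad <- strains[!is.finite(scores)]
    stop("profile '", profile_id, "': non-finite score for strain(s): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(profile_id = profile_id, treatment = treatment, dose = dose,
         library_type = library_type, profile_class = profile_class,
         platform = platform, score_type = score_type, polarity = polarity,
         scores = scores, metadata = metadata),
    class = "fitness_profile")
}

#' @export
print.fitness_profile <- function(x, ...) {
  cat("<fitness_profile> ", x$profile_id, "\n",
      "  treatment: ", x$treatment,
      if (!is.null(x$dose)) paste0(" @ ", x$dose), "\n",
      "  class/library: ", x$profile_class, " / ", x$library_type, "\n",
      "  scores: ", length(x$scores), " strains (", x$score_type,
      ", ", x$polarity, ")\n", sep = "")
  invisible(x)
}

#' Rank profile
#'
#' The universal comparison currency: a strict permutation of a strain
#' universe in which position `r` holds the strain of rank `r`, rank 1 being
#' the most severe growth defect. Binary-origin profiles additionally carry
#' `fixed_query_cutoff` (ranks past the hit set are arbitrary, so the
#' optimizer fixes the cutoff there); tiered genetic profiles carry
#' `tier_boundaries` (within-tier order is arbitrary, so only tier ends are
#' meaningful cutoffs).
#'
#' @param profile_id Profile identifier.
#' @param ordered_strains Character vector of strain ids, rank order.
#' @param fixed_query_cutoff Optional integer in `1..n`.
#' @param tier_boundaries Optional strictly increasing integers `<= n`.
#' @param metadata Named list of carried-through metadata.
#' @return An object of class `rank_profile`.
#' @export
rank_profile <- function(profile_id, ordered_strains,
                         fixed_query_cutoff = NULL, tier_boundaries = NULL,
                         metadata = list()) {
  stopifnot(is.character(profile_id), length(profile_id) == 1L)
  ordered_strains <- as.character(ordered_strains)
  n <- length(ordered_strains)
  if (n == 0L) stop("profile '", profile_id, "': empty rank profile")
  if (anyDuplicated(ordered_strains))
    stop("profile '", profile_id, "': ordered_strains is not a permutation ",
         "(duplicate: ",
         paste(unique(ordered_strains[duplicated(ordered_strains)]),
               collapse = ", "), ")")
  if (!is.null(fixed_query_cutoff)) {
    fixed_query_cutoff <- as.integer(fixed_query_cutoff)
    stopifnot(length(fixed_query_cutoff) == 1L,
              fixed_query_cutoff >= 1L, fixed_query_cutoff <= n)
  }
  if (!is.null(tier_boundaries)) {
    tier_boundaries <- as.integer(tier_boundaries)
    if (any(diff(tier_boundaries) <= 0L) || any(tier_boundaries < 1L) ||
        any(tier_boundaries > n))
      stop("profile '", profile_id,
           "': tier_boundaries must be strictly increasing within 1..n")
  }
  structure(
    list(profile_id = profile_id, ordered_strains = ordered_strains,
         n = n, fixed_query_cutoff = fixed_query_cutoff,
         tier_boundaries = tier_boundaries, metadata = metadata),
    class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  head_strains <- utils::head(x$ordered_strains, 5L)
  cat("<rank_profile> ", x$profile_id, " (n = ", x$n, ")\n",
      "  top ranks: ", paste(head_strains, collapse = " > "),
      if (x$n > 5L) " > ...", "\n", sep = "")
  if (!is.null(x$fixed_query_cutoff))
    cat("  fixed query cutoff:", x$fixed_query_cutoff, "\n")
  if (!is.null(x$tier_boundaries))
    cat("  tier boundaries:", paste(x$tier_boundaries, collapse = ", "), "\n")
  invisible(x)
}

order_by_tie_rule <- function(strains, tie_rule) {
  if (tie_rule == "lexicographic") {
    strains[order(strains, method = "radix")]
  } else {
    strains
  }
}

#' Convert a fitness profile to a strict rank profile
#'
#' Transforms the fitness values of each strain into their ranks, the first
#' step of the rank-cutoff optimizer. Rank 1 is assigned to the strain with
#' the strongest growth defect according to the profile's `polarity`; ties in
#' the raw scores are broken by `tie_rule` so the output permutation is
#' deterministic.
#'
#' @param profile A [fitness_profile()] with a continuous score type
#'   (`fold_ratio`, `z_score`, `p_value` or `rank`).
#' @param tie_rule `"lexicographic"` (default; ties ordered by strain id) or
#'   `"input_order"` (ties keep their input order).
#' @return A [rank_profile()] over the same strains.
#' @examples
#' fp <- fitness_profile("ex", c(a = 0.9, b = 0.5, c = 0.1),
#'                       score_type = "z_score", polarity = "low_is_defect")
#' to_rank_profile(fp)$ordered_strains  # c, b, a
#' @export
to_rank_profile <- function(profile, tie_rule = c("lexicographic",
                                                  "input_order")) {
  stopifnot(inherits(profile, "fitness_profile"))
  tie_rule <- match.arg(tie_rule)
  if (!profile$score_type %in% CONTINUOUS_SCORE_TYPES)
    stop("profile '", profile$profile_id, "': score_type '",
         profile$score_type, "' is not continuous-valued; use ",
         "binary_to_rank_profile() or build_genetic_rank_profile()")
  scores <- profile$scores
  if (any(!is.finite(scores))) {
    bad <- names(scores)[!is.finite(scores)]
    stop("profile '", profile$profile_id,
         "': non-finite score for strain(s): ", paste(bad, collapse = ", "))
  }
  key <- if (profile$polarity == "low_is_defect") scores else -scores
  ord <- if (tie_rule == "lexicographic") {
    order(key, names(scores), method = "radix")
  } else {
    order(key, method = "radix") # radix sort is stable: input order kept
  }
  rank_profile(profile$profile_id, names(scores)[ord],
               metadata = profile$metadata)
}

#' Rank profile from a binary hit list
#'
#' Encodes a binary screen (a set of hit strains within a universe) as a rank
#' profile: hits occupy ranks `1..h`, non-hits fill the remaining ranks, both
#' blocks ordered by `tie_rule`. Because ranks beyond the hit set carry no
#' information, the result's `fixed_query_cutoff` is set to `h`, which pins
#' this profile's cutoff during optimization.
#'
#' @param hits Character vector of hit strain ids (non-empty, subset of
#'   `universe`).
#' @param universe Character vector of all strain ids.
#' @param profile_id Identifier for the resulting profile.
#' @param tie_rule See [to_rank_profile()].
#' @return A [rank_profile()] with `fixed_query_cutoff = length(hits)`.
#' @export
binary_to_rank_profile <- function(hits, universe, profile_id = "binary",
                                   tie_rule = c("lexicographic",
                                                "input_order")) {
  tie_rule <- match.arg(tie_rule)
  hits <- unique(as.character(hits))
  universe <- as.character(universe)
  if (anyDuplicated(universe))
    stop("universe contains duplicate strain ids")
  if (length(hits) == 0L) stop("empty hit set")
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L)
    stop("hit strain(s) outside universe: ", paste(outside, collapse = ", "))
  non_hits <- setdiff(universe, hits)
  ordered <- c(order_by_tie_rule(hits, tie_rule),
               order_by_tie_rule(non_hits, tie_rule))
  rank_profile(profile_id, ordered, fixed_query_cutoff = length(hits))
}

#' Genetic-interaction record table
#'
#' Validates a table of tiered genetic-interaction records. Severity classes,
#' in decreasing order of growth defect, are synthetic lethality (`SL`),
#' synthetic growth defect (`SD`) and phenotypic enhancement (`PE`).
#'
#' @param query_gene,array_gene Character vectors (recycled to equal length).
#' @param severity Character vector of `"SL"`, `"SD"`, `"PE"`.
#' @param source Publication identifier(s) for each record.
#' @return A `data.frame` with class `interaction_records`.
#' @export
interaction_records <- function(query_gene, array_gene, severity,
                                source = "") {
  df <- data.frame(query_gene = as.character(query_gene),
                   array_gene = as.character(array_gene),
                   severity = as.character(severity),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  bad <- !df$severity %in% SEVERITY_LEVELS
  if (any(bad))
    stop("unknown severity class(es): ",
         paste(unique(df$severity[bad]), collapse = ", "),
         " (expected SL, SD or PE)")
  self <- df$query_gene == df$array_gene
  if (any(self))
    stop("query_gene equals array_gene for: ",
         paste(unique(df$query_gene[self]), collapse = ", "))
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Tiered rank profile from genetic-interaction records
#'
#' Builds the genetic-genetic rank profile of one query gene: array genes are
#' placed in severity blocks (all `SL` first, then `SD`, then `PE`; the more
#' severe the interaction class, the smaller the rank), ordered within each
#' block by `tie_rule`; remaining universe strains fill the deep ranks
#' lexicographically. `tier_boundaries` records the cumulative block ends so
#' the optimizer only considers cutoffs at tier ends, where the ordering is
#' meaningful.
#'
#' In `merged` mode an array gene reported with several severities (e.g. by
#' different publications) keeps its most severe class; in `individual` mode
#' conflicting duplicate records are an error.
#'
#' @param records An [interaction_records()] table for a single query gene.
#' @param universe Character vector of all strain/gene ids.
#' @param merge_mode `"merged"` or `"individual"`.
#' @param tie_rule See [to_rank_profile()].
#' @return A [rank_profile()] with `tier_boundaries` set.
#' @export
build_genetic_rank_profile <- function(records, universe,
                                       merge_mode = c("merged", "individual"),
                                       tie_rule = c("lexicographic",
                                                    "input_order")) {
  merge_mode <- match.arg(merge_mode)
  tie_rule <- match.arg(tie_rule)
  if (!inherits(records, "interaction_records"))
    records <- interaction_records(records$query_gene, records$array_gene,
                                   records$severity,
                                   records$source %||% "")
  qg <- unique(records$query_gene)
  if (length(qg) != 1L)
    stop("records span multiple query genes: ", paste(qg, collapse = ", "))
  universe <- as.character(universe)
  outside <- setdiff(records$array_gene, universe)
  if (length(outside) > 0L)
    stop("array gene(s) outside universe: ", paste(outside, collapse = ", "))

  sev <- factor(records$severity, levels = SEVERITY_LEVELS)
  if (merge_mode == "individual") {
    agg <- tapply(as.integer(sev), records$array_gene,
                  function(v) length(unique(v)))
    conflict <- names(agg)[agg > 1L]
    if (length(conflict) > 0L)
      stop("conflicting duplicate records in individual mode for query '",
           qg, "', array gene(s): ", paste(conflict, collapse = ", "))
    keep <- !duplicated(records$array_gene)
  } else {
    # most-severe class wins: SL < SD < PE as integer levels
    ord <- order(records$array_gene, as.integer(sev), method = "radix")
    keep <- ord[!duplicated(records$array_gene[ord])]
  }
  genes <- records$array_gene[keep]
  classes <- as.integer(sev)[keep]

  blocks <- lapply(seq_along(SEVERITY_LEVELS), function(lev) {
    order_by_tie_rule(genes[classes == lev], tie_rule)
  })
  tier_ends <- cumsum(vapply(blocks, length, integer(1)))
  rest <- sort(setdiff(universe, genes), method = "radix")
  ordered <- c(unlist(blocks), rest)
  boundaries <- unique(tier_ends[tier_ends > 0L])
  rank_profile(qg, ordered, tier_boundaries = boundaries,
               metadata = list(merge_mode = merge_mode))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict two rank profiles to their common strain universe
#'
#' The hypergeometric overlap model requires one shared population of size
#' `n`, so profiles over different strain sets are intersected and re-ranked
#' by relative order within each original profile (order-preserving
#' compression). A `fixed_query_cutoff` or `tier_boundaries` entry is
#' remapped to the number of retained strains at or above it; boundaries that
#' collapse to zero retained strains are dropped.
#'
#' @param qp,tp [rank_profile()] objects.
#' @return A list with elements `query` and `target`, both over exactly the
#'   strain intersection with equal `n`.
#' @export
restrict_to_common_strains <- function(qp, tp) {
  stopifnot(inherits(qp, "rank_profile"), inherits(tp, "rank_profile"))
  common <- intersect(qp$ordered_strains, tp$ordered_strains)
  if (length(common) == 0L)
    stop("profiles '", qp$profile_id, "' and '", tp$profile_id,
         "' share no strains")
  squeeze <- function(p) {
    keep <- p$ordered_strains %in% common
    remap <- function(cut) {
      if (is.null(cut)) return(NULL)
      vapply(cut, function(b) sum(keep[seq_len(b)]), integer(1))
    }
    fqc <- remap(p$fixed_query_cutoff)
    if (!is.null(fqc) && fqc == 0L)
      stop("profile '", p$profile_id,
           "': no hit strain survives restriction to the common universe")
    tb <- remap(p$tier_boundaries)
    if (!is.null(tb)) {
      tb <- unique(tb[tb > 0L])
      if (length(tb) == 0L) tb <- NULL
    }
    rank_profile(p$profile_id, p$ordered_strains[keep],
                 fixed_query_cutoff = fqc, tier_boundaries = tb,
                 metadata = p$metadata)
  }
  list(query = squeeze(qp), target = squeeze(tp))
}
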