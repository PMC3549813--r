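# Rank-cutoff optimizer core.
#
# Two rank profiles over a shared universe of n strains are compared by
# scanning all candidate cutoff pairs (i, j): the overlap m_ij between the
# top-i query strains and top-j target strains is read from the accumulated
# match matrix A (a dynamic-programming prefix-sum of the permutation match
# matrix M), and the cumulative hypergeometric tail
#   Hp(m, q, t; n) = sum_{x = m}^{min(q, t)} C(q, x) C(n-q, t-x) / C(n, t)
# is minimized over the grid. The optimum is reported with its -log10 p
# significance and the Tanimoto overlap score m / (q + t - m).

#' Match matrix of two rank profiles
#'
#' `M[i, j] = 1` iff the strain at rank `i` in the query is the strain at
#' rank `j` in the target; `M` is therefore a permutation matrix. Both
#' profiles must cover the same strain universe (use
#' [restrict_to_common_strains()] first otherwise).
#'
#' @param qp,tp [rank_profile()] objects over the same strain universe.
#' @return An `n x n` integer 0/1 matrix.
#' @export
match_matrix <- function(qp, tp) {
  stopifnot(inherits(qp, "rank_profile"), inherits(tp, "rank_profile"))
  sdiff <- c(setdiff(qp$ordered_strains, tp$ordered_strains),
             setdiff(tp$ordered_strains, qp$ordered_strains))
  if (length(sdiff) > 0L)
    stop("profiles '", qp$profile_id, "' and '", tp$profile_id,
         "' cover different universes; symmetric difference: ",
         paste(sdiff, collapse = ", "))
  n <- qp$n
  M <- matrix(0L, n, n)
  # for each strain: row = query rank, col = target rank
  j_of_strain <- seq_len(n)
  names(j_of_strain) <- tp$ordered_strains
  M[cbind(seq_len(n), j_of_strain[qp$ordered_strains])] <- 1L
  M
}

#' Accumulated match matrix
#'
#' Fills the dynamic-programming recurrence
#' `A[i, j] = M[i, j] + A[i, j-1] + A[i-1, j] - A[i-1, j-1]` (boundary rows
#' and columns zero), so that `A[i, j]` is the number of strains ranked at
#' most `i` in the query and at most `j` in the target — the overlap count
#' `m_ij` for every cutoff pair at once.
#'
#' @param M A permutation match matrix from [match_matrix()].
#' @return An `n x n` integer matrix of accumulated match counts.
#' @export
accumulate_matches <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (any(rowSums(M) != 1L) || any(colSums(M) != 1L) ||
      !all(M %in% c(0L, 1L)))
    stop("M is not a permutation matrix")
  # the Eq.-style recurrence is a 2-D prefix sum; cumsum along both axes
  A <- apply(M, 2L, cumsum)
  if (is.null(dim(A))) A <- matrix(A, 1L, 1L) # n = 1 collapses to scalar
  A <- t(apply(A, 1L, cumsum))
  storage.mode(A) <- "integer"
  A
}

#' Cumulative hypergeometric overlap tail
#'
#' The probability of observing `m` or more common strains when `q` strains
#' are drawn above the query cutoff and `t` above the target cutoff from a
#' shared population of `n`:
#' `Hp = sum_{x = m}^{min(q, t)} C(q, x) C(n-q, t-x) / C(n, t)`.
#' Computed in log space, so overlaps whose true p-value is far below the
#' smallest normal double (around 1e-308) still yield a finite `log10`
#' tail; at such extremes the linear `p` underflows to 0 and the log10 form
#' is the usable quantity.
#'
#' @param m Overlap count(s), `0 <= m <= min(q, t)`.
#' @param q,t Query and target cutoff sizes, each `<= n`.
#' @param n Shared population size.
#' @param log10p If `TRUE`, return `log10(Hp)` instead of `Hp`.
#' @return Numeric vector of tail probabilities in `(0, 1]` (or their log10).
#'   Arguments recycle as in [stats::phyper()].
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1/252 = 0.003968...
#' hypergeom_tail(250, 250, 250, 4000, log10p = TRUE)  # ~ -410, finite
#' @export
hypergeom_tail <- function(m, q, t, n, log10p = FALSE) {
  if (any(m < 0 | q < 1 | t < 1 | q > n | t > n | m > pmin(q, t)))
    stop("require 0 <= m <= min(q, t) and 1 <= q, t <= n")
  lp <- stats::phyper(m - 1, q, n - q, t, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Bonferroni correction
#'
#' `min(1, N * p)` for `N` tests; the optimizer evaluates many cutoff pairs,
#' so the minimized p-value is corrected for the size of the search grid.
#'
#' @param p Raw p-value(s) in `(0, 1]`.
#' @param N Number of tests, `>= 1`.
#' @return Corrected p-value(s), capped at 1.
#' @export
bonferroni <- function(p, N) {
  stopifnot(all(p > 0), all(p <= 1), all(N >= 1))
  pmin(1, N * p)
}

#' Tanimoto overlap coefficient
#'
#' The overlapping score `T = m / (q + t - m)`: the size of the intersection
#' of the two above-cutoff strain sets over the size of their union. `T = 1`
#' iff the two sets are identical.
#'
#' @param m Overlap count, `0 <= m <= min(q, t)`.
#' @param q,t Set sizes, `>= 1`.
#' @return Numeric in `[0, 1]`.
#' @export
tanimoto <- function(m, q, t) {
  stopifnot(all(q >= 1), all(t >= 1), all(m >= 0), all(m <= pmin(q, t)))
  m / (q + t - m)
}

#' Optimizer options
#'
#' @param k Maximal rank cutoff scanned on each axis (default `n`, as in the
#'   full-grid scan; genome-scale profiles may cap it since deep ranks are
#'   noise and the scan is O(k^2)).
#' @param fixed_i,fixed_j Pin the query (target) cutoff to one value, used
#'   for binary-origin profiles whose only meaningful cutoff is the hit
#'   count.
#' @param candidate_i,candidate_j Restrict the candidate cutoffs to a sorted
#'   integer set, used for tiered genetic profiles whose only meaningful
#'   cutoffs are tier ends.
#' @param n_tests_policy `"cutoff_pairs"` (Bonferroni `N` = number of grid
#'   cells evaluated, the per-comparison default) or `"explicit"` (use
#'   `n_tests`, e.g. for database-level correction).
#' @param n_tests Explicit `N` when `n_tests_policy = "explicit"`.
#' @return A list of class `optimizer_options`.
#' @export
optimizer_options <- function(k = NULL, fixed_i = NULL, fixed_j = NULL,
                              candidate_i = NULL, candidate_j = NULL,
                              n_tests_policy = c("cutoff_pairs", "explicit"),
                              n_tests = NULL) {
  n_tests_policy <- match.arg(n_tests_policy)
  if (n_tests_policy == "explicit" && is.null(n_tests))
    stop("n_tests required under explicit policy")
  structure(list(k = k, fixed_i = fixed_i, fixed_j = fixed_j,
                 candidate_i = candidate_i, candidate_j = candidate_j,
                 n_tests_policy = n_tests_policy, n_tests = n_tests),
            class = "optimizer_options")
}

candidate_axis <- function(fixed, candidates, k) {
  if (!is.null(fixed)) {
    fixed <- as.integer(fixed)
    if (fixed < 1L || fixed > k)
      stop("fixed cutoff ", fixed, " outside 1..k (k = ", k, ")")
    return(fixed)
  }
  if (!is.null(candidates)) {
    candidates <- sort(unique(as.integer(candidates)))
    if (any(candidates < 1L) || any(candidates > k))
      stop("candidate cutoffs outside 1..k (k = ", k, ")")
    return(candidates)
  }
  seq_len(k)
}

#' Find the rank-cutoff pair minimizing the hypergeometric overlap p-value
#'
#' Evaluates the cumulative hypergeometric tail `Hp(A[i, j], i, j; n)` over
#' every candidate cutoff pair and returns the minimizing pair `(i*, j*)`.
#' Ties on p are broken toward the smallest `i + j`, then the smallest `i`
#' (the most parsimonious strain sets). The whole grid is evaluated in one
#' vectorized log-space pass, so a full `k = n = 1000` scan takes well under
#' a second.
#'
#' @param A Accumulated match matrix from [accumulate_matches()].
#' @param opts An [optimizer_options()] object.
#' @return An `overlap_result`: list with `i_star`, `j_star`, `m`, `q`, `t`,
#'   `n`, `p_value`, `log10_p`, `p_bonferroni`, `n_tests`, `significance`
#'   (`-log10 p`), `tanimoto`, and `no_signal` (`TRUE` when no cutoff pair
#'   shows any informative overlap, i.e. the minimum is p = 1).
#' @export
optimize_cutoffs <- function(A, opts = optimizer_options()) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  k <- as.integer(opts$k %||% n)
  if (k < 1L || k > n) stop("k must lie in 1..n (n = ", n, ")")
  is_cand <- candidate_axis(opts$fixed_i, opts$candidate_i, k)
  js_cand <- candidate_axis(opts$fixed_j, opts$candidate_j, k)
  if (length(is_cand) == 0L || length(js_cand) == 0L)
    stop("empty candidate cutoff grid")

  grid_i <- rep(is_cand, times = length(js_cand))
  grid_j <- rep(js_cand, each = length(is_cand))
  m <- A[cbind(grid_i, grid_j)]
  log10_p <- hypergeom_tail(m, grid_i, grid_j, n, log10p = TRUE)

  # argmin with deterministic tie-break: smallest i + j, then smallest i.
  # Ties are analytic equalities (e.g. transposed cells with equal overlap),
  # so they are detected with a small absolute tolerance on log10 p rather
  # than exact double equality.
  best_p <- min(log10_p)
  at_min <- which(log10_p <= best_p + 1e-9)
  at_min <- at_min[order(grid_i[at_min] + grid_j[at_min], grid_i[at_min])]
  best <- at_min[1L]

  i_star <- grid_i[best]; j_star <- grid_j[best]; m_star <- m[best]
  N <- if (opts$n_tests_policy == "explicit") as.integer(opts$n_tests)
       else length(log10_p)
  log10_p_star <- log10_p[best]
  p_star <- exp(log10_p_star * log(10))
  p_bonf <- min(1, exp(log10_p_star * log(10) + log(N)))
  structure(
    list(i_star = i_star, j_star = j_star, m = m_star,
         q = i_star, t = j_star, n = n,
         p_value = p_star, log10_p = log10_p_star,
         p_bonferroni = p_bonf, n_tests = N,
         significance = -log10_p_star,
         tanimoto = tanimoto(m_star, i_star, j_star),
         no_signal = log10_p_star >= 0),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result>\n",
      "  optimal cutoffs (i*, j*): (", x$i_star, ", ", x$j_star, ")\n",
      "  overlap m = ", x$m, " of n = ", x$n, "\n",
      "  p-value: ", format_p(x$p_value, x$log10_p),
      "  (Bonferroni x", x$n_tests, ": ",
      format_p(x$p_bonferroni, NULL), ")\n",
      "  significance (-log10 p): ", sprintf("%.4f", x$significance), "\n",
      "  Tanimoto score: ", sprintf("%.4f", x$tanimoto), "\n", sep = "")
  if (x$no_signal) cat("  [no_signal: no informative overlap]\n")
  invisible(x)
}

format_p <- function(p, log10_p) {
  if (!is.null(log10_p) && p == 0)
    sprintf("1e%+.0f", log10_p) # deep underflow: show magnitude from log form
  else
    sprintf("%.3g", p)
}

#' Compare two rank profiles end to end
#'
#' The full pipeline: restrict both profiles to their common strain universe,
#' build the match and accumulated match matrices, and scan cutoff pairs for
#' the minimal overlap p-value. A profile's `fixed_query_cutoff` pins its
#' cutoff; `tier_boundaries` restrict its candidate cutoffs to tier ends.
#' Explicit `opts` entries override profile-derived ones.
#'
#' @param qp,tp [rank_profile()] objects (universes may differ).
#' @param opts An [optimizer_options()] object.
#' @return An `overlap_result` (see [optimize_cutoffs()]) with attributes
#'   `query_id` and `target_id`.
#' @examples
#' toy <- toy_overlap_pair()
#' compare_profiles(toy$query, toy$target)
#' @export
compare_profiles <- function(qp, tp, opts = optimizer_options()) {
  pair <- restrict_to_common_strains(qp, tp)
  qp <- pair$query; tp <- pair$target
  k <- as.integer(opts$k %||% qp$n)
  k <- min(k, qp$n)
  clip <- function(v) if (is.null(v)) NULL else pmin(as.integer(v), k)
  opts2 <- optimizer_options(
    k = k,
    fixed_i = opts$fixed_i %||% clip(qp$fixed_query_cutoff),
    fixed_j = opts$fixed_j %||% clip(tp$fixed_query_cutoff),
    candidate_i = opts$candidate_i %||% clip(qp$tier_boundaries),
    candidate_j = opts$candidate_j %||% clip(tp$tier_boundaries),
    n_tests_policy = opts$n_tests_policy, n_tests = opts$n_tests)
  A <- accumulate_matches(match_matrix(qp, tp))
  res <- optimize_cutoffs(A, opts2)
  attr(res, "query_id") <- qp$profile_id
  attr(res, "target_id") <- tp$profile_id
  res
}

#' Serialize an overlap result as a TSV row
#'
#' Columns: query_id, target_id, i_star, j_star, m, n, p_value,
#' p_bonferroni, significance, tanimoto, flags. Float formatting is fixed
#' (p in scientific notation with 3 significant digits plus a 3-d.p. rounded
#' column; significance and Tanimoto to 4 d.p.) so output is byte-stable.
#'
#' @param res An `overlap_result` from [compare_profiles()].
#' @param query_id,target_id Identifiers (defaults from the result's
#'   attributes).
#' @param header If `TRUE`, prepend the header line.
#' @return Character vector of TSV line(s).
#' @export
overlap_result_tsv <- function(res, query_id = NULL, target_id = NULL,
                               header = FALSE) {
  stopifnot(inherits(res, "overlap_result"))
  query_id <- query_id %||% attr(res, "query_id") %||% "query"
  target_id <- target_id %||% attr(res, "target_id") %||% "target"
  row <- paste(query_id, target_id, res$i_star, res$j_star, res$m, res$n,
               sprintf("%.3e", res$p_value), sprintf("%.3f", res$p_value),
               sprintf("%.3e", res$p_bonferroni),
               sprintf("%.4f", res$significance),
               sprintf("%.4f", res$tanimoto),
               if (res$no_signal) "no_signal" else ".",
               sep = "\t")
  if (header) c(overlap_tsv_header(), row) else row
}

overlap_tsv_header <- function() {
  paste("query_id", "target_id", "i_star", "j_star", "m", "n",
        "p_value", "p_value_3dp", "p_bonferroni", "significance",
        "tanimoto", "flags", sep = "\t")
}
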