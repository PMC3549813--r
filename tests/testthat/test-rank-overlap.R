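test_that("match matrix pairs equal strains across the two rank axes", {
  p <- rank_profile("p", letters[1:6])
  expect_equal(match_matrix(p, p), diag(6), ignore_attr = TRUE)

  rev_p <- rank_profile("r", rev(letters[1:6]))
  anti <- matrix(0L, 6, 6)
  anti[cbind(1:6, 6:1)] <- 1L
  expect_equal(match_matrix(p, rev_p), anti)

  set.seed(8)
  q <- random_rank_profile(8, "q")
  t <- rank_profile("t", sample(q$ordered_strains))
  M <- match_matrix(q, t)
  expect_true(all(rowSums(M) == 1) && all(colSums(M) == 1))

  expect_error(match_matrix(p, rank_profile("x", letters[2:7])),
               "symmetric difference")
})

test_that("accumulated matrix satisfies the prefix-sum recurrence", {
  # identity permutation: closed form A[i, j] = min(i, j)
  for (n in c(1, 4, 9)) {
    p <- rank_profile("p", sprintf("s%02d", 1:n))
    A <- accumulate_matches(match_matrix(p, p))
    expect_equal(A, outer(1:n, 1:n, pmin), ignore_attr = TRUE)
  }

  # anti-diagonal at n = 4: brute-force count over all 16 cells
  p4 <- rank_profile("p", letters[1:4])
  r4 <- rank_profile("r", letters[4:1])
  A <- accumulate_matches(match_matrix(p4, r4))
  brute <- outer(1:4, 1:4, function(i, j) {
    mapply(function(ii, jj) length(intersect(letters[seq_len(ii)],
                                             letters[4:1][seq_len(jj)])),
           i, j)
  })
  expect_equal(A, brute, ignore_attr = TRUE)
  expect_equal(A, outer(1:4, 1:4, function(i, j) pmax(0, i + j - 4)),
               ignore_attr = TRUE)

  # the recurrence itself, checked cell by cell on a random permutation
  set.seed(21)
  q <- random_rank_profile(12, "q")
  t <- rank_profile("t", sample(q$ordered_strains))
  M <- match_matrix(q, t)
  A <- accumulate_matches(M)
  Ap <- rbind(0L, cbind(0L, A)) # padded with the zero boundary
  for (i in 1:12) for (j in 1:12)
    expect_equal(A[i, j],
                 M[i, j] + Ap[i + 1, j] + Ap[i, j + 1] - Ap[i, j])
  expect_equal(A[12, 12], 12L)

  expect_error(accumulate_matches(matrix(1L, 2, 2)), "permutation")
})

test_that("hypergeometric tail matches direct summation and known values", {
  expect_equal(hypergeom_tail(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(round(hypergeom_tail(5, 5, 5, 10), 3), 0.004)
  expect_equal(hypergeom_tail(0, 3, 4, 10), 1.0)
  expect_equal(hypergeom_tail(1, 1, 1, 10), 0.1, tolerance = 1e-12)
  expect_equal(hypergeom_tail(2, 4, 3, 10), oracle_tail(2, 4, 3, 10),
               tolerance = 1e-12)

  # random configurations against the log-gamma summation oracle
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    q <- sample(n, 1); t <- sample(n, 1)
    m <- sample(0:min(q, t), 1)
    expect_equal(hypergeom_tail(m, q, t, n), oracle_tail(m, q, t, n),
                 tolerance = 1e-11)
  }

  expect_error(hypergeom_tail(6, 5, 5, 10), "m <= min")
  expect_error(hypergeom_tail(1, 11, 5, 10), "<= n")
})

test_that("tail is strictly decreasing in the overlap count", {
  for (cfg in list(c(5, 7, 20), c(3, 3, 8), c(40, 60, 200))) {
    q <- cfg[1]; t <- cfg[2]; n <- cfg[3]
    tails <- hypergeom_tail(0:min(q, t), q, t, n, log10p = TRUE)
    expect_true(all(diff(tails) < 0))
  }
})

test_that("extreme overlaps keep a finite log10 tail far below 1e-300", {
  lp <- hypergeom_tail(250, 250, 250, 4000, log10p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -300)
  expect_equal(lp, oracle_tail_log10(250, 250, 250, 4000),
               tolerance = 1e-9)
})

test_that("bonferroni scales and caps", {
  expect_equal(bonferroni(0.004, 1), 0.004)
  expect_equal(bonferroni(0.004, 100), 0.4)
  expect_equal(bonferroni(0.5, 10), 1.0)
})

test_that("tanimoto is intersection over union", {
  expect_equal(tanimoto(5, 5, 5), 1.0)
  expect_equal(tanimoto(0, 4, 7), 0.0)
  expect_equal(tanimoto(2, 4, 3), 0.4)
  expect_error(tanimoto(5, 4, 3), "m <= ")
})

test_that("the optimizer reproduces the canonical toy optimum", {
  toy <- toy_overlap_pair()
  res <- compare_profiles(toy$query, toy$target,
                          optimizer_options(k = 10))
  expect_equal(res$i_star, 5L)
  expect_equal(res$j_star, 5L)
  expect_equal(res$m, 5L)
  expect_equal(round(res$p_value, 3), 0.004)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-10)
  expect_equal(res$tanimoto, 1.0)
  expect_equal(res$n_tests, 100L)
  expect_equal(res$significance, -log10(1 / 252), tolerance = 1e-9)
})

test_that("identical profiles minimize at the sharpest binomial cutoff", {
  # identical top sets: p at (i, i) is 1/C(10, i); min over the grid
  p <- rank_profile("p", letters[1:10])
  res <- compare_profiles(p, rank_profile("copy", letters[1:10]))
  o <- oracle_compare(letters[1:10], letters[1:10])
  expect_equal(res$i_star, o$i)
  expect_equal(res$j_star, o$j)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-10)
  expect_equal(res$tanimoto, 1.0)
})

test_that("DP optimum equals the set-theoretic oracle on random pairs", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    perm_q <- sample.int(n); perm_t <- sample.int(n)
    qp <- rank_profile_from_perm(perm_q, "q")
    tp <- rank_profile_from_perm(perm_t, "t")
    res <- compare_profiles(qp, tp)
    o <- oracle_compare(qp$ordered_strains, tp$ordered_strains)
    expect_equal(res$i_star, o$i)
    expect_equal(res$j_star, o$j)
    expect_equal(res$m, o$m)
    expect_equal(res$log10_p, o$lp, tolerance = 1e-9)
  }
})

test_that("cutoff ties break toward the most parsimonious strain sets", {
  # reversed 2-strain profiles: every cell has p = 1, a four-way tie that
  # must resolve to the smallest (i + j), i.e. (1, 1), flagged no_signal
  res <- compare_profiles(rank_profile("p", c("a", "b")),
                          rank_profile("r", c("b", "a")))
  expect_equal(c(res$i_star, res$j_star), c(1L, 1L))
  expect_true(res$no_signal)

  # identical 2-strain profiles: unique minimum 1/2 at (1, 1)
  res2 <- compare_profiles(rank_profile("p", c("a", "b")),
                           rank_profile("c", c("a", "b")))
  expect_equal(c(res2$i_star, res2$j_star), c(1L, 1L))
  expect_equal(res2$p_value, 0.5)
})

test_that("pipeline is symmetric in query and target up to cutoff swap", {
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(3:25, 1)
    qp <- random_rank_profile(n, "q")
    tp <- rank_profile("t", sample(qp$ordered_strains))
    ab <- compare_profiles(qp, tp)
    ba <- compare_profiles(tp, qp)
    expect_equal(ab$log10_p, ba$log10_p, tolerance = 1e-9)
    expect_equal(ab$tanimoto, ba$tanimoto)
    expect_equal(ab$m, ba$m)
    # cutoffs swap as an unordered pair: when a cell ties with its mirror
    # the deterministic tie rule (smallest i + j, then smallest i) picks the
    # same oriented cell in both directions
    expect_equal(sort(c(ab$i_star, ab$j_star)),
                 sort(c(ba$i_star, ba$j_star)))
  }
})

test_that("results are invariant under strain relabeling", {
  set.seed(14)
  qp <- random_rank_profile(20, "q")
  tp <- rank_profile("t", sample(qp$ordered_strains))
  base <- compare_profiles(qp, tp)
  relabel <- stats::setNames(sprintf("NEW%02d", sample.int(20)),
                             qp$ordered_strains)
  res <- compare_profiles(
    rank_profile("q2", unname(relabel[qp$ordered_strains])),
    rank_profile("t2", unname(relabel[tp$ordered_strains])))
  expect_equal(res$i_star, base$i_star)
  expect_equal(res$j_star, base$j_star)
  expect_equal(res$log10_p, base$log10_p)
})

test_that("fixed and tiered cutoffs restrict the candidate grid", {
  set.seed(15)
  universe <- sprintf("s%02d", 1:30)
  bq <- binary_to_rank_profile(sample(universe, 6), universe)
  tp <- rank_profile("t", sample(universe))
  res <- compare_profiles(bq, tp)
  expect_equal(res$i_star, 6L)       # pinned at the hit count
  expect_equal(res$n_tests, 30L)     # 1 x k grid evaluated

  gq <- rank_profile("g", sample(universe), tier_boundaries = c(4L, 9L))
  res2 <- compare_profiles(gq, tp)
  expect_true(res2$i_star %in% c(4L, 9L))
  expect_equal(res2$n_tests, 2L * 30L)

  # a binary target pins j the same way the query side is pinned
  res3 <- compare_profiles(tp, bq)
  expect_equal(res3$j_star, 6L)
  expect_equal(res3$log10_p, res$log10_p, tolerance = 1e-12)
})

test_that("degenerate no-overlap comparisons flag no_signal instead of failing", {
  # n = 1: the only cell is (1,1) with m = 1 and p = 1
  one <- rank_profile("solo", "a")
  res <- compare_profiles(one, rank_profile("solo2", "a"))
  expect_equal(res$p_value, 1.0)
  expect_equal(res$significance, 0.0)
  expect_true(res$no_signal)
  expect_equal(res$tanimoto, 1.0)  # as computed: m = q = t = 1
})

test_that("explicit n_tests policy drives the Bonferroni column", {
  toy <- toy_overlap_pair()
  res <- compare_profiles(toy$query, toy$target,
                          optimizer_options(n_tests_policy = "explicit",
                                            n_tests = 5000L))
  expect_equal(res$n_tests, 5000L)
  expect_equal(res$p_bonferroni, min(1, 5000 * res$p_value),
               tolerance = 1e-9)
})

test_that("TSV serialization of a result is byte-stable and formatted", {
  toy <- toy_overlap_pair()
  res <- compare_profiles(toy$query, toy$target)
  row1 <- overlap_result_tsv(res)
  row2 <- overlap_result_tsv(res)
  expect_identical(row1, row2)
  fields <- strsplit(row1, "\t")[[1]]
  expect_equal(fields[1:2], c("toy_query", "toy_target"))
  expect_equal(fields[8], "0.004")           # 3-d.p. rounded column
  expect_match(fields[7], "^3\\.968e-03$")   # scientific, 3 sig digits
  expect_match(fields[10], "^2\\.4014$")     # significance, 4 d.p.
  expect_match(fields[11], "^1\\.0000$")     # tanimoto, 4 d.p.
})
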