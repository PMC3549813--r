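# Independent oracles used to cross-check the optimizer pipeline. These
# deliberately share no code with the package internals: the tail is a
# direct log-gamma summation of the hypergeometric mass, and the cutoff
# search recounts overlaps set-theoretically for every cutoff pair.

# log10 of sum_{x=m}^{min(q,t)} C(q,x) C(n-q,t-x) / C(n,t), via logsumexp
oracle_tail_log10 <- function(m, q, t, n) {
  xs <- m:min(q, t)
  terms <- lchoose(q, xs) + lchoose(n - q, t - xs) - lchoose(n, t)
  mx <- max(terms)
  (mx + log(sum(exp(terms - mx)))) / log(10)
}

oracle_tail <- function(m, q, t, n) 10^oracle_tail_log10(m, q, t, n)

# Exhaustive set-theoretic cutoff search with the same deterministic
# tie rule (smallest i + j, then smallest i; analytic ties detected with
# a small tolerance on log10 p).
oracle_compare <- function(q_order, t_order, k = NULL) {
  n <- length(q_order)
  k <- if (is.null(k)) n else k
  is <- rep(seq_len(k), times = k)
  js <- rep(seq_len(k), each = k)
  m <- integer(k * k)
  lp <- numeric(k * k)
  idx <- 1L
  for (j in seq_len(k)) {
    t_top <- t_order[seq_len(j)]
    for (i in seq_len(k)) {
      m[idx] <- length(intersect(q_order[seq_len(i)], t_top))
      lp[idx] <- oracle_tail_log10(m[idx], i, j, n)
      idx <- idx + 1L
    }
  }
  cand <- which(lp <= min(lp) + 1e-9)
  cand <- cand[order(is[cand] + js[cand], is[cand])]
  b <- cand[[1L]]
  list(i = is[b], j = js[b], m = m[b], lp = lp[b])
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

rank_profile_from_perm <- function(perm, id = "p") {
  rank_profile(id, sprintf("s%02d", perm))
}

random_rank_profile <- function(n, id = "p") {
  rank_profile(id, sprintf("s%04d", sample.int(n)))
}
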