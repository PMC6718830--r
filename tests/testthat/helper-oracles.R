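# Independent brute-force oracles and small fixture builders. These stay
# deliberately separate from the package implementations they check.

# Scalar truth-table transcription of the pathotype criteria, evaluated
# rule by rule with explicit precedence.
oracle_classify_one <- function(cd3, cd20, cd68l, cd68sl, cd138, agg) {
  if ((agg %in% c(2L, 3L) && cd20 >= 2L) || cd138 >= 3L) return("lymphoid")
  if (cd68sl >= 2L && cd138 <= 2L && (cd20 <= 1L || cd3 >= 1L))
    return("myeloid")
  if (cd68sl <= 1L && cd3 == 0L && cd20 == 0L && cd138 == 0L)
    return("fibroid")
  "ungraded"
}

# Step-up BH computed from the order statistics definition
# q_(i) = min_{j >= i} min(1, n p_(j) / j).
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(pmin(1, n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Upper-tail hypergeometric P(X >= k) as an explicit sum of choose terms
# on the log scale.
oracle_hyper_upper <- function(k, n_success, n_total, n_draw) {
  lo <- max(k, 0)
  hi <- min(n_success, n_draw)
  if (lo > hi) return(0)
  terms <- vapply(lo:hi, function(x)
    exp(lchoose(n_success, x) + lchoose(n_total - n_success, n_draw - x) -
        lchoose(n_total, n_draw)), numeric(1))
  sum(terms)
}

# Two-sided Fisher exact p by enumerating the hypergeometric support and
# summing tables no more probable than the observed one.
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force per-gene filter for module derivation on a small Z atlas.
oracle_derive <- function(z, tissue, z_min, rank_max, spec_max, z_spec,
                          excluded = character(0)) {
  hits <- character(0)
  for (g in rownames(z)) {
    if (g %in% excluded) next
    row <- z[g, ]
    rk <- sum(row > row[tissue]) +
      sum(row == row[tissue] & seq_along(row) < which(names(row) == tissue)) + 1
    spec <- sum(row > z_spec)
    if (rk <= rank_max && row[tissue] > z_min && spec < spec_max)
      hits <- c(hits, g)
  }
  hits[order(-z[hits, tissue])]
}

# Small deterministic fixtures.
small_counts <- function(n_genes = 60, n_samples = 12, seed = 42,
                         mu = 50, disp = 0.1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / disp),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("S%02d", 1:n_samples)))
  m
}

histology_row <- function(CD3 = 0, CD20 = 0, CD68L = 0, CD68SL = 0,
                          CD138 = 0, agg = 0, id = "S1") {
  data.frame(sample_id = id, CD3 = CD3, CD20 = CD20, CD68L = CD68L,
             CD68SL = CD68SL, CD138 = CD138, cd20_aggregate_grade = agg,
             stringsAsFactors = FALSE)
}
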