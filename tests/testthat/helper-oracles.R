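# Independent oracles used by unit and acceptance tests. Each implements
# the defining formula directly, on a different code path from the
# package implementation it checks.

# Maximum-weight linear forest by exhaustive search over edge subsets.
brute_force_linear_forest <- function(nodes, edges) {
  m <- nrow(edges)
  if (!m) return(0)
  best <- 0
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0L)
    if (!length(sel)) next
    deg <- table(c(edges$hog_u[sel], edges$hog_v[sel]))
    if (any(deg > 2)) next
    uf <- seq_along(nodes)
    names(uf) <- nodes
    find <- function(i) {
      while (uf[[i]] != i) i <- uf[[i]]
      i
    }
    acyclic <- TRUE
    for (e in sel) {
      a <- find(edges$hog_u[e]); b <- find(edges$hog_v[e])
      if (a == b) { acyclic <- FALSE; break }
      uf[[a]] <- b
    }
    if (!acyclic) next
    w <- sum(edges$weight[sel])
    if (w > best) best <- w
  }
  best
}

# Benjamini-Hochberg by its step-up definition:
# adj_(i) = min_{j >= i} min(1, p_(j) * m / j), in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in i:m) {
      cand <- min(1, ps[j] * m / j)
      if (cand < best) best <- cand
    }
    adj[i] <- best
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by direct summation of the pmf definition.
hyper_tail_oracle <- function(x, n, K, N) {
  ks <- x:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# simRel by exhaustive enumeration of the common-ancestor set.
simrel_oracle <- function(t1, t2, stats, ontology) {
  anc <- function(t) c(t, ontology$ancestors[[t]])
  common <- intersect(anc(t1), anc(t2))
  denom <- log(stats[t1, "probability"]) + log(stats[t2, "probability"])
  if (denom == 0) return(0)
  vals <- vapply(common, function(a) {
    pa <- stats[a, "probability"]
    if (is.na(pa) || pa >= 1) return(0)
    2 * log(pa) / denom * (1 - pa)
  }, numeric(1))
  max(0, vals)
}

# unordered breakpoint distance between two orderings of the same genes
breakpoint_distance <- function(ref, other) {
  pair_set <- function(v) {
    if (length(v) < 2) return(character(0))
    a <- v[-length(v)]; b <- v[-1]
    paste(pmin(a, b), pmax(a, b))
  }
  length(setdiff(pair_set(ref), unlist(lapply(other, pair_set))))
}
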