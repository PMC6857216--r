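# Fixture builders and the independent betweenness oracle.

# A minimal valid actor record; override fields by name.
fix_actor <- function(actor_id, ...) {
  rec <- list(actor_id = actor_id, age_group = ">=30",
              marital_status = "married", education = "tertiary",
              occupation = "informal", ethnicity = "Hausa",
              marriage_type = "monogamy", fp_use = "yes",
              cbdic_use = "yes")
  over <- list(...)
  rec[names(over)] <- over
  rec
}

# Network on actors v1 (ego), v2..vn from an unordered edge index matrix
# (2-column, indices into 1..n). `actor_overrides` is a named list of
# per-attribute vectors of length n.
fix_network <- function(n, edges = NULL, label = "FIX", site = "A",
                        actor_overrides = list()) {
  ids <- paste0("v", seq_len(n))
  recs <- lapply(seq_len(n), function(i) {
    over <- lapply(actor_overrides, function(v) v[i])
    do.call(fix_actor, c(list(actor_id = ids[i]), over))
  })
  actors <- do.call(rbind, lapply(recs, as.data.frame,
                                  stringsAsFactors = FALSE))
  ties <- if (is.null(edges) || NROW(edges) == 0) NULL else {
    data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
               stringsAsFactors = FALSE)
  }
  build_network(label, site, actors[1, ], actors[-1, , drop = FALSE],
                ties)
}

all_pairs <- function(n) t(utils::combn(n, 2))

fix_complete <- function(n, ...) fix_network(n, all_pairs(n), ...)

fix_star <- function(n, ...) {
  fix_network(n, cbind(1L, 2:n), ...)
}

fix_path <- function(n, ...) {
  fix_network(n, cbind(seq_len(n - 1), 2:n), ...)
}

# Erdos-Renyi edge index matrix on n nodes with tie probability p,
# drawn from the current RNG state.
random_edges <- function(n, p) {
  pairs <- all_pairs(n)
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

# Independent betweenness oracle: geodesic counting via adjacency-matrix
# powers. The number of s-t walks of length k is (A^k)[s, t]; the
# shortest-path length d(s, t) is the smallest k with a positive entry,
# and every walk of that minimal length is a geodesic, so
# sigma_st = (A^d)[s, t] and sigma_st(v) = (A^d1)[s, v] * (A^d2)[v, t]
# whenever d(s, v) + d(v, t) = d(s, t). Shares no code with the Brandes
# implementation under test.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  powers <- vector("list", n)
  powers[[1]] <- A
  if (n >= 2) for (k in 2:n) powers[[k]] <- powers[[k - 1]] %*% A
  dist <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) { dist[s, t] <- 0; cnt[s, t] <- 1; next }
      for (k in seq_len(n)) {
        if (powers[[k]][s, t] > 0) {
          dist[s, t] <- k
          cnt[s, t] <- powers[[k]][s, t]
          break
        }
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || !is.finite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          bc[v] <- bc[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
        }
      }
    }
  }
  bc
}

edges_to_adjacency <- function(n, edges) {
  A <- matrix(0, n, n)
  if (NROW(edges) > 0) {
    A[edges] <- 1
    A[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}
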