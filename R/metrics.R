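#' Network density
#'
#' The number of ties present as a proportion of possible ties. Under the
#' directed-symmetric counting convention an 11-actor network has 110
#' possible ties, so density is `directed_tie_count / (n * (n - 1))`,
#' identical to the unordered count over `n * (n - 1) / 2`.
#'
#' @param network an `ego_network`.
#' @return density in `[0, 1]` at full precision (render with
#'   [round_half_up()] for report tables).
#' @export
net_density <- function(network) {
  n <- n_actors(network)
  if (n < 2) stop("density needs at least 2 actors")
  directed_tie_count(network) / (n * (n - 1))
}

#' Degree centrality of one actor
#'
#' The number of distinct actors an actor is tied to.
#'
#' @param network an `ego_network`.
#' @param actor actor id.
#' @return integer degree.
#' @export
actor_degree <- function(network, actor) {
  if (!actor %in% network$actors$actor_id) {
    stop("unknown actor '", actor, "'")
  }
  sum(network$ties$from == actor | network$ties$to == actor)
}

#' Degree of every actor
#' @param network an `ego_network`.
#' @return named integer vector in roster order.
#' @export
degree_vector <- function(network) {
  ids <- network$actors$actor_id
  d <- integer(length(ids))
  names(d) <- ids
  if (nrow(network$ties) > 0) {
    tab <- table(c(network$ties$from, network$ties$to))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Average degree centrality
#'
#' Mean directed ties per actor, `directed_tie_count / n`; the quantity
#' survey reports print as "average degree centrality".
#'
#' @param network an `ego_network`.
#' @return numeric mean degree.
#' @export
average_degree <- function(network) {
  n <- n_actors(network)
  if (n < 1) stop("empty network")
  directed_tie_count(network) / n
}

#' Raw betweenness centrality (Brandes' algorithm)
#'
#' For each actor v, the sum over unordered pairs `{s, t}` (s, t != v) of
#' the fraction of shortest s-t paths that pass through v. Geodesics are
#' taken on the undirected binary graph; pairs with no connecting path
#' contribute nothing. Computed with Brandes' dependency-accumulation
#' algorithm (one BFS per source, O(n * m) for unweighted graphs); since
#' each unordered pair is seen from both endpoints, the accumulated total
#' is halved.
#'
#' @param network an `ego_network`.
#' @return named numeric vector of betweenness values in roster order.
#' @export
betweenness_raw <- function(network) {
  ids <- network$actors$actor_id
  n <- length(ids)
  adj <- vector("list", n)
  if (nrow(network$ties) > 0) {
    i <- match(network$ties$from, ids)
    j <- match(network$ties$to, ids)
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k])
      adj[[j[k]]] <- c(adj[[j[k]]], i[k])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    visited <- integer(0)
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      visited <- c(visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  names(bc) <- ids
  bc / 2
}

#' Normalized betweenness centrality (nBetweenness)
#'
#' Raw betweenness as a percentage of its maximum `(n - 1) * (n - 2) / 2`
#' (attained by the centre of a star), the "nBetweenness" scaling of
#' classic SNA software.
#'
#' @param network an `ego_network` with at least 3 actors.
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
betweenness_normalized <- function(network) {
  n <- n_actors(network)
  if (n < 3) stop("normalized betweenness needs at least 3 actors")
  betweenness_raw(network) / ((n - 1) * (n - 2) / 2) * 100
}

#' Freeman degree centralization
#'
#' How concentrated degree is on a single actor:
#' `sum(max(deg) - deg) / ((n - 1) * (n - 2)) * 100` on undirected
#' degrees. 0 for any regular graph (including complete graphs), 100 for
#' a star.
#'
#' @param network an `ego_network` with at least 3 actors.
#' @return percentage in `[0, 100]`.
#' @export
degree_centralization <- function(network) {
  n <- n_actors(network)
  if (n < 3) stop("degree centralization needs at least 3 actors")
  d <- degree_vector(network)
  sum(max(d) - d) / ((n - 1) * (n - 2)) * 100
}

#' Group-level E-I homophily index
#'
#' For one group of a binary partition of the actors, counts the ties
#' internal to the group (both endpoints inside, `I`) and external to it
#' (exactly one endpoint inside, `E`) and returns
#' `(E - I) / (E + I)`: -1 when every tie stays inside the group
#' (perfect homophily), +1 when every tie crosses the boundary. Ties with
#' an endpoint whose attribute value is missing are excluded from both
#' counts, which keeps the index inside `[-1, 1]` under missingness. The
#' index is undefined (`NA`, rendered as an en dash in report tables)
#' when the group is empty or has no counted ties.
#'
#' @param network an `ego_network`.
#' @param attribute attribute name (recoded to binary via the scheme).
#' @param group which group of the binary partition; defaults to the
#'   first group of the recoding.
#' @param scheme the [attribute_scheme()].
#' @return data frame row with `attribute`, `group`, `external`,
#'   `internal`, `ei_index`.
#' @export
group_ei_index <- function(network, attribute, group = NULL,
                           scheme = default_scheme()) {
  part <- recode_attribute(network, attribute, scheme)
  if (is.null(group)) group <- names(part$groups)[1]
  if (!group %in% names(part$groups)) {
    stop("unknown group '", group, "' for attribute '", attribute, "'")
  }
  members <- part$groups[[group]]
  res <- data.frame(attribute = attribute, group = group,
                    external = NA_integer_, internal = NA_integer_,
                    ei_index = NA_real_, stringsAsFactors = FALSE)
  if (length(members) == 0) return(res)

  keep <- !(network$ties$from %in% part$na) &
    !(network$ties$to %in% part$na)
  ties <- network$ties[keep, , drop = FALSE]
  in_from <- ties$from %in% members
  in_to <- ties$to %in% members
  internal <- sum(in_from & in_to)
  external <- sum(xor(in_from, in_to))
  res$external <- external
  res$internal <- internal
  if (external + internal > 0) {
    res$ei_index <- (external - internal) / (external + internal)
  }
  res
}

#' E-I indices for both groups of several attributes
#'
#' @param network an `ego_network`.
#' @param attributes attribute names; default covers the four homophily
#'   dimensions a diffusion survey reports (ethnicity, age group,
#'   education, marriage type).
#' @param scheme the [attribute_scheme()].
#' @return data frame, one row per attribute x group.
#' @export
ei_table <- function(network,
                     attributes = c("ethnicity", "age_group",
                                    "education", "marriage_type"),
                     scheme = default_scheme()) {
  rows <- lapply(attributes, function(at) {
    groups <- binary_groups(scheme, at)
    do.call(rbind, lapply(groups, function(g) {
      group_ei_index(network, at, g, scheme)
    }))
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(network_label = network$label,
                   stringsAsFactors = FALSE), out)
}

#' Actor-level homophily classification
#'
#' An actor is classified homophilic on an attribute when a strict
#' majority of her counted ties connect her to actors of her own
#' (recoded) category, i.e. her actor-level E - I is below `threshold`
#' (default 0). Ties to actors with a missing value are not counted.
#' Returns `NA` for actors with a missing value or no counted ties.
#'
#' The exact rule behind published homophily-source tables is rarely
#' stated; the strict-majority default is this package's declared
#' interpretation, and `threshold` makes it tunable.
#'
#' @param network an `ego_network`.
#' @param actor actor id.
#' @param attribute attribute name.
#' @param scheme the [attribute_scheme()].
#' @param threshold classify homophilic when `E - I < threshold`.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
actor_homophily <- function(network, actor, attribute,
                            scheme = default_scheme(), threshold = 0) {
  if (!actor %in% network$actors$actor_id) {
    stop("unknown actor '", actor, "'")
  }
  part <- recode_attribute(network, attribute, scheme)
  if (actor %in% part$na) return(NA)
  own <- names(part$groups)[vapply(part$groups, function(g) actor %in% g,
                                   logical(1))]
  nbrs <- c(network$ties$to[network$ties$from == actor],
            network$ties$from[network$ties$to == actor])
  nbrs <- setdiff(nbrs, part$na)
  if (length(nbrs) == 0) return(NA)
  internal <- sum(nbrs %in% part$groups[[own]])
  external <- length(nbrs) - internal
  (external - internal) < threshold
}

#' Homophily-source summary across a study
#'
#' Counts and percentages of homophilic egos, alters and actors overall
#' for one attribute, on the role denominators of the whole roster
#' (20 egos / 200 alters / 220 total at the default design). Actors whose
#' classification is `NA` count in the denominator but not the numerator,
#' matching fixed-denominator survey tables.
#'
#' @param collection a `study_collection`.
#' @param attribute attribute name.
#' @param threshold passed to [actor_homophily()].
#' @return data frame row with ego/alter/total counts and percentages.
#' @export
homophily_summary <- function(collection, attribute, threshold = 0) {
  ego_n <- 0L; ego_h <- 0L; alt_n <- 0L; alt_h <- 0L
  for (nw in collection$networks) {
    for (i in seq_len(nrow(nw$actors))) {
      h <- actor_homophily(nw, nw$actors$actor_id[i], attribute,
                           collection$scheme, threshold)
      if (nw$actors$role[i] == "ego") {
        ego_n <- ego_n + 1L
        if (isTRUE(h)) ego_h <- ego_h + 1L
      } else {
        alt_n <- alt_n + 1L
        if (isTRUE(h)) alt_h <- alt_h + 1L
      }
    }
  }
  summarize_homophily_counts(attribute, ego_h, alt_h, ego_n, alt_n)
}

#' Assemble a homophily-summary row from counts
#'
#' The aggregation arithmetic behind a homophily-source table: totals are
#' the sum of the ego and alter counts, percentages are computed on the
#' role denominators and rendered at one decimal place.
#'
#' @param attribute attribute name (carried through).
#' @param ego_count,alter_count homophilic actor counts by role.
#' @param n_egos,n_alters role denominators.
#' @return one-row data frame with counts and percentages.
#' @export
summarize_homophily_counts <- function(attribute, ego_count, alter_count,
                                       n_egos = 20, n_alters = 200) {
  total <- ego_count + alter_count
  n_total <- n_egos + n_alters
  pct <- function(k, n) if (n > 0) round_half_up(100 * k / n, 1) else NA_real_
  data.frame(
    attribute = attribute,
    ego_count = ego_count, ego_pct = pct(ego_count, n_egos),
    alter_count = alter_count, alter_pct = pct(alter_count, n_alters),
    total_count = total, total_pct = pct(total, n_total),
    stringsAsFactors = FALSE
  )
}

#' Per-network metrics row
#'
#' Everything a per-network summary table reports: directed tie count,
#' density, ego and average degree, ego and network-average normalized
#' betweenness, Freeman degree centralization, and the number of
#' injectable-contraceptive users. Values are full precision; round for
#' display. Centralization and betweenness are `NA` when the network has
#' fewer than 3 actors.
#'
#' @param network an `ego_network`.
#' @return one-row data frame.
#' @export
network_summary <- function(network) {
  n <- n_actors(network)
  eid <- ego_id(network)
  nb <- if (n >= 3) betweenness_normalized(network) else NULL
  users <- if ("cbdic_use" %in% names(network$actors)) {
    sum(network$actors$cbdic_use == "yes", na.rm = TRUE)
  } else NA_integer_
  data.frame(
    network_label = network$label,
    site = network$site,
    n_actors = n,
    directed_ties = directed_tie_count(network),
    density = net_density(network),
    ego_degree = actor_degree(network, eid),
    average_degree = average_degree(network),
    ego_nbetweenness = if (is.null(nb)) NA_real_ else unname(nb[eid]),
    average_nbetweenness = if (is.null(nb)) NA_real_ else mean(nb),
    degree_centralization = if (n >= 3) degree_centralization(network)
                            else NA_real_,
    cbdic_users = users,
    stringsAsFactors = FALSE
  )
}

#' Metrics table for a whole study
#'
#' @param collection a `study_collection`.
#' @return data frame with one [network_summary()] row per network.
#' @export
metrics_table <- function(collection) {
  if (length(collection$networks) == 0) {
    return(network_summary_empty())
  }
  out <- do.call(rbind, lapply(collection$networks, network_summary))
  rownames(out) <- NULL
  out
}

network_summary_empty <- function() {
  data.frame(network_label = character(), site = character(),
             n_actors = integer(), directed_ties = integer(),
             density = numeric(), ego_degree = integer(),
             average_degree = numeric(), ego_nbetweenness = numeric(),
             average_nbetweenness = numeric(),
             degree_centralization = numeric(), cbdic_users = integer(),
             stringsAsFactors = FALSE)
}
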