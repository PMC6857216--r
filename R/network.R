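#' Build a validated ego network
#'
#' An ego network is one respondent (the ego), the alters she named, and
#' the symmetric binary communication ties she reported among all of them
#' (ego-alter and alter-alter alike). Ties are stored undirected; reported
#' *directed* tie counts, which follow the directed-symmetric convention of
#' classic SNA software (110 possible ties among 11 actors), are always
#' emitted as twice the number of stored unordered pairs.
#'
#' @param label short network name, e.g. `"SNA-A"`.
#' @param site site tag, e.g. `"A"` or `"B"`.
#' @param ego_record one-row data frame (or named list) with `actor_id`
#'   and attribute columns for the ego.
#' @param alter_records data frame with one row per alter, same columns.
#' @param tie_pairs two-column data frame/matrix of actor-id pairs. Input
#'   may be directed; pairs are symmetrized and de-duplicated.
#' @param scheme an [attribute_scheme()]; defaults to [default_scheme()].
#' @return an object of class `ego_network` with elements `label`, `site`,
#'   `actors` (data frame: `actor_id`, `role`, one column per attribute,
#'   optional numeric `age`) and `ties` (canonical unordered pair table).
#' @examples
#' ego <- list(actor_id = "ego", ethnicity = "Hausa", cbdic_use = "yes",
#'             marital_status = "married", age_group = ">=30")
#' alters <- data.frame(actor_id = paste0("a", 1:10), ethnicity = "Hausa",
#'                      cbdic_use = "yes", marital_status = "married",
#'                      age_group = ">=30")
#' ties <- data.frame(from = "ego", to = paste0("a", 1:10))
#' nw <- build_network("SNA-X", "A", ego, alters, ties)
#' directed_tie_count(nw)
#' @export
build_network <- function(label, site, ego_record, alter_records,
                          tie_pairs = NULL, scheme = default_scheme()) {
  ego_record <- as.data.frame(as.list(ego_record), stringsAsFactors = FALSE)
  alter_records <- as.data.frame(alter_records, stringsAsFactors = FALSE)
  if (nrow(ego_record) != 1L) stop("exactly one ego record is required")
  ego_record$role <- "ego"
  if (nrow(alter_records) > 0) alter_records$role <- "alter"

  cols <- union(names(ego_record), names(alter_records))
  pad <- function(df) {
    for (cn in setdiff(cols, names(df))) df[[cn]] <- rep(NA, nrow(df))
    df[cols]
  }
  actors <- rbind(pad(ego_record), pad(alter_records))
  actors$actor_id <- as.character(actors$actor_id)

  first <- c("actor_id", "role")
  actors <- actors[c(first, setdiff(names(actors), first))]
  rownames(actors) <- NULL

  if (anyDuplicated(actors$actor_id)) {
    dup <- actors$actor_id[duplicated(actors$actor_id)][1]
    stop("network '", label, "': duplicate actor id '", dup, "'")
  }
  validate_attributes(actors, scheme, label)

  ties <- canonical_ties(tie_pairs, actors$actor_id)
  bad <- setdiff(c(ties$from, ties$to), actors$actor_id)
  if (length(bad) > 0) {
    stop("network '", label, "': tie references undeclared actor '",
         bad[1], "'")
  }
  if (any(ties$from == ties$to)) {
    loop <- ties$from[ties$from == ties$to][1]
    stop("network '", label, "': self-tie on actor '", loop, "'")
  }

  structure(list(label = label, site = site, actors = actors, ties = ties),
            class = "ego_network")
}

# Attribute-value validation against the scheme, plus the marriage-type
# missingness rule: marriage_type may be NA only for single actors.
validate_attributes <- function(actors, scheme, label) {
  for (nm in intersect(names(scheme$attributes), names(actors))) {
    vals <- actors[[nm]]
    bad <- !is.na(vals) & !(vals %in% scheme$attributes[[nm]])
    if (any(bad)) {
      i <- which(bad)[1]
      stop("network '", label, "': actor '", actors$actor_id[i],
           "': illegal level '", vals[i], "' for attribute '", nm, "'")
    }
  }
  if (all(c("marriage_type", "marital_status") %in% names(actors))) {
    bad <- is.na(actors$marriage_type) &
      !is.na(actors$marital_status) & actors$marital_status != "single"
    if (any(bad)) {
      i <- which(bad)[1]
      stop("network '", label, "': actor '", actors$actor_id[i],
           "': marriage_type may be NA only when single")
    }
  }
  invisible(TRUE)
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network> ", x$label, " (site ", x$site, "): ",
      nrow(x$actors), " actors, ", nrow(x$ties),
      " undirected ties (", 2L * nrow(x$ties), " directed)\n", sep = "")
  invisible(x)
}

#' Number of actors in a network
#' @param network an `ego_network`.
#' @return integer actor count.
#' @export
n_actors <- function(network) nrow(network$actors)

#' Directed tie count
#'
#' Reported tie counts follow the directed-symmetric convention: each
#' stored unordered pair counts twice, so a complete 11-actor network has
#' 110 ties.
#'
#' @param network an `ego_network`.
#' @return integer, `2 * nrow(network$ties)`.
#' @export
directed_tie_count <- function(network) 2L * nrow(network$ties)

ego_id <- function(network) {
  network$actors$actor_id[network$actors$role == "ego"]
}

# 0/1 symmetric adjacency matrix in roster order (ego first).
adjacency_matrix <- function(network) {
  ids <- network$actors$actor_id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(network$ties) > 0) {
    i <- match(network$ties$from, ids)
    j <- match(network$ties$to, ids)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

#' Collect ego networks into a study
#'
#' @param networks list of [build_network()] results with unique labels.
#' @param scheme the shared [attribute_scheme()].
#' @return object of class `study_collection`.
#' @export
study_collection <- function(networks, scheme = default_scheme()) {
  stopifnot(is.list(networks))
  labels <- vapply(networks, function(nw) nw$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate network label '", labels[duplicated(labels)][1], "'")
  }
  names(networks) <- labels
  structure(list(networks = networks, scheme = scheme),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  n_act <- sum(vapply(x$networks, n_actors, integer(1)))
  cat("<study_collection> ", length(x$networks), " ego networks, ",
      n_act, " actors\n", sep = "")
  invisible(x)
}

#' All actors of a study as one data frame
#'
#' @param collection a `study_collection`.
#' @return data frame with a `network_label` and `site` column prepended
#'   to each network's actor table.
#' @export
collection_actors <- function(collection) {
  if (length(collection$networks) == 0) {
    return(data.frame(network_label = character(), site = character(),
                      actor_id = character(), role = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(collection$networks, function(nw) {
    cbind(data.frame(network_label = nw$label, site = nw$site,
                     stringsAsFactors = FALSE),
          nw$actors)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Partition a network's actors into two groups by a recoded attribute
#'
#' Applies the scheme's binary recoding of `attribute` (identity for
#' attributes that are already binary) and splits the actors accordingly.
#' Actors with a missing value are set aside rather than forced into a
#' group: group-level E-I indices are only defined over actors whose
#' attribute is known.
#'
#' @param network an `ego_network`.
#' @param attribute attribute name.
#' @param scheme the [attribute_scheme()] to recode under.
#' @return list with `groups` (named list of two character vectors of
#'   actor ids, one per group, possibly empty) and `na` (actor ids with a
#'   missing value).
#' @export
recode_attribute <- function(network, attribute,
                             scheme = default_scheme()) {
  if (!attribute %in% names(network$actors)) {
    stop("unknown attribute '", attribute, "'")
  }
  groups <- binary_groups(scheme, attribute)
  vals <- apply_recoding(scheme, attribute, network$actors[[attribute]])
  na_ids <- network$actors$actor_id[is.na(vals)]
  out <- lapply(groups, function(g) {
    network$actors$actor_id[!is.na(vals) & vals == g]
  })
  names(out) <- groups
  list(groups = out, na = na_ids)
}
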