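#' Write a study to roster and tie files
#'
#' The roster file is comma-delimited UTF-8 with columns `network_label`,
#' `site`, `actor_id`, `role`, then one column per attribute (plus the
#' optional numeric `age`); exactly one `role = ego` row per network, ego
#' first then alters in roster order. The tie file is an edge list with
#' columns `network_label`, `actor_id_1`, `actor_id_2`, one row per
#' unordered tie in canonical order, so output is byte-stable.
#'
#' @param collection a `study_collection`.
#' @param roster_path,ties_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_study <- function(collection, roster_path, ties_path) {
  roster <- collection_actors(collection)
  ties <- if (length(collection$networks) == 0) {
    data.frame(network_label = character(), actor_id_1 = character(),
               actor_id_2 = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(collection$networks, function(nw) {
      if (nrow(nw$ties) == 0) {
        return(data.frame(network_label = character(),
                          actor_id_1 = character(),
                          actor_id_2 = character(),
                          stringsAsFactors = FALSE))
      }
      data.frame(network_label = nw$label, actor_id_1 = nw$ties$from,
                 actor_id_2 = nw$ties$to, stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(roster, roster_path, row.names = FALSE, na = "")
  utils::write.csv(ties, ties_path, row.names = FALSE, na = "")
  invisible(c(roster = roster_path, ties = ties_path))
}

#' Read a study from roster and tie files
#'
#' `ties_path` may be an edge-list file (columns `network_label`,
#' `actor_id_1`, `actor_id_2`) or a directory of per-network square 0/1
#' adjacency matrices named `<label>.csv` (actor ids as header row and
#' first column). Adjacency input must be square and hollow; asymmetric
#' entries are OR-symmetrized with a warning, since the relation is
#' symmetric by design and a one-sided report still records a tie.
#'
#' @param roster_path roster CSV (see [write_study()]).
#' @param ties_path edge-list CSV or directory of adjacency matrices.
#' @param scheme the [attribute_scheme()] to validate against.
#' @return a `study_collection`.
#' @export
read_study <- function(roster_path, ties_path,
                       scheme = default_scheme()) {
  if (!file.exists(roster_path)) {
    stop("roster file not found: ", roster_path)
  }
  if (!file.exists(ties_path)) {
    stop("ties file not found: ", ties_path)
  }
  roster <- utils::read.csv(roster_path, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = "")
  if ("age" %in% names(roster)) roster$age <- as.numeric(roster$age)
  needed <- c("network_label", "site", "actor_id", "role")
  if (!all(needed %in% names(roster))) {
    stop(roster_path, ": missing required column(s) ",
         paste(setdiff(needed, names(roster)), collapse = ", "))
  }
  labels <- unique(roster$network_label)

  tie_lookup <- if (dir.exists(ties_path)) {
    function(label, ids) read_adjacency_ties(
      file.path(ties_path, paste0(label, ".csv")), ids)
  } else {
    edges <- utils::read.csv(ties_path, stringsAsFactors = FALSE,
                             colClasses = "character")
    function(label, ids) {
      e <- edges[edges$network_label == label, , drop = FALSE]
      data.frame(from = e$actor_id_1, to = e$actor_id_2,
                 stringsAsFactors = FALSE)
    }
  }

  networks <- lapply(labels, function(label) {
    rows <- roster[roster$network_label == label, , drop = FALSE]
    ego_rows <- rows[rows$role == "ego", , drop = FALSE]
    if (nrow(ego_rows) != 1L) {
      stop(roster_path, ": network '", label, "' has ", nrow(ego_rows),
           " ego rows (exactly one required)")
    }
    alt_rows <- rows[rows$role == "alter", , drop = FALSE]
    drop_cols <- c("network_label", "site", "role")
    keep <- setdiff(names(rows), drop_cols)
    build_network(label, ego_rows$site[1],
                  ego_rows[keep], alt_rows[keep],
                  tie_lookup(label, rows$actor_id), scheme = scheme)
  })
  study_collection(networks, scheme)
}

# Parse one square 0/1 adjacency matrix file into an unordered tie list;
# OR-symmetrize with a warning when (i,j) and (j,i) disagree.
read_adjacency_ties <- function(path, ids) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop(path, ": adjacency matrix is not square (", nrow(m), "x",
         ncol(m), ")")
  }
  if (!setequal(rownames(m), colnames(m))) {
    stop(path, ": row and column actor ids differ")
  }
  m <- m[, rownames(m), drop = FALSE]
  storage.mode(m) <- "integer"
  if (any(diag(m) != 0)) {
    stop(path, ": nonzero diagonal (self-tie)")
  }
  if (!identical(m, t(m))) {
    warning(path, ": asymmetric entries OR-symmetrized")
    m <- pmax(m, t(m))
  }
  idx <- which(m == 1L & upper.tri(m), arr.ind = TRUE)
  data.frame(from = rownames(m)[idx[, 1]], to = rownames(m)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Write one network's adjacency matrix
#'
#' Square 0/1 matrix with the ego first and alters in roster order,
#' readable back by [read_study()] when pointed at a directory of such
#' files.
#'
#' @param network an `ego_network`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_adjacency <- function(network, path) {
  A <- adjacency_matrix(network)
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  invisible(path)
}

# --- sociogram export ---------------------------------------------------

SOCIOGRAM_COLORS <- c(relative_or_close_friend = "pink",
                      close_friend = "blue",
                      co_worker = "black",
                      neighbour_or_acquaintance = "green")

#' Node visual coding for a sociogram
#'
#' The attribute-driven coding used on the study's network maps: circles
#' for injectable-contraceptive users and squares for non-users; the ego
#' red and alters coloured by their relationship to the ego (pink for
#' relatives and close friends, blue for close friends, black for
#' co-workers, green for neighbours and acquaintances); node size
#' strictly increasing in degree centrality; and a box drawn around the
#' actors holding the top three betweenness values. When every actor has
#' the same betweenness (as in a complete network, where all values are
#' zero) no node is boxed. If a tie at the third rank would box more
#' than three actors, all tied actors are boxed and a message is logged.
#'
#' @param network an `ego_network`.
#' @param color_map named character vector mapping relationship levels to
#'   colours (defaults to the standard coding).
#' @return data frame with `actor_id`, `role`, `shape`, `color`, `size`,
#'   `boxed`.
#' @export
sociogram_node_coding <- function(network,
                                  color_map = SOCIOGRAM_COLORS) {
  actors <- network$actors
  deg <- degree_vector(network)
  btw <- betweenness_raw(network)

  shape <- rep("circle", nrow(actors))
  if ("cbdic_use" %in% names(actors)) {
    shape[!is.na(actors$cbdic_use) & actors$cbdic_use == "no"] <- "square"
  }
  color <- rep("grey", nrow(actors))
  if ("relationship" %in% names(actors)) {
    known <- actors$relationship %in% names(color_map)
    color[known] <- unname(color_map[actors$relationship[known]])
  }
  color[actors$role == "ego"] <- "red"

  # size must be strictly monotone in degree; a linear map suffices
  size <- 10 + 3 * unname(deg)

  # Box the top-three betweenness actors. No boxes when all values are
  # equal; actors at the network minimum are never "high betweenness",
  # so a rank-3 cutoff that falls on the minimum does not box them
  # (a star boxes only its centre). A genuine tie at rank 3 boxes all
  # tied actors, with a log message.
  boxed <- rep(FALSE, nrow(actors))
  if (length(unique(btw)) > 1L) {
    ord <- order(-btw, seq_along(btw))
    cutoff <- btw[ord[min(3L, length(ord))]]
    boxed <- btw >= cutoff & btw > min(btw)
    if (sum(boxed) > 3L) {
      message(network$label, ": betweenness tie at rank 3; boxing ",
              sum(boxed), " actors")
    }
  }

  data.frame(actor_id = actors$actor_id, role = actors$role,
             shape = shape, color = color, size = size, boxed = boxed,
             stringsAsFactors = FALSE)
}

#' Export a sociogram
#'
#' Writes the network with its visual node coding (see
#' [sociogram_node_coding()]) as GraphML or DOT. Colours, shapes and
#' sizes are emitted as node attributes for downstream renderers; no
#' layout is computed.
#'
#' @param network an `ego_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @param coding optional precomputed node coding.
#' @return invisibly, `path`.
#' @export
export_sociogram <- function(network, path,
                             format = c("graphml", "dot"),
                             coding = NULL) {
  format <- match.arg(format)
  coding <- coding %||% sociogram_node_coding(network)
  switch(format,
         graphml = write_graphml(network, coding, path),
         dot = write_dot(network, coding, path))
  invisible(path)
}

write_graphml <- function(network, coding, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keys <- list(
    c(id = "d_role", attr.name = "role", attr.type = "string"),
    c(id = "d_shape", attr.name = "shape", attr.type = "string"),
    c(id = "d_color", attr.name = "color", attr.type = "string"),
    c(id = "d_size", attr.name = "size", attr.type = "double"),
    c(id = "d_boxed", attr.name = "boxed", attr.type = "boolean")
  )
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[["id"]], `for` = "node",
                        attr.name = k[["attr.name"]],
                        attr.type = k[["attr.type"]])
  }
  g <- xml2::xml_add_child(doc, "graph", id = network$label,
                           edgedefault = "undirected")
  for (i in seq_len(nrow(coding))) {
    node <- xml2::xml_add_child(g, "node", id = coding$actor_id[i])
    add_data <- function(key, value) {
      d <- xml2::xml_add_child(node, "data", key = key)
      xml2::xml_set_text(d, as.character(value))
    }
    add_data("d_role", coding$role[i])
    add_data("d_shape", coding$shape[i])
    add_data("d_color", coding$color[i])
    add_data("d_size", coding$size[i])
    add_data("d_boxed", tolower(as.character(coding$boxed[i])))
  }
  for (i in seq_len(nrow(network$ties))) {
    xml2::xml_add_child(g, "edge", source = network$ties$from[i],
                        target = network$ties$to[i])
  }
  xml2::write_xml(doc, path)
}

write_dot <- function(network, coding, path) {
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c(paste0("graph ", q(network$label), " {"))
  for (i in seq_len(nrow(coding))) {
    lines <- c(lines, sprintf(
      "  %s [role=%s, shape=%s, color=%s, size=%s, boxed=%s];",
      q(coding$actor_id[i]), q(coding$role[i]), q(coding$shape[i]),
      q(coding$color[i]), q(coding$size[i]),
      q(tolower(as.character(coding$boxed[i])))))
  }
  for (i in seq_len(nrow(network$ties))) {
    lines <- c(lines, sprintf("  %s -- %s;", q(network$ties$from[i]),
                              q(network$ties$to[i])))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
}
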