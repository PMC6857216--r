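#' Descriptive tabulations for a study
#'
#' The three descriptive summaries an ego-network survey reports:
#'
#' * `actors`: counts and percentages of every attribute level by role
#'   (egos / alters / total). Percentages use the number of actors with
#'   a non-missing value as denominator, so e.g. marriage type is
#'   tabulated over married actors only.
#' * `alter_relationship`: the alter-only attributes (relationship to
#'   ego, interaction place and frequency) by site and in total.
#' * `ages`: per-network ego age and alter age mean and SD, emitted only
#'   when the roster carries a numeric `age` column.
#'
#' Percentages are rendered at one decimal place, half away from zero.
#'
#' @param collection a `study_collection`.
#' @return list of data frames `actors`, `alter_relationship`, `ages`.
#' @export
tabulate_descriptives <- function(collection) {
  actors <- collection_actors(collection)
  scheme <- collection$scheme
  pct <- function(k, n) if (n > 0) round_half_up(100 * k / n, 1) else NA_real_

  actor_rows <- list()
  for (at in intersect(names(scheme$attributes), names(actors))) {
    vals <- actors[[at]]
    known <- !is.na(vals)
    n_ego <- sum(known & actors$role == "ego")
    n_alt <- sum(known & actors$role == "alter")
    for (lv in scheme$attributes[[at]]) {
      k_ego <- sum(known & actors$role == "ego" & vals == lv)
      k_alt <- sum(known & actors$role == "alter" & vals == lv)
      actor_rows[[length(actor_rows) + 1L]] <- data.frame(
        attribute = at, level = lv,
        ego_n = k_ego, ego_pct = pct(k_ego, n_ego),
        alter_n = k_alt, alter_pct = pct(k_alt, n_alt),
        total_n = k_ego + k_alt,
        total_pct = pct(k_ego + k_alt, n_ego + n_alt),
        stringsAsFactors = FALSE)
    }
  }
  actors_tab <- if (length(actor_rows)) do.call(rbind, actor_rows) else
    data.frame(attribute = character(), level = character(),
               ego_n = integer(), ego_pct = numeric(),
               alter_n = integer(), alter_pct = numeric(),
               total_n = integer(), total_pct = numeric(),
               stringsAsFactors = FALSE)

  rel_rows <- list()
  alters <- actors[actors$role == "alter", , drop = FALSE]
  for (at in intersect(ALTER_ONLY_ATTRS, names(actors))) {
    vals <- alters[[at]]
    known <- !is.na(vals)
    n_a <- sum(known & alters$site == "A")
    n_b <- sum(known & alters$site == "B")
    for (lv in scheme$attributes[[at]]) {
      k_a <- sum(known & alters$site == "A" & vals == lv)
      k_b <- sum(known & alters$site == "B" & vals == lv)
      rel_rows[[length(rel_rows) + 1L]] <- data.frame(
        attribute = at, level = lv,
        site_a_n = k_a, site_a_pct = pct(k_a, n_a),
        site_b_n = k_b, site_b_pct = pct(k_b, n_b),
        total_n = k_a + k_b, total_pct = pct(k_a + k_b, n_a + n_b),
        stringsAsFactors = FALSE)
    }
  }
  rel_tab <- if (length(rel_rows)) do.call(rbind, rel_rows) else
    data.frame(attribute = character(), level = character(),
               site_a_n = integer(), site_a_pct = numeric(),
               site_b_n = integer(), site_b_pct = numeric(),
               total_n = integer(), total_pct = numeric(),
               stringsAsFactors = FALSE)

  ages_tab <- data.frame(network_label = character(), site = character(),
                         ego_age = numeric(), alter_age_mean = numeric(),
                         alter_age_sd = numeric(), stringsAsFactors = FALSE)
  if ("age" %in% names(actors) && nrow(actors) > 0) {
    ages_tab <- do.call(rbind, lapply(collection$networks, function(nw) {
      a <- nw$actors
      alter_age <- a$age[a$role == "alter"]
      data.frame(network_label = nw$label, site = nw$site,
                 ego_age = a$age[a$role == "ego"],
                 alter_age_mean = round_half_up(mean(alter_age), 1),
                 alter_age_sd = round_half_up(stats::sd(alter_age), 1),
                 stringsAsFactors = FALSE)
    }))
    rownames(ages_tab) <- NULL
  }

  list(actors = actors_tab, alter_relationship = rel_tab, ages = ages_tab)
}

#' E-I index table for a whole study
#'
#' One row per network with the E-I index of each group of each
#' attribute in wide form; undefined indices are `NA` (printed as an
#' en dash by [run_report()]).
#'
#' @param collection a `study_collection`.
#' @param attributes attribute names to include.
#' @return wide data frame, one row per network.
#' @export
study_ei_table <- function(collection,
                           attributes = c("ethnicity", "age_group",
                                          "education",
                                          "marriage_type")) {
  if (length(collection$networks) == 0) {
    return(data.frame(network_label = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(collection$networks, function(nw) {
    long <- ei_table(nw, attributes, collection$scheme)
    wide <- data.frame(network_label = nw$label, site = nw$site,
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(long))) {
      wide[[paste(long$attribute[i], long$group[i], sep = ".")]] <-
        long$ei_index[i]
    }
    wide
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Homophily summary table for a study
#'
#' @param collection a `study_collection`.
#' @param attributes attributes to classify homophily on.
#' @param threshold passed to [actor_homophily()].
#' @return data frame, one [homophily_summary()] row per attribute.
#' @export
study_homophily_table <- function(collection,
                                  attributes = c("ethnicity",
                                                 "cbdic_use",
                                                 "age_group",
                                                 "education",
                                                 "marriage_type"),
                                  threshold = 0) {
  out <- do.call(rbind, lapply(attributes, function(at) {
    homophily_summary(collection, at, threshold)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full reporting pipeline
#'
#' Takes a study (given directly, read from files, or generated from a
#' config), computes every report table and writes them with one
#' sociogram per network and a provenance log to `out_dir`:
#'
#' * `descriptives_actors.csv`, `descriptives_relationship.csv`,
#'   `descriptives_ages.csv` -- see [tabulate_descriptives()];
#' * `network_metrics.csv` -- per-network metrics (2-dp rendering of
#'   density, degrees, betweenness, centralization);
#' * `ei_indices.csv` -- E-I indices at 3 dp, undefined cells printed
#'   as an en dash;
#' * `homophily_summary.csv`;
#' * `sociograms/<label>.<ext>`;
#' * `run_log.txt` (and `config_echo.yaml` when generated).
#'
#' @param collection a `study_collection`, or `NULL` to use files/config.
#' @param roster_path,ties_path input files for [read_study()].
#' @param config a [generator_config()] to simulate from.
#' @param out_dir output directory (created if needed).
#' @param sociogram_format `"graphml"` or `"dot"`.
#' @param homophily_threshold passed through to homophily tables.
#' @return invisibly, the report bundle (list of the computed tables).
#' @export
run_report <- function(collection = NULL, roster_path = NULL,
                       ties_path = NULL, config = NULL,
                       out_dir = ".", sociogram_format = "graphml",
                       homophily_threshold = 0) {
  if (is.null(collection)) {
    if (!is.null(config)) {
      collection <- generate_study(config)
    } else if (!is.null(roster_path)) {
      collection <- read_study(roster_path, ties_path)
    } else {
      stop("one of collection, roster_path or config is required")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  desc <- tabulate_descriptives(collection)
  metrics <- metrics_table(collection)
  ei <- study_ei_table(collection)
  hom <- study_homophily_table(collection,
                               threshold = homophily_threshold)

  metrics_out <- metrics
  for (cn in c("density", "average_degree", "ego_nbetweenness",
               "average_nbetweenness", "degree_centralization")) {
    metrics_out[[cn]] <- round_half_up(metrics_out[[cn]], 2)
  }
  ei_out <- ei
  for (cn in setdiff(names(ei_out), c("network_label", "site"))) {
    v <- round_half_up(ei_out[[cn]], 3)
    ei_out[[cn]] <- ifelse(is.na(v), "–", format(v, trim = TRUE))
  }

  utils::write.csv(desc$actors,
                   file.path(out_dir, "descriptives_actors.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(desc$alter_relationship,
                   file.path(out_dir, "descriptives_relationship.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(desc$ages,
                   file.path(out_dir, "descriptives_ages.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(metrics_out,
                   file.path(out_dir, "network_metrics.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(ei_out, file.path(out_dir, "ei_indices.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(hom, file.path(out_dir, "homophily_summary.csv"),
                   row.names = FALSE, na = "")

  soc_dir <- file.path(out_dir, "sociograms")
  dir.create(soc_dir, showWarnings = FALSE)
  ext <- if (sociogram_format == "graphml") "graphml" else "dot"
  for (nw in collection$networks) {
    export_sociogram(nw, file.path(soc_dir, paste0(nw$label, ".", ext)),
                     format = sociogram_format)
  }

  log_lines <- c(
    paste0("egosna version: ",
           as.character(utils::packageVersion("egosna"))),
    paste0("R version: ", R.version.string),
    paste0("networks: ", length(collection$networks)),
    paste0("sociogram format: ", sociogram_format),
    paste0("homophily threshold: ", homophily_threshold),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  if (!is.null(config)) {
    log_lines <- c(log_lines, paste0("seed: ", config$seed))
    cfg_echo <- config[setdiff(names(config), "scheme")]
    yaml::write_yaml(cfg_echo, file.path(out_dir, "config_echo.yaml"))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(descriptives = desc, metrics = metrics, ei = ei,
                 homophily = hom, collection = collection))
}
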