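#' Default attribute marginals
#'
#' Marginal category probabilities used by the synthetic questionnaire
#' generator, matching the published actor composition of the survey the
#' package models: 62.7% of actors aged 30 or older, 98.2% married, 80.5%
#' Hausa, 84.1% users of community-distributed injectable contraceptives,
#' and so on. Relationship, interaction place and interaction frequency
#' apply to alters only (they describe the alter relative to her ego).
#'
#' @return named list of named probability vectors, one per attribute.
#' @export
default_marginals <- function() {
  list(
    age_group = c("<30" = 0.373, ">=30" = 0.627),
    marital_status = c(single = 0.018, married = 0.982),
    education = c(none = 0.255, primary_or_secondary = 0.550,
                  tertiary = 0.195),
    occupation = c(informal = 0.582, formal = 0.236,
                   self_employed = 0.182),
    ethnicity = c(Hausa = 0.805, Others = 0.195),
    marriage_type = c(monogamy = 0.537, polygamy = 0.463),
    fp_use = c(yes = 0.923, no = 0.077),
    cbdic_use = c(yes = 0.841, no = 0.159),
    relationship = c(relative_or_close_friend = 0.54, close_friend = 0,
                     co_worker = 0.11, neighbour_or_acquaintance = 0.35),
    interaction_place = c(worship = 0.16, market_or_workplace = 0.255,
                          social_visit = 0.585),
    interaction_freq = c(weekly = 0.38, monthly = 0.51, yearly = 0.11)
  )
}

# Alter-only attributes: describe the alter's relation to her ego.
ALTER_ONLY_ATTRS <- c("relationship", "interaction_place",
                      "interaction_freq")

#' Configuration for the synthetic study generator
#'
#' @param seed integer root seed; per-network substreams are derived from
#'   it by hashing the network label, so regenerating with more networks
#'   never changes the earlier ones.
#' @param k_egos number of ego networks (default 20).
#' @param n_alters alters per ego (default 10, i.e. 11 actors and 110
#'   possible directed ties per network).
#' @param attribute_marginals named list of per-level probabilities;
#'   see [default_marginals()].
#' @param base_tie_prob baseline probability `p0` that an actor pair is
#'   tied when they share no attribute the homophily weights act on.
#' @param homophily_weights named non-negative vector; weight `w` for an
#'   attribute adds `w` to the log-odds of a tie when the pair shares
#'   that attribute's category, so assortativity composes additively on
#'   the log-odds scale and probabilities never leave `[0, 1]`.
#' @param site_split fraction of networks assigned to site "A".
#' @param scheme the [attribute_scheme()] generated actors must satisfy.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             k_egos = 20L,
                             n_alters = 10L,
                             attribute_marginals = default_marginals(),
                             base_tie_prob = 0.65,
                             homophily_weights = c(ethnicity = 1,
                                                   age_group = 0.5,
                                                   education = 0.5,
                                                   marriage_type = 0.25),
                             site_split = 0.5,
                             scheme = default_scheme()) {
  stopifnot(k_egos >= 0, n_alters >= 1,
            base_tie_prob >= 0, base_tie_prob <= 1,
            site_split >= 0, site_split <= 1,
            all(homophily_weights >= 0))
  for (nm in names(attribute_marginals)) {
    p <- attribute_marginals[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
      stop("marginal for '", nm,
           "' must be probabilities summing to 1")
    }
    if (nm %in% names(scheme$attributes) &&
        !all(names(p) %in% scheme$attributes[[nm]])) {
      stop("marginal for '", nm, "' names a level outside the scheme")
    }
  }
  structure(list(seed = as.integer(seed), k_egos = as.integer(k_egos),
                 n_alters = as.integer(n_alters),
                 attribute_marginals = attribute_marginals,
                 base_tie_prob = base_tie_prob,
                 homophily_weights = homophily_weights,
                 site_split = site_split, scheme = scheme),
            class = "generator_config")
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [generator_config()]; missing keys fall
#' back to the defaults. `attribute_marginals` entries override the
#' default marginals attribute by attribute.
#'
#' @param path YAML file path.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  marg <- default_marginals()
  for (nm in names(cfg$attribute_marginals %||% list())) {
    marg[[nm]] <- unlist(cfg$attribute_marginals[[nm]])
  }
  generator_config(
    seed = cfg$seed %||% 1L,
    k_egos = cfg$k_egos %||% 20L,
    n_alters = cfg$n_alters %||% 10L,
    attribute_marginals = marg,
    base_tie_prob = cfg$base_tie_prob %||% 0.65,
    homophily_weights = unlist(cfg$homophily_weights) %||%
      c(ethnicity = 1, age_group = 0.5, education = 0.5,
        marriage_type = 0.25),
    site_split = cfg$site_split %||% 0.5
  )
}

sample_level <- function(marginal) {
  sample(names(marginal), 1L, prob = marginal)
}

#' Draw one synthetic actor
#'
#' Attributes are drawn independently from the configured marginals.
#' Egos are forced to be married users of the innovation (family planning
#' and injectable contraceptives alike), matching a design that recruits
#' early adopters; alters additionally receive the ego-relative
#' attributes (relationship, interaction place and frequency).
#' `marriage_type` is set to `NA` for single actors. A numeric `age` is
#' drawn uniformly inside the actor's age band (18-29 / 30-45) so that
#' age summaries per network can be tabulated.
#'
#' Sampling uses the current RNG state; callers seed it.
#'
#' @param config a [generator_config()].
#' @param actor_id id for the new actor.
#' @param role `"ego"` or `"alter"`.
#' @return one-row data frame.
#' @export
sample_actor <- function(config, actor_id, role = c("alter", "ego")) {
  role <- match.arg(role)
  m <- config$attribute_marginals
  rec <- list(actor_id = actor_id, role = role)
  for (nm in setdiff(names(m), ALTER_ONLY_ATTRS)) {
    rec[[nm]] <- sample_level(m[[nm]])
  }
  if (role == "ego") {
    rec$marital_status <- "married"
    rec$fp_use <- "yes"
    rec$cbdic_use <- "yes"
  }
  if (rec$marital_status == "single") {
    rec$marriage_type <- NA_character_
  } else if (is.na(rec$marriage_type %||% NA)) {
    rec$marriage_type <- sample_level(m$marriage_type)
  }
  for (nm in intersect(ALTER_ONLY_ATTRS, names(m))) {
    rec[[nm]] <- if (role == "alter") sample_level(m[[nm]])
                 else NA_character_
  }
  rec$age <- if (rec$age_group == "<30") sample(18:29, 1L)
             else sample(30:45, 1L)
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Generate one synthetic ego network
#'
#' Draws one ego and `n_alters` alters, then assigns each unordered actor
#' pair a tie independently with probability
#' `plogis(qlogis(p0) + sum_a w_a * [same category on a])`:
#' assortativity acts on the log-odds scale, and ego-alter and
#' alter-alter pairs are treated identically. The RNG is seeded from the
#' root seed plus a stable hash of the label, giving each network its own
#' reproducible substream.
#'
#' @param config a [generator_config()].
#' @param label network label.
#' @param site site tag.
#' @return an `ego_network`.
#' @export
generate_network <- function(config, label, site = "A") {
  set.seed((config$seed + stable_hash(label)) %% 2147483647L)
  ego <- sample_actor(config, "ego", role = "ego")
  alters <- do.call(rbind, lapply(seq_len(config$n_alters), function(i) {
    sample_actor(config, paste0("a", i), role = "alter")
  }))
  actors <- rbind(ego, alters)
  n <- nrow(actors)
  base_logit <- stats::qlogis(config$base_tie_prob)
  w <- config$homophily_weights
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      lo <- base_logit
      for (at in names(w)) {
        vi <- actors[[at]][i]; vj <- actors[[at]][j]
        if (!is.na(vi) && !is.na(vj) && vi == vj) lo <- lo + w[[at]]
      }
      if (stats::runif(1) < stats::plogis(lo)) {
        from <- c(from, actors$actor_id[i])
        to <- c(to, actors$actor_id[j])
      }
    }
  }
  build_network(label, site, ego, alters,
                data.frame(from = from, to = to,
                           stringsAsFactors = FALSE),
                scheme = config$scheme)
}

#' Generate a whole synthetic study
#'
#' `k_egos` networks labelled `SNA-A`, `SNA-B`, ... with the first
#' `round(k_egos * site_split)` assigned to site "A" and the rest to
#' site "B". Deterministic for a fixed seed.
#'
#' @param config a [generator_config()].
#' @return a `study_collection`.
#' @examples
#' study <- generate_study(generator_config(seed = 42, k_egos = 4))
#' metrics_table(study)
#' @export
generate_study <- function(config) {
  labels <- study_labels(config$k_egos)
  n_a <- round(config$k_egos * config$site_split)
  sites <- c(rep("A", n_a), rep("B", config$k_egos - n_a))
  networks <- lapply(seq_along(labels), function(i) {
    generate_network(config, labels[i], sites[i])
  })
  study_collection(networks, config$scheme)
}

study_labels <- function(k) {
  if (k == 0) return(character(0))
  pool <- c(LETTERS,
            as.vector(outer(LETTERS, LETTERS, paste0)))
  paste0("SNA-", pool[seq_len(k)])
}
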