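#' Attribute schemes for ego-network rosters
#'
#' An attribute scheme is the codebook for the categorical actor attributes
#' collected by an ego-network questionnaire: each attribute has an ordered
#' set of category labels, and may carry a *recoding* that collapses its
#' levels onto exactly two groups. Recodings are what group-level E-I
#' (external-internal) homophily indices are computed on, since those
#' indices compare exactly two groups at a time.
#'
#' @param attributes named list; each element a character vector of unique
#'   category labels for one attribute.
#' @param recodings named list; each element a named character vector
#'   mapping every original level of the attribute onto one of exactly two
#'   group labels. Attributes that are already binary need no recoding.
#' @return an object of class `attribute_scheme`.
#' @seealso [default_scheme()] for the scheme used by the survey design
#'   this package models.
#' @export
attribute_scheme <- function(attributes, recodings = list()) {
  stopifnot(is.list(attributes), length(attributes) > 0)
  if (is.null(names(attributes)) || any(names(attributes) == "")) {
    stop("every attribute must be named")
  }
  for (nm in names(attributes)) {
    lv <- attributes[[nm]]
    if (!is.character(lv) || anyDuplicated(lv)) {
      stop("attribute '", nm, "': levels must be unique character labels")
    }
  }
  for (nm in names(recodings)) {
    if (!nm %in% names(attributes)) {
      stop("recoding for unknown attribute '", nm, "'")
    }
    rc <- recodings[[nm]]
    lv <- attributes[[nm]]
    if (!setequal(names(rc), lv)) {
      stop("recoding for '", nm, "' must map every level exactly once")
    }
    if (length(unique(rc)) != 2L) {
      stop("recoding for '", nm, "' must be onto exactly two groups")
    }
  }
  structure(list(attributes = attributes, recodings = recodings),
            class = "attribute_scheme")
}

#' Default questionnaire attribute scheme
#'
#' The scheme for a community-health-worker-delivered injectable
#' contraceptive (CHWDIC) adoption survey: sociodemographic attributes of
#' each woman (ego or alter), her family-planning and CHWDIC use, and --
#' for alters only -- her relationship to the ego and where and how often
#' the two interact.
#'
#' Education is collected at three levels but compared at two
#' ("less than secondary" vs "at least secondary"). Where women whose
#' highest education is the pooled "primary or secondary" level fall is a
#' genuine coding choice, so both variants are available:
#' `"pool_primary_up"` places them in "at_least_secondary" (the pooled
#' level contains secondary completers), `"pool_primary_down"` in
#' "less_than_secondary".
#'
#' @param edu_recode which education recoding variant to use.
#' @return an `attribute_scheme`.
#' @export
default_scheme <- function(edu_recode = c("pool_primary_up",
                                          "pool_primary_down")) {
  edu_recode <- match.arg(edu_recode)
  edu_primary_group <- switch(edu_recode,
    pool_primary_up = "at_least_secondary",
    pool_primary_down = "less_than_secondary"
  )
  attribute_scheme(
    attributes = list(
      age_group = c("<30", ">=30"),
      marital_status = c("single", "married"),
      education = c("none", "primary_or_secondary", "tertiary"),
      occupation = c("informal", "formal", "self_employed"),
      ethnicity = c("Hausa", "Others"),
      marriage_type = c("monogamy", "polygamy"),
      fp_use = c("yes", "no"),
      cbdic_use = c("yes", "no"),
      relationship = c("relative_or_close_friend", "close_friend",
                       "co_worker", "neighbour_or_acquaintance"),
      interaction_place = c("worship", "market_or_workplace",
                            "social_visit"),
      interaction_freq = c("weekly", "monthly", "yearly")
    ),
    recodings = list(
      education = c(none = "less_than_secondary",
                    primary_or_secondary = edu_primary_group,
                    tertiary = "at_least_secondary")
    )
  )
}

#' @export
print.attribute_scheme <- function(x, ...) {
  cat("<attribute_scheme> ", length(x$attributes), " attributes\n", sep = "")
  for (nm in names(x$attributes)) {
    rec <- if (nm %in% names(x$recodings)) " [recoded to binary]" else ""
    cat("  ", nm, ": ", paste(x$attributes[[nm]], collapse = ", "),
        rec, "\n", sep = "")
  }
  invisible(x)
}

# Binary group labels for an attribute: its recoding's groups if one is
# declared, otherwise its own two levels; error if neither applies.
binary_groups <- function(scheme, attribute) {
  if (!attribute %in% names(scheme$attributes)) {
    stop("unknown attribute '", attribute, "'")
  }
  if (attribute %in% names(scheme$recodings)) {
    unique(unname(scheme$recodings[[attribute]]))
  } else if (length(scheme$attributes[[attribute]]) == 2L) {
    scheme$attributes[[attribute]]
  } else {
    stop("attribute '", attribute,
         "' has more than two levels and no recoding")
  }
}

# Map raw levels to binary group labels (identity for binary attributes).
apply_recoding <- function(scheme, attribute, values) {
  if (attribute %in% names(scheme$recodings)) {
    unname(scheme$recodings[[attribute]][as.character(values)])
  } else if (length(scheme$attributes[[attribute]]) == 2L) {
    as.character(values)
  } else {
    stop("attribute '", attribute,
         "' has more than two levels and no recoding")
  }
}
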