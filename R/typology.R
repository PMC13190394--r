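# Country-level causality typology: turn the six directional p-values
# into per-pair direction labels, a three-way country classification
# (bidirectional / unidirectional / none), distinct-profile enumeration
# and rule-based dominant-source groupings.

parse_direction <- function(d) {
  parts <- strsplit(d, "->", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed direction '", d, "'", call. = FALSE)
  trimws(parts)
}

#' Label the causal direction of each variable pair per country
#'
#' Applies the inclusive threshold rule p <= alpha to the two directional
#' p-values of every pair: both significant gives `Bidirectional`, one
#' gives that direction, neither gives `None`.
#'
#' @param pvalues data frame with columns `country`, `direction` (strings
#'   like `"CO2->MIGR"`) and `p_value`; both directions of each pair must
#'   be present for every country.
#' @param alpha significance threshold (inclusive), default 0.10.
#' @return data frame with columns `country`, `var_a`, `var_b`, `pair`
#'   and `label` (`"None"`, `"A->B"`/`"B->A"` spelled with the variable
#'   names, or `"Bidirectional"`); pair order follows first appearance in
#'   `pvalues`.
#' @export
label_directions <- function(pvalues, alpha = 0.10) {
  stopifnot(all(c("country", "direction", "p_value") %in% names(pvalues)))
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)", call. = FALSE)
  dirs <- unique(pvalues$direction)
  ends <- lapply(dirs, parse_direction)
  pair_key <- vapply(ends, function(e) paste(sort(e), collapse = ":"),
                     character(1))
  pairs <- list()
  for (j in seq_along(dirs)) {
    if (!pair_key[j] %in% names(pairs)) pairs[[pair_key[j]]] <- ends[[j]]
  }
  countries <- unique(pvalues$country)
  rows <- list()
  for (ct in countries) {
    sub <- pvalues[pvalues$country == ct, ]
    for (pk in names(pairs)) {
      ab <- pairs[[pk]]
      fwd <- paste0(ab[1L], "->", ab[2L])
      rev <- paste0(ab[2L], "->", ab[1L])
      pf <- sub$p_value[sub$direction == fwd]
      pr <- sub$p_value[sub$direction == rev]
      if (length(pf) != 1L || length(pr) != 1L)
        stop("country '", ct, "': both directions of pair ", pk,
             " must be present exactly once", call. = FALSE)
      sf <- pf <= alpha; sr <- pr <= alpha
      label <- if (sf && sr) "Bidirectional" else if (sf) fwd
               else if (sr) rev else "None"
      rows[[length(rows) + 1L]] <- data.frame(
        country = ct, var_a = ab[1L], var_b = ab[2L],
        pair = paste(ab, collapse = ":"), label = label,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

# significant directed edges implied by a set of pair labels
labels_to_edges <- function(labels) {
  edges <- list()
  for (r in seq_len(nrow(labels))) {
    lb <- labels$label[r]
    a <- labels$var_a[r]; b <- labels$var_b[r]
    if (lb == "None") next
    if (lb == "Bidirectional") {
      edges[[length(edges) + 1L]] <- c(a, b)
      edges[[length(edges) + 1L]] <- c(b, a)
    } else {
      edges[[length(edges) + 1L]] <- parse_direction(lb)
    }
  }
  edges
}

dominant_group <- function(labels, recipient_target) {
  if (any(labels$label == "Bidirectional")) return("feedback")
  edges <- labels_to_edges(labels)
  if (length(edges) == 0L) return("none")
  sources <- unique(vapply(edges, `[`, character(1), 1L))
  targets <- unique(vapply(edges, `[`, character(1), 2L))
  if (length(sources) == 1L) return(paste0(sources, "-dominant"))
  if (!is.na(recipient_target) && length(targets) == 1L &&
      targets == recipient_target)
    return("recipient")
  "multi-linkage"
}

# optional interpretive mapping from rule-based groups to narrative
# regime names; anything without a clean one-to-one mapping stays NA
regime_of_group <- function(group, migration_var) {
  if (group == "feedback") return("integrated nexus")
  if (group == "none") return("decoupled")
  if (!is.na(migration_var)) {
    if (group == paste0(migration_var, "-dominant"))
      return("demographic-pressure")
  }
  if (grepl("-dominant$", group) &&
      grepl("co2", group, ignore.case = TRUE))
    return("environment-sensitive")
  NA_character_
}

#' Classify countries by their causality profiles
#'
#' From the per-pair direction labels, assigns each country to one of
#' three classes: `bidirectional` (at least one pair with causality in
#' both directions), `unidirectional` (at least one significant direction
#' but no bidirectional pair) or `none`; enumerates the distinct label
#' triples (profiles); and applies rule-based dominant-source groupings:
#' a single active source variable makes that variable dominant, multiple
#' sources all pointing at the migration variable make the country a
#' migration `recipient`, any other multi-source pattern is
#' `multi-linkage`, and countries with a bidirectional pair form the
#' `feedback` group. An optional interpretive regime name is attached per
#' group; it is narrative shorthand, not a statistical output.
#'
#' @param labels output of [label_directions()].
#' @param migration_var name of the migration-like variable used by the
#'   recipient rule; `NULL` auto-detects a variable whose name contains
#'   "migr" (case-insensitive) and `NA` disables the rule.
#' @return list of class `typology_summary`: `profiles` (per-country data
#'   frame with one label column per pair, `class`, `group`,
#'   `regime_interpretive`), `class_counts`, `n_distinct_profiles`,
#'   `profile_table` (one row per distinct profile with its countries and
#'   count) and `group_counts`.
#' @export
classify_countries <- function(labels, migration_var = NULL) {
  pair_order <- unique(labels$pair)
  countries <- unique(labels$country)
  vars <- unique(c(labels$var_a, labels$var_b))
  if (is.null(migration_var)) {
    hit <- grep("migr", vars, ignore.case = TRUE, value = TRUE)
    migration_var <- if (length(hit) == 1L) hit else NA_character_
  }

  prof <- data.frame(country = countries, stringsAsFactors = FALSE)
  for (pk in pair_order) prof[[pk]] <- NA_character_
  prof$class <- NA_character_
  prof$group <- NA_character_
  prof$regime_interpretive <- NA_character_
  for (i in seq_along(countries)) {
    sub <- labels[labels$country == countries[i], ]
    for (pk in pair_order)
      prof[i, pk] <- sub$label[sub$pair == pk]
    lbls <- sub$label
    prof$class[i] <- if (any(lbls == "Bidirectional")) "bidirectional"
                     else if (all(lbls == "None")) "none"
                     else "unidirectional"
    prof$group[i] <- dominant_group(sub, migration_var)
    prof$regime_interpretive[i] <- regime_of_group(prof$group[i],
                                                   migration_var)
  }

  key <- apply(prof[, pair_order, drop = FALSE], 1L, paste, collapse = " | ")
  uk <- unique(key)
  profile_table <- data.frame(
    profile = seq_along(uk),
    labels = uk,
    countries = vapply(uk, function(k)
      paste(sort(prof$country[key == k]), collapse = "; "), character(1)),
    n = vapply(uk, function(k) sum(key == k), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  class_counts <- c(
    bidirectional = sum(prof$class == "bidirectional"),
    unidirectional = sum(prof$class == "unidirectional"),
    none = sum(prof$class == "none"))

  structure(list(
    profiles = prof,
    class_counts = class_counts,
    n_distinct_profiles = length(uk),
    profile_table = profile_table,
    group_counts = table(prof$group),
    alpha = attr(labels, "alpha"),
    migration_var = migration_var), class = "typology_summary")
}

#' @export
print.typology_summary <- function(x, ...) {
  cat(sprintf("Country typology at alpha = %.2f\n", x$alpha))
  cat(sprintf("  bidirectional %d | unidirectional %d | none %d; %d distinct profiles\n",
              x$class_counts[["bidirectional"]],
              x$class_counts[["unidirectional"]],
              x$class_counts[["none"]], x$n_distinct_profiles))
  print(x$group_counts)
  invisible(x)
}

#' Long p-value table from computed pair results
#'
#' Collects the country-level p-values of a set of
#' `causality_pair_result` objects into the long format consumed by
#' [label_directions()].
#'
#' @param pair_results list of `causality_pair_result` (e.g. from
#'   [run_all_pairs()]).
#' @return data frame: country, direction, statistic, p_value.
#' @export
causality_pvalue_table <- function(pair_results) {
  rows <- list()
  for (pr in pair_results) {
    for (dn in names(pr$per_direction)) {
      d <- pr$per_direction[[dn]]
      rows[[length(rows) + 1L]] <- data.frame(
        country = d$countries$country, direction = dn,
        statistic = d$countries$statistic, p_value = d$countries$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
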