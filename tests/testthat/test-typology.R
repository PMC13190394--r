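pv_row <- function(country, direction, p)
  data.frame(country = country, direction = direction, p_value = p,
             stringsAsFactors = FALSE)

two_var_pvals <- function(p_ab, p_ba, country = "X") {
  rbind(pv_row(country, "A->B", p_ab), pv_row(country, "B->A", p_ba))
}

test_that("direction labels follow the inclusive threshold rule", {
  lab <- function(p1, p2)
    label_directions(two_var_pvals(p1, p2), alpha = 0.10)$label
  expect_equal(lab(0.002, 0.018), "Bidirectional")
  expect_equal(lab(0.5, 0.5), "None")
  expect_equal(lab(0.10, 0.11), "A->B")     # boundary inclusive at 0.10
  expect_equal(lab(0.11, 0.10), "B->A")
  expect_error(label_directions(two_var_pvals(.5, .5), alpha = 0.6),
               "alpha")
  expect_error(label_directions(pv_row("X", "A->B", 0.5)),
               "both directions")
})

# p-value table for one country across the three canonical pairs
three_pair_pvals <- function(country, p) {
  dirs <- c("CO2->MIGR", "MIGR->CO2", "HEXP->MIGR", "MIGR->HEXP",
            "HEXP->CO2", "CO2->HEXP")
  do.call(rbind, Map(pv_row, country, dirs, p))
}

test_that("country classes and dominant-source groups follow the rules", {
  hi <- 0.5; lo <- 0.01
  pv <- rbind(
    three_pair_pvals("Bi",   c(lo, lo, hi, hi, hi, hi)),  # bidirectional
    three_pair_pvals("Co2d", c(lo, hi, hi, hi, hi, lo)),  # CO2 source only
    three_pair_pvals("Recip", c(lo, hi, lo, hi, hi, hi)), # both -> MIGR
    three_pair_pvals("Multi", c(hi, hi, hi, lo, hi, lo)), # two sources, tgt HEXP
    three_pair_pvals("Quiet", rep(hi, 6)))                # nothing
  ty <- classify_countries(label_directions(pv))
  prof <- ty$profiles
  cls <- setNames(prof$class, prof$country)
  grp <- setNames(prof$group, prof$country)
  expect_equal(unname(cls[c("Bi", "Co2d", "Recip", "Multi", "Quiet")]),
               c("bidirectional", "unidirectional", "unidirectional",
                 "unidirectional", "none"))
  expect_equal(unname(grp[c("Bi", "Co2d", "Recip", "Multi", "Quiet")]),
               c("feedback", "CO2-dominant", "recipient", "multi-linkage",
                 "none"))
  expect_equal(sum(ty$class_counts), 5)
})

test_that("the summary is invariant to country order", {
  fx <- fixture_printed_tables()$countries
  ty1 <- classify_countries(label_directions(fx))
  set.seed(6)
  shuffled <- fx[sample(nrow(fx)), ]
  ty2 <- classify_countries(label_directions(shuffled))
  expect_equal(ty1$class_counts, ty2$class_counts)
  expect_equal(ty1$n_distinct_profiles, ty2$n_distinct_profiles)
  expect_equal(ty1$profile_table$countries[order(ty1$profile_table$labels)],
               ty2$profile_table$countries[order(ty2$profile_table$labels)])
})

test_that("all-None input yields a single profile and the none class", {
  pv <- do.call(rbind, lapply(c("A", "B", "C"),
                              function(ct) three_pair_pvals(ct, rep(0.9, 6))))
  ty <- classify_countries(label_directions(pv))
  expect_equal(unname(ty$class_counts),
               c(0L, 0L, 3L))
  expect_equal(ty$n_distinct_profiles, 1)
})

test_that("tightening alpha moves classes monotonically through unidirectional", {
  fx <- fixture_printed_tables()$countries
  grid <- c(0.20, 0.15, 0.10, 0.05, 0.02, 0.01)
  rank_of <- c(none = 0, unidirectional = 1, bidirectional = 2)
  prev <- NULL
  for (a in grid) {
    ty <- classify_countries(label_directions(fx, alpha = a))
    cur <- setNames(rank_of[ty$profiles$class], ty$profiles$country)
    if (!is.null(prev)) {
      # classes can only stay or step down as alpha shrinks, never jump
      # from none back up past unidirectional relative to a looser alpha
      expect_true(all(cur[names(prev)] <= prev))
    }
    prev <- cur
  }
})

test_that("interpretive regime names attach only where the mapping is clean", {
  fx <- fixture_printed_tables()$countries
  ty <- classify_countries(label_directions(fx))
  prof <- ty$profiles
  expect_equal(unique(prof$regime_interpretive[prof$group == "feedback"]),
               "integrated nexus")
  expect_equal(unique(prof$regime_interpretive[prof$group == "none"]),
               "decoupled")
  expect_true(all(is.na(prof$regime_interpretive[prof$group == "multi-linkage"])))
})
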