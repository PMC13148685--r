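test_that("component scores follow level / denominator x weight", {
  expect_equal(component_score(4, 4, 32.10), 32.10)
  expect_equal(hfvuln:::round_half_up(component_score(2, 3, 7.60), 2), 5.07)
  expect_equal(component_score(4, 5, 29.60), 23.68)
  expect_error(component_score(5, 4, 32.10), "out of range")
})

test_that("reproduction and literal aggregation modes differ only in the CTB denominator", {
  w <- afro47_weights()
  malawi_rep <- ordinal_dataset("Malawi", rbind(c(4, 5, 2, 4)),
                                c("che", "fad", "bsp", "ctb"),
                                c(4, 5, 3, 4), c(4, 5, 3, 5))
  expect_equal(hfvuln:::round_half_up(
    vulnerability_scores(malawi_rep, w)$v_score, 2), 91.55)
  malawi_lit <- ordinal_dataset("Malawi", rbind(c(4, 5, 2, 4)),
                                c("che", "fad", "bsp", "ctb"),
                                c(4, 5, 3, 4), c(4, 5, 3, 4))
  expect_equal(hfvuln:::round_half_up(
    vulnerability_scores(malawi_lit, w)$v_score, 2), 97.47)
  all_ones <- ordinal_dataset("X", rbind(c(1, 1, 1, 1)),
                              c("che", "fad", "bsp", "ctb"),
                              c(4, 5, 3, 4), c(4, 5, 3, 5))
  expect_equal(hfvuln:::round_half_up(
    vulnerability_scores(all_ones, w)$v_score, 2), 22.62)
})

test_that("archetype boundaries follow the reference label conventions", {
  expect_equal(as.character(categorize(c(0, 39.99, 40, 59.18, 59.49))),
               c("Low", "Low", "Moderate", "Moderate", "Moderate"))
  expect_equal(as.character(categorize(c(59.5, 59.83, 73))),
               c("High", "High", "High"))
  expect_equal(as.character(categorize(c(73.01, 73.35, 100))),
               rep("Very High", 3))
  expect_error(categorize(101), "\\[0, 100\\]")
})

test_that("v_score is the sum of component scores and strictly monotone in levels", {
  lev <- afro47_levels()
  w <- afro47_weights()
  sc <- vulnerability_scores(lev, w)
  comp_cols <- paste0(lev$factor_names, "_score")
  expect_equal(rowSums(sc[comp_cols]), sc$v_score, tolerance = 1e-9,
               ignore_attr = TRUE)
  # components never exceed their factor's weight
  for (j in seq_along(comp_cols))
    expect_true(all(sc[[comp_cols[j]]] <= w$weights[j] + 1e-12))
  # raising any one level strictly increases the score
  set.seed(91)
  for (rep in 1:25) {
    base <- sapply(lev$max_levels, function(m) sample(seq_len(m - 1), 1))
    j <- sample.int(length(base), 1)
    up <- base
    up[j] <- up[j] + 1L
    mk <- function(v) ordinal_dataset("x", rbind(v), lev$factor_names,
                                      lev$max_levels, lev$norm_denominators)
    expect_gt(vulnerability_scores(mk(up), w)$v_score,
              vulnerability_scores(mk(base), w)$v_score)
  }
})

test_that("reproduction-mode scores are bounded by the extreme profiles", {
  lev <- afro47_levels()
  w <- afro47_weights()
  sc <- vulnerability_scores(lev, w)
  lo <- 22.62
  hi <- 94.08  # all-max profile (4,5,3,4) with CTB normalized by 5
  expect_true(all(sc$v_score >= lo - 0.005 & sc$v_score <= hi + 0.005))
  mk <- function(v) ordinal_dataset("x", rbind(v), lev$factor_names,
                                    lev$max_levels, lev$norm_denominators)
  expect_equal(hfvuln:::round_half_up(
    vulnerability_scores(mk(c(4, 5, 3, 4)), w)$v_score, 2), 94.08)
})

test_that("summaries report footer statistics, counts and frequencies", {
  lev <- afro47_levels()
  sc <- vulnerability_scores(lev, afro47_weights())
  s <- summarize_scores(sc, lev)
  vrow <- s$stats[s$stats$column == "v_score", ]
  expect_equal(c(vrow$mean, vrow$min, vrow$max), c(59.54, 22.62, 91.55))
  expect_equal(unname(s$archetype_counts[c("Very High", "High")]), c(14, 13))
  expect_equal(unname(s$level_counts$bsp), c(15, 20, 12))
  single <- summarize_scores(sc[1, ])
  expect_equal(single$stats$mean, single$stats$min)
  expect_equal(single$stats$mean, single$stats$max)
})
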