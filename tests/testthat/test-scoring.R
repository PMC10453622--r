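wt_half <- 23.14

test_that("scores reproduce the published single-mutant score table", {
  expect_equal(activity_score(100), 100)
  expect_equal(activity_score(75.73), 75.73)
  expect_equal(activity_score(0), 0)
  expect_error(activity_score(-1), ">= 0")

  # R143L and S101V thermostability scores match the printed table at 2 d.p.
  expect_equal(round(thermostability_score(62.96, wt_half), 2), 272.08)
  expect_equal(round(thermostability_score(190.44, wt_half), 2), 822.99)
  expect_equal(thermostability_score(wt_half, wt_half), 100)
  expect_error(thermostability_score(0, wt_half), "positive")

  expect_equal(composite_score(100, 100), 10000)
  expect_equal(composite_score(272.0829, 75.73), 20604.41, tolerance = 5e-4)
  expect_equal(composite_score(1234, 0), 0)
  expect_error(composite_score(100, 100, w_thermo = -1), "non-negative")
})

test_that("composite score is symmetric and strictly increasing at unit weights", {
  set.seed(17)
  a <- stats::runif(50, 0, 1000)
  b <- stats::runif(50, 0, 1000)
  expect_equal(composite_score(a, b), composite_score(b, a))
  expect_true(all(composite_score(a + 1, b) > composite_score(a, b)))
  expect_true(all(composite_score(a, b + 1) > composite_score(a, b)))
  # exponent weights keep the wild type at 10,000 for any weight pair
  expect_equal(composite_score(100, 100, 0.7, 1.3), 10000)
})

test_that("recomputing the score table matches >= 12 of 15 printed composites", {
  meas <- pb92_single_mutants()
  sc <- score_mutants(meas)
  m <- merge(sc, meas[, c("mutant_id", "composite_score_reported")],
             by = "mutant_id")
  m <- m[m$mutant_id != "WT" & !is.na(m$composite_score), ]
  expect_equal(nrow(m), 15)
  rel <- abs(m$composite_score - m$composite_score_reported) /
    m$composite_score_reported
  expect_gte(sum(rel < 5e-4), 12)
  # wild type scores exactly (100, 100, 10000)
  wt <- sc[sc$mutant_id == "WT", ]
  expect_equal(c(wt$activity_score, wt$thermostability_score,
                 wt$composite_score), c(100, 100, 10000))
})

test_that("combination-mutant composites imply the reported activity retention", {
  cm <- pb92_complex_mutants()
  wt <- cm$t_half_min[cm$mutant_id == "WT"]
  m31 <- cm[cm$mutant_id == "M3-1", ]
  implied_activity <- m31$composite_score_reported /
    thermostability_score(m31$t_half_min, wt)
  expect_equal(implied_activity, 75.1, tolerance = 0.01)  # "more than 75%"
  expect_gt(implied_activity, 75)
})

test_that("per-site winners and advancement match the published selection", {
  sel <- select_per_site_best(score_mutants(pb92_single_mutants()))
  winners <- stats::setNames(sel$mutant_id, sel$group)
  expect_equal(winners[c("18", "97", "98", "99", "100", "143")],
               c(`18` = "N18L", `97` = "S97A", `98` = "G98R", `99` = "S99L",
                 `100` = "G100A", `143` = "R143L"))
  expect_true(all(sel$advanced[sel$group %in% c(18, 97, 98, 99, 100, 143)]))
  expect_false(any(sel$advanced[sel$group %in% c(101, 110)]))
})

test_that("winner selection equals an exhaustive max oracle on random tables", {
  set.seed(23)
  for (rep in 1:10) {
    ids <- c("WT", paste0(sample(c("A", "G", "S"), 12, TRUE),
                          rep(1:4, each = 3),
                          c("L", "V", "K")))
    sc <- data.frame(mutant_id = ids,
                     activity_score = c(100, stats::runif(12, 0, 120)),
                     thermostability_score = c(100, stats::runif(12, 50, 900)),
                     stringsAsFactors = FALSE)
    sc$composite_score <- sc$thermostability_score * sc$activity_score
    sel <- select_per_site_best(sc)
    for (g in sel$group) {
      pos <- as.integer(g)
      members <- ids[-1][as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1",
                                        ids[-1])) == pos]
      best <- -Inf; best_id <- NULL  # exhaustive scan
      for (id in members) {
        cs <- sc$composite_score[sc$mutant_id == id]
        ts <- sc$thermostability_score[sc$mutant_id == id]
        key <- c(cs, ts)
        if (is.null(best_id) || cs > best[1] ||
            (cs == best[1] && ts > best[2]) ||
            (cs == best[1] && ts == best[2] && id < best_id)) {
          best <- key; best_id <- id
        }
      }
      expect_equal(sel$mutant_id[sel$group == g], best_id)
    }
  }
})

test_that("single-member groups win trivially and ties break deterministically", {
  sc <- data.frame(
    mutant_id = c("WT", "A5L", "A5V", "G9K"),
    activity_score = c(100, 50, 100, 80),
    thermostability_score = c(100, 200, 100, 90),
    stringsAsFactors = FALSE)
  sc$composite_score <- sc$activity_score * sc$thermostability_score
  sel <- select_per_site_best(sc)
  expect_equal(sel$mutant_id[sel$group == "9"], "G9K")  # single member
  # 5: both composites 10000; A5L has higher thermostability score
  expect_equal(sel$mutant_id[sel$group == "5"], "A5L")
  expect_false(sel$advanced[sel$group == "5"])  # no improvement over WT
})

test_that("combination plans enumerate base, base+each, base+all", {
  plan <- propose_combinations(c("N18L", "S97A", "G98R", "S99L", "G100A",
                                 "R143L"), loop = 97:100)
  expect_equal(plan$proposals$id, c("M2", "M3-1", "M3-2", "M3-3", "M3-4", "M6"))
  expect_equal(plan$proposals$mutant_id,
               c("N18L/R143L",
                 "N18L/R143L/S97A", "N18L/R143L/G98R", "N18L/R143L/S99L",
                 "N18L/R143L/G100A",
                 "N18L/R143L/S97A/G98R/S99L/G100A"))
  # every proposal contains all base substitutions, no duplicated positions
  for (m in plan$proposals$mutant_id) {
    subs <- parse_substitutions(m)[[1]]
    expect_true(all(c(18L, 143L) %in% subs$pos))
    expect_false(anyDuplicated(subs$pos) > 0)
  }

  # empty loop: the base alone
  p0 <- propose_combinations(c("N18L", "R143L"))
  expect_equal(p0$proposals$mutant_id, "N18L/R143L")

  # count formula: g loop winners -> g + 2 proposals (g >= 2)
  for (g in 2:4) {
    w <- c("N18L", paste0("S", 96 + seq_len(g), "A"))
    p <- propose_combinations(w, loop = 96 + seq_len(g))
    expect_equal(nrow(p$proposals), g + 2)
  }

  expect_error(propose_combinations(c("N18L", "A18V")), "overlapping")
  expect_error(propose_combinations(c("N18L"), loop = 99), "not among")
})
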