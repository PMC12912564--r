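make_items <- function(typical, pandemic, items = paste0("item", seq_along(typical))) {
  n_subj <- nrow(as.matrix(typical))
  typical <- matrix(typical, nrow = n_subj)
  pandemic <- matrix(pandemic, nrow = n_subj)
  dplyr::bind_rows(lapply(seq_len(ncol(typical)), function(j) {
    tibble::tibble(
      subject_id = rep(sprintf("s%02d", seq_len(n_subj)), 2),
      item_id = items[j],
      phase = rep(c("typical", "pandemic"), each = n_subj),
      response = c(typical[, j], pandemic[, j])
    )
  }))
}

test_that("scores are phase sums with exact change arithmetic", {
  tab <- make_items(matrix(3, 1, 10), matrix(2, 1, 10))
  sc <- score_leq(tab)
  expect_equal(sc$typical, 30)
  expect_equal(sc$pandemic, 20)
  expect_equal(sc$change, 10)
  zero <- score_leq(make_items(matrix(0, 2, 4), matrix(0, 2, 4)))
  expect_equal(zero$typical, c(0, 0))
  expect_equal(zero$change, c(0, 0))
  same <- score_leq(make_items(matrix(2:5, 1, 4), matrix(2:5, 1, 4)))
  expect_equal(same$change, 0)
})

test_that("scoring is invariant to item order and honours exclusions/weights", {
  tab <- make_items(matrix(c(1, 4, 2), 1, 3), matrix(c(0, 3, 1), 1, 3))
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(score_leq(tab)$typical, score_leq(shuffled)$typical)
  ex <- score_leq(tab, exclusions = "item2")
  expect_equal(ex$typical, 3)
  expect_equal(ex$pandemic, 1)
  w <- score_leq(tab, weights = c(item1 = 2))
  expect_equal(w$typical, 2 * 1 + 4 + 2)
  # increasing any pandemic response strictly decreases the change score
  tab2 <- tab
  i <- which(tab2$phase == "pandemic")[1]
  tab2$response[i] <- tab2$response[i] + 1
  expect_lt(score_leq(tab2)$change, score_leq(tab)$change)
})

test_that("incomplete subjects are flagged and out-of-range rows rejected", {
  tab <- make_items(matrix(2, 3, 4), matrix(1, 3, 4))
  tab <- tab[!(tab$subject_id == "s02" & tab$item_id == "item3" &
                 tab$phase == "pandemic"), ]
  sc <- score_leq(tab)
  expect_false(sc$complete[sc$subject_id == "s02"])
  expect_true(is.na(sc$change[sc$subject_id == "s02"]))
  expect_true(all(sc$complete[sc$subject_id != "s02"]))
  bad <- make_items(matrix(2, 1, 2), matrix(1, 1, 2))
  bad$response[1] <- 7
  expect_error(score_leq(bad), "0-5")
})

test_that("item-level tests use the Bonferroni level from the item count", {
  it <- generate_lifestyle_items(n_subjects = 30, seed = 19)
  tests <- item_change_tests(it)
  expect_equal(nrow(tests), 17)
  expect_equal(attr(tests, "alpha_bonferroni"), 0.05 / 17)
  expect_equal(round(0.05 / 17, 4), 0.0029)
  # degenerate all-tied item is flagged, never significant
  tied <- make_items(matrix(3, 10, 2), matrix(c(rep(3, 10), rep(1, 10)), 10, 2))
  tt <- item_change_tests(tied, min_pairs = 5)
  expect_true(tt$degenerate[tt$item_id == "item1"])
  expect_false(tt$significant[tt$item_id == "item1"])
  expect_error(item_change_tests(make_items(matrix(1, 3, 2),
                                            matrix(0, 3, 2))),
               "at least")
})
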