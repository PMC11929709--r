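masked_from_values <- function(values, h = length(values), w = 1,
                               class_id = "object") {
  # one column of object pixels carrying the given own-class probabilities
  pm <- probability_map(matrix(values, h, w))
  lm <- label_mask(matrix(1L, h, w))
  mask_by_class(pm, lm, class_id)
}

test_that("select_k_best keeps the k largest own-class probabilities", {
  mk <- masked_from_values(c(0.9, 0.8, 0.7))
  sel <- select_k_best(mk, 2)
  expect_equal(sort(sel$pixels$value, decreasing = TRUE), c(0.9, 0.8))

  # fewer candidates than k: all returned, with a warning
  mk2 <- masked_from_values(c(0.3, 0.6))
  expect_warning(sel2 <- select_k_best(mk2, 5), class = "antl_short_support")
  expect_equal(nrow(sel2$pixels), 2)

  # tie at the k-th rank: first row-major coordinate wins
  pm <- probability_map(matrix(0.6, 2, 2))
  lm <- label_mask(matrix(1L, 2, 2))
  tie <- select_k_best(mask_by_class(pm, lm, "object"), 1)
  expect_equal(c(tie$pixels$row, tie$pixels$col), c(1L, 1L))

  expect_error(select_k_best(mk, 0), "positive integer")
  empty <- mask_by_class(pm, label_mask(matrix(0L, 2, 2)), "object")
  expect_warning(e <- select_k_best(empty, 1), class = "antl_empty_support")
  expect_equal(nrow(e$pixels), 0)
})

test_that("select_k_best is rank-based (invariant to monotone transforms)", {
  set.seed(21)
  for (rep in 1:20) {
    v <- runif(15)
    mk <- masked_from_values(v)
    mk2 <- masked_from_values(sqrt(v))  # strictly monotone on [0, 1]
    s1 <- select_k_best(mk, 4)
    s2 <- select_k_best(mk2, 4)
    expect_equal(s1$pixels[c("row", "col")], s2$pixels[c("row", "col")])
  }
})

test_that("select_k_hard follows the adaptive widening schedule", {
  # found in the first round at the initial interval (0.5, 0.55)
  mk <- masked_from_values(c(0.52, 0.54, 0.90))
  s <- select_k_hard(mk, 2)
  expect_setequal(s$pixels$value, c(0.52, 0.54))
  expect_equal(attr(s, "final_bounds")[["upper"]], 0.55)

  # two upper-bound widenings: 0.55 -> 0.60 -> 0.65
  mk2 <- masked_from_values(c(0.62, 0.63))
  s2 <- select_k_hard(mk2, 2)
  expect_setequal(s2$pixels$value, c(0.62, 0.63))
  expect_equal(attr(s2, "final_bounds")[["upper"]], 0.65)

  # all pixels mispredicted: the lower bound falls 0.50 -> 0.45 -> 0.40,
  # then 0.40 < 0.45 < 0.55 admits the pixel
  mk3 <- masked_from_values(c(0.40, 0.45))
  s3 <- select_k_hard(mk3, 1)
  expect_equal(s3$pixels$value, 0.45)
  expect_equal(attr(s3, "final_bounds")[["lower"]], 0.40)

  # a probability of exactly 1 is admitted in the final half-open round
  mk4 <- masked_from_values(c(1, 1, 1))
  s4 <- select_k_hard(mk4, 2)
  expect_equal(nrow(s4$pixels), 2)

  # bounds are strict: a value at the bound is excluded
  mk5 <- masked_from_values(c(0.55, 0.53))
  s5 <- select_k_hard(mk5, 1)
  expect_equal(s5$pixels$value, 0.53)

  # exhaustion: only a value of exactly 0 exists beyond the candidates
  mk6 <- masked_from_values(c(0, 0.7))
  expect_warning(s6 <- select_k_hard(mk6, 2), class = "antl_interval_exhausted")
  expect_equal(s6$pixels$value, 0.7)

  no_obj <- mask_by_class(
    probability_map(matrix(0.4, 2, 2)), label_mask(matrix(0L, 2, 2)), "object"
  )
  expect_warning(e <- select_k_hard(no_obj, 1), class = "antl_empty_support")
  expect_equal(nrow(e$pixels), 0)
})

test_that("random down-selection to k is seeded and reproducible", {
  set.seed(5)
  v <- runif(40, 0.51, 0.54)  # everything inside the first interval
  mk <- masked_from_values(v)
  a <- select_k_hard(mk, 5, rng_seed = 7)
  b <- select_k_hard(mk, 5, rng_seed = 7)
  c <- select_k_hard(mk, 5, rng_seed = 8)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
  expect_equal(nrow(a$pixels), 5)
  expect_equal(nrow(attr(a, "candidates")), 40)
  # selection is a subset of the candidate set
  expect_true(all(a$pixels$value %in% attr(a, "candidates")$value))
})

test_that("pre-subsampling candidates match the brute-force widening oracle", {
  set.seed(99)
  for (rep in 1:300) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    case <- random_case(h, w, object_frac = runif(1, 0.1, 0.9))
    cls <- sample(c("object", "background"), 1)
    mk <- mask_by_class(case$probs, case$labels, cls)
    k <- sample(1:12, 1)
    got <- suppressWarnings(select_k_hard(mk, k, rng_seed = rep))
    want <- brute_force_hard_candidates(mk, k)
    expect_identical(attr(got, "candidates"), want)
    # hard values lie strictly inside the final interval
    b <- attr(got, "final_bounds")
    if (nrow(got$pixels) > 0) {
      expect_true(all(got$pixels$value > b["lower"] & got$pixels$value < b["upper"]))
    }
  }
})

test_that("search_interval validates its bounds", {
  expect_error(search_interval(0.6, 0.5), "lower < upper")
  expect_error(search_interval(step = 0), "positive")
  expect_silent(search_interval(0, 1, 0.1))
})
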