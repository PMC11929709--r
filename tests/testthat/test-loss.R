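# A 2x4 grid: columns 1-2 object, 3-4 background, with object-channel
# values chosen so the set means are easy to write down by hand.
term_fixture <- function(p_object) {
  list(
    probs = probability_map(p_object),
    labels = label_mask(matrix(rep(c(1L, 1L, 0L, 0L), each = 2), 2, 4))
  )
}

test_that("antl_term reproduces hand-computed arithmetic", {
  # A = 1.0 (anchor), P = 0.8, N = 0.1 on the object channel
  fx <- term_fixture(matrix(c(1.0, 1.0, 0.8, 0.8, 0.1, 0.1, 0.5, 0.5), 2, 4))
  anchors <- make_sel("object", "best", c(1L, 2L), c(1L, 1L), c(1, 1))
  positives <- make_nb("object", c(1L, 2L), c(2L, 2L), c(0.8, 0.8))
  negatives <- make_nb("background", c(1L, 2L), c(3L, 3L), c(0.9, 0.9))
  # (1 - 0.8)^2 - (1 - 0.1)^2 + 1 = 0.04 - 0.81 + 1 = 0.23
  expect_equal(
    antl_term(anchors, positives, negatives, fx$probs, delta = 1),
    0.23, tolerance = 1e-12
  )

  # ideal object-anchor case: A = 1, P = 1, N = 0, delta = 1 -> 0
  fx2 <- term_fixture(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2, 4))
  pos2 <- make_nb("object", c(1L, 2L), c(2L, 2L), c(1, 1))
  neg2 <- make_nb("background", c(1L, 2L), c(3L, 3L), c(1, 1))
  expect_identical(antl_term(anchors, pos2, neg2, fx2$probs, delta = 1), 0)

  # maximally bad negatives: N at the anchor value -> 0 - 0 + 1 = 1
  fx3 <- term_fixture(matrix(1, 2, 4))
  expect_equal(antl_term(anchors, pos2, neg2, fx3$probs, delta = 1), 1)

  # hinge clamps below at zero; without it the raw value is returned
  fx4 <- term_fixture(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2, 4))
  expect_identical(
    antl_term(anchors, pos2, neg2, fx4$probs, delta = 0.5, hinge = TRUE), 0
  )
  expect_equal(
    antl_term(anchors, pos2, neg2, fx4$probs, delta = 0.5, hinge = FALSE), -0.5
  )

  # degenerate sets: empty positives -> 0 with a warning
  empty_nb <- make_nb("object", integer(0), integer(0), numeric(0), integer(0))
  expect_warning(
    z <- antl_term(anchors, empty_nb, neg2, fx2$probs),
    class = "antl_empty_triplet"
  )
  expect_identical(z, 0)

  # class contract
  expect_error(antl_term(anchors, neg2, pos2, fx2$probs), "class")
})

test_that("antl_term is monotone in how far positives/negatives sit from the anchors", {
  anchors <- make_sel("object", "best", c(1L, 2L), c(1L, 1L), c(1, 1))
  pos <- make_nb("object", c(1L, 2L), c(2L, 2L), c(0.8, 0.8))
  neg <- make_nb("background", c(1L, 2L), c(3L, 3L), c(0.9, 0.9))
  term_at <- function(p_val, n_val) {
    fx <- term_fixture(matrix(c(1, 1, p_val, p_val, n_val, n_val, 0.5, 0.5), 2, 4))
    antl_term(anchors, pos, neg, fx$probs, delta = 1, hinge = FALSE)
  }
  # negatives moving toward the anchor mean increase the term
  n_path <- vapply(seq(0.1, 0.9, by = 0.2), function(n) term_at(0.8, n), numeric(1))
  expect_true(all(diff(n_path) > 0))
  # positives moving toward the anchor mean decrease it
  p_path <- vapply(seq(0.3, 0.9, by = 0.2), function(p) term_at(p, 0.1), numeric(1))
  expect_true(all(diff(p_path) < 0))
})

test_that("cross_entropy matches closed forms and clips at 1e-7", {
  one <- function(S, g) {
    cross_entropy(probability_map(matrix(S, 1, 1)), label_mask(matrix(g, 1, 1)))
  }
  expect_equal(one(0.5, 1L), log(2), tolerance = 1e-9)
  expect_equal(one(0.5, 0L), log(2), tolerance = 1e-9)
  expect_equal(one(0, 1L), -log(1e-7), tolerance = 1e-9)   # clipped worst case
  expect_lte(one(1, 1L), 1.1e-7)                           # perfect prediction
  expect_equal(one(0.2, 0L), -log(0.8), tolerance = 1e-12)
  # mean over pixels
  pm <- probability_map(matrix(c(0.5, 1), 1, 2))
  lm <- label_mask(matrix(c(1L, 1L), 1, 2))
  expect_equal(cross_entropy(pm, lm), (log(2) - log(1 - 1e-7)) / 2)
})

test_that("the composite loss obeys its own accounting identity", {
  set.seed(51)
  m <- make_mask(blob_spec(24, 24, radius_range = c(5, 8), seed = 3))
  pm <- make_prediction(m, corruption_spec(boundary_band = 2, seed = 4))
  for (alpha in c(0, 0.015, 0.3)) {
    cfg <- antl_config(k = 5, alpha = alpha, rng_seed = 2)
    b <- antl_loss(pm, m, cfg)
    expect_equal(
      b$total, alpha * (b$l_antl_object + b$l_antl_background) + b$l_ce,
      tolerance = 1e-9
    )
    expect_true(all(is.finite(unlist(b[c(
      "l_antl_object", "l_antl_background", "l_ce", "total"
    )]))))
  }
  # alpha = 0 reduces the total to cross-entropy exactly
  b0 <- antl_loss(pm, m, antl_config(alpha = 0, rng_seed = 2))
  expect_identical(b0$total, b0$l_ce)
  # linear response in alpha for a fixed seed
  b1 <- antl_loss(pm, m, antl_config(alpha = 1, rng_seed = 2))
  b2 <- antl_loss(pm, m, antl_config(alpha = 0.25, rng_seed = 2))
  expect_equal(
    b2$total - b0$total,
    0.25 * (b1$l_antl_object + b1$l_antl_background),
    tolerance = 1e-9
  )
})

test_that("a perfect prediction zeroes both ANTL terms at delta = 1", {
  for (seed in c(2, 9, 17)) {
    m <- make_mask(blob_spec(32, 32, radius_range = c(6, 10), seed = seed))
    b <- antl_loss(perfect_prediction(m), m, antl_config(rng_seed = seed))
    expect_identical(b$l_antl_object, 0)
    expect_identical(b$l_antl_background, 0)
    expect_lt(b$total, 1e-6)
  }
})

test_that("relabeling object<->background with swapped channels swaps the terms", {
  m <- make_mask(blob_spec(28, 28, radius_range = c(6, 9), seed = 13))
  pm <- make_prediction(m, corruption_spec(seed = 14))
  swapped_probs <- probability_map(pm$p_background, pm$p_object)
  swapped_labels <- label_mask(1L - m$label)
  cfg <- antl_config(rng_seed = 6)
  a <- antl_loss(pm, m, cfg)
  b <- antl_loss(swapped_probs, swapped_labels, cfg)
  # identical selections by construction; valuation channels swap, so the
  # agreement is exact up to summation of 1 - x in floating point
  expect_equal(a$l_antl_object, b$l_antl_background, tolerance = 1e-12)
  expect_equal(a$l_antl_background, b$l_antl_object, tolerance = 1e-12)
})

test_that("an image missing one class zeroes both triplet terms with warnings", {
  lab <- label_mask(matrix(0L, 8, 8))
  pm <- probability_map(matrix(0.1, 8, 8))
  warns <- character(0)
  b <- withCallingHandlers(
    antl_loss(pm, lab, antl_config(k = 3)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  expect_identical(b$l_antl_object, 0)
  expect_identical(b$l_antl_background, 0)
  expect_identical(b$total, b$l_ce)
  expect_true(length(warns) > 0)
})

test_that("batches reduce by unweighted mean over images", {
  m1 <- make_mask(blob_spec(20, 20, radius_range = c(4, 7), seed = 1))
  m2 <- make_mask(blob_spec(20, 20, radius_range = c(4, 7), seed = 2))
  p1 <- make_prediction(m1, corruption_spec(seed = 1))
  p2 <- make_prediction(m2, corruption_spec(seed = 2))
  cfg <- antl_config(k = 4, rng_seed = 3)
  single <- lapply(list(list(p1, m1), list(p2, m2)),
                   function(x) antl_loss(x[[1]], x[[2]], cfg))
  batch <- antl_loss(list(p1, p2), list(m1, m2), cfg)
  for (f in c("l_antl_object", "l_antl_background", "l_ce", "total")) {
    expect_equal(batch[[f]], mean(c(single[[1]][[f]], single[[2]][[f]])))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(61)
  for (rep in 1:3) {
    case <- random_case(16, 16)
    cfg <- antl_config(k = 4, alpha = 0.5, rng_seed = rep)
    rep_out <- gradient_check(case$probs, case$labels, cfg,
                              n_points = 80, seed = rep)
    expect_gt(rep_out$n_checked, 0)
    expect_lt(rep_out$max_discrepancy, 1e-5)
  }
  # alpha = 0: the gradient is exactly the cross-entropy closed form
  case <- random_case(12, 12)
  cfg0 <- antl_config(alpha = 0)
  sel <- suppressWarnings(freeze_selections(case$probs, case$labels, cfg0))
  g <- antl_gradient(case$probs, case$labels, sel, cfg0)
  S <- case$probs$p_object
  lab <- case$labels$label
  expect_equal(g, (S - lab) / (S * (1 - S)) / 144, tolerance = 1e-12)
})

test_that("antl_config validates its fields", {
  expect_error(antl_config(k = 0), "positive")
  expect_error(antl_config(delta = -1), "non-negative")
  expect_error(antl_config(alpha = -0.1), "non-negative")
  expect_error(antl_config(num_layers = 0), "positive")
  expect_error(antl_config(hinge = NA), "TRUE or FALSE")
  cfg <- antl_config()
  expect_equal(cfg$k, 10L)
  expect_equal(cfg$delta, 1)
  expect_equal(cfg$interval$lower, 0.5)
  expect_equal(cfg$interval$upper, 0.55)
})
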