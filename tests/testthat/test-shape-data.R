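test_that("read_tps multiplies raw coordinates by the record scale", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c(
    "LM=3", "2 4", "6 8", "10 0", "ID=alpha", "SCALE=0.5",
    "LM=3", "1 1", "2 2", "3 3", "ID=beta", "SCALE=2"), f)
  lms <- read_tps(f)
  a <- lms[lms$specimen_id == "alpha", ]
  expect_equal(cbind(a$x, a$y),
               cbind(c(1, 3, 5), c(2, 4, 0)), ignore_attr = TRUE)
  b <- lms[lms$specimen_id == "beta", ]
  expect_equal(b$x, c(2, 4, 6))
  expect_equal(unique(lms$specimen_id), c("alpha", "beta"))  # file order
})

test_that("a record without a SCALE line falls back to scale 1 with a warning", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=2", "3 4", "5 6", "ID=no_scale"), f)
  expect_warning(lms <- read_tps(f), "SCALE")
  expect_equal(lms$scale, c(1, 1))
  expect_equal(lms$x, c(3, 5))
})

test_that("TPS parse errors name the offending record or line", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LMX=3", "1 2"), f)
  expect_error(read_tps(f), "malformed TPS count header")
  writeLines(c("LM=3", "1 2", "3 4", "ID=short"), f)
  expect_error(read_tps(f), "declared 3 landmarks but found 2")
})

test_that("write_tps then read_tps is the identity to 1e-9 mm", {
  lms <- random_landmarks(n_spec = 3, p = 12, seed = 7)
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(lms, f)
  back <- read_tps(f)
  expect_lt(max(abs(back$x - lms$x)), 1e-9)
  expect_lt(max(abs(back$y - lms$y)), 1e-9)
  expect_equal(back$specimen_id, lms$specimen_id)
})

test_that("write_tps refuses invalid input", {
  lms <- random_landmarks(1, 5)
  lms$x[2] <- NaN
  expect_error(write_tps(lms, tempfile()), "finite")
  expect_error(write_tps(lms[0, ], tempfile()), "empty")
})

test_that("variant totals match the preset designs", {
  expect_identical(validate_variant(variant_spec("a")), 52L)
  expect_identical(validate_variant(variant_spec("b")), 76L)
  expect_identical(validate_variant(variant_spec("c")), 206L)
  expect_identical(validate_variant(variant_spec("d")), 230L)
  # components recompute the totals
  expect_identical(
    validate_variant(variant_spec("a", n_traditional = 10, n_curves = 6,
                                  points_per_curve = 7)), 52L)
  expect_identical(
    validate_variant(variant_spec("d", n_traditional = 21, n_curves = 19,
                                  points_per_curve = 11)), 230L)
})

test_that("degenerate and contradictory variants are rejected", {
  expect_error(variant_spec("tiny", 0, 0, 0), "at least 3")
  expect_error(variant_spec("a", n_traditional = 11), "must total 52")
  expect_error(variant_spec("x", -1, 2, 3), "non-negative")
})

test_that("validate_variant equals brute-force per-point kind counting", {
  for (v in c("a", "b")) {
    spec <- variant_spec(v)
    lms <- template_landmarks(make_template(spec))
    expect_identical(nrow(lms), as.integer(validate_variant(spec)))
    expect_identical(sum(lms$kind == "traditional"),
                     as.integer(spec$n_traditional))
    expect_identical(sum(lms$kind == "semilandmark"),
                     as.integer(spec$n_curves * spec$points_per_curve))
    # semilandmark curves are contiguous runs of the declared length
    runs <- rle(lms$curve[lms$kind == "semilandmark"])
    expect_true(all(runs$lengths == spec$points_per_curve))
  }
})

test_that("subset_to_variant reduces nested designs and validates mapping", {
  spec_d <- variant_spec("d")
  spec_a <- variant_spec("a")
  lms <- dplyr::bind_rows(
    template_landmarks(make_template(spec_d), "s1"),
    template_landmarks(make_template(spec_d), "s2"))
  mapping <- seq_len(52)
  out <- subset_to_variant(lms, spec_a, mapping)
  expect_equal(max(out$point), 52)
  expect_equal(sum(out$kind == "traditional"), 2 * 10)
  # identity mapping preserves coordinates
  spec_same <- variant_spec("same", 230, 0, 0)
  idt <- subset_to_variant(lms, spec_same, seq_len(230))
  expect_equal(idt$x, lms$x)
  expect_error(subset_to_variant(lms, spec_a, c(seq_len(51), 9999)),
               "out-of-range")
  expect_error(subset_to_variant(lms, spec_a, seq_len(10)), "needs 52")
})

test_that("subsetting commutes with rigid motions of the configurations", {
  spec_a <- variant_spec("a")
  lms <- template_landmarks(make_template(), "s1")
  target <- variant_spec("sub", 5, 0, 0)
  mapping <- c(1, 10, 20, 30, 40)
  moved <- lms
  xy <- rigid_motion(cbind(lms$x, lms$y), 0.7, c(12, -3), 1.5)
  moved$x <- xy[, 1]; moved$y <- xy[, 2]
  sub_then_move <- subset_to_variant(lms, target, mapping)
  xy2 <- rigid_motion(cbind(sub_then_move$x, sub_then_move$y),
                      0.7, c(12, -3), 1.5)
  move_then_sub <- subset_to_variant(moved, target, mapping)
  expect_equal(cbind(move_then_sub$x, move_then_sub$y), xy2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("landmark CSV export carries the documented schema", {
  lms <- random_landmarks(2, 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(lms, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_named(back, c("specimen_id", "taxon_id", "point_index", "kind",
                       "curve", "x_mm", "y_mm"))
  expect_equal(back$x_mm, lms$x)
})
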