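test_that("the reference design enumerates 25 factorial runs plus replicates", {
  D <- ref_design(0L)
  expect_equal(nrow(D$values), 25L)
  expect_false(any(D$is_replicate))

  D5 <- ref_design(5L)
  expect_equal(nrow(D5$values), 30L)
  expect_equal(sum(D5$is_replicate), 5L)
  # replicate rows sit at coded zero for every factor
  expect_true(all(D5$coded[D5$is_replicate, ] == 0))
  expect_true(all(D5$values[D5$is_replicate, c("pH", "temperature")] == 0))
  # intercept column all ones
  expect_true(all(D5$values[, "1"] == 1))
})

test_that("coded levels map to the real pH and temperature settings", {
  ph <- factor_spec("pH", center = 3.75, step = 0.25)
  tc <- factor_spec("temperature", center = 40.0, step = 2.5)
  expect_equal(coded_to_real(2, ph), 4.25)
  expect_equal(coded_to_real(-2, ph), 3.25)
  expect_equal(coded_to_real(0, tc), 40.0)
  expect_equal(coded_to_real(2, tc), 45.0)
  expect_equal(coded_to_real(0, ph), ph$center)
  expect_error(coded_to_real(3, ph), "outside declared levels")
})

test_that("coded_to_real is affine in the coded level", {
  f <- factor_spec("x", center = 7.5, step = 0.4, coded_levels = -2L:2L)
  for (a in -1:1) for (b in -1:1) {
    expect_equal(coded_to_real(a, f) + coded_to_real(b, f) - f$center,
                 coded_to_real(a + b, f))
  }
})

test_that("term expansion produces the documented row layout", {
  terms <- c("1", "pH", "temperature", "pH^2", "temperature^2",
             "pH:temperature")
  fn <- c("pH", "temperature")
  expect_equal(unname(expand_terms(c(-2, 1), terms, fn)),
               c(1, -2, 1, 4, 1, -2))
  expect_equal(unname(expand_terms(c(0, 0), terms, fn)),
               c(1, 0, 0, 0, 0, 0))
  expect_error(expand_terms(c(1), terms, fn), "one coded value per factor")
})

test_that("linear columns of the full factorial are mutually orthogonal", {
  D <- ref_design(5L)
  # brute-force dot products over the enumerated rows
  expect_equal(sum(D$values[, "pH"] * D$values[, "temperature"]), 0)
  expect_equal(sum(D$values[, "pH"]), 0)
  expect_equal(sum(D$values[, "temperature"]), 0)
  expect_equal(sum(D$values[, "pH"] * D$values[, "1"]), 0)
})

test_that("a minimal one-factor two-level design has the expected rows", {
  D <- build_design(toy_one_factor(levels = c(-1L, 1L)))
  expect_equal(unname(D$values), rbind(c(1, -1), c(1, 1)))
})

test_that("row count equals the product of level counts plus replicates", {
  set.seed(101)
  for (i in 1:8) {
    n_fac <- sample(1:3, 1)
    specs <- lapply(seq_len(n_fac), function(j) {
      lv <- sort(sample(-3:3, sample(2:4, 1)))
      if (!0 %in% lv) lv <- sort(c(lv, 0L))
      factor_spec(paste0("f", j), center = runif(1, 1, 50),
                  step = runif(1, 0.1, 3), coded_levels = lv)
    })
    reps <- sample(0:4, 1)
    terms <- c("1", vapply(specs, `[[`, character(1), "name"))
    D <- build_design(design_spec(specs, center_replicates = reps,
                                  model_terms = terms))
    expected <- prod(vapply(specs, function(s) length(s$coded_levels),
                            integer(1))) + reps
    expect_equal(nrow(D$values), expected)
    # every linear coded column of the factorial block sums over a full
    # cycle structure; check orthogonality to the intercept on symmetric
    # level sets only when levels are symmetric
  }
})

test_that("run order is deterministic with the first factor outermost", {
  D <- ref_design(0L)
  # first factor (pH) held at -2 for the first 5 rows
  expect_equal(unname(D$coded[1:5, "pH"]), rep(-2, 5))
  expect_equal(unname(D$coded[1:5, "temperature"]), -2:2)
})

test_that("invalid specs are rejected", {
  expect_error(design_spec(list()), "non-empty list")
  f <- factor_spec("a", 0, 1)
  expect_error(design_spec(list(f), model_terms = c("1", "b")),
               "refers to no declared factor")
  expect_error(design_spec(list(f), model_terms = c("1", "a:b")),
               "refers to no declared factor")
  expect_error(design_spec(list(f), model_terms = c("a", "1")),
               "must come first")
  expect_error(design_spec(list(f), model_terms = c("1", "a", "a")),
               "duplicate")
  expect_error(factor_spec("a", 0, -1), "positive")
  expect_error(factor_spec("a", 0, 1, coded_levels = c(2, 1)),
               "strictly increasing")
  no_center <- factor_spec("a", 0, 1, coded_levels = c(-1L, 1L))
  expect_error(design_spec(list(no_center), center_replicates = 2),
               "0 is not a coded level")
})

test_that("design specs round-trip through YAML and JSON config files", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "factors:",
    "  - name: pH",
    "    center: 3.75",
    "    step: 0.25",
    "  - name: temperature",
    "    center: 40.0",
    "    step: 2.5",
    "center_replicates: 5"
  ), yml)
  spec <- read_design_spec(yml)
  expect_equal(build_design(spec)$values, ref_design(5L)$values)

  jsn <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"factors":[{"name":"pH","center":3.75,"step":0.25},',
    '{"name":"temperature","center":40.0,"step":2.5}],',
    '"center_replicates":5}'), jsn)
  spec2 <- read_design_spec(jsn)
  expect_equal(build_design(spec2)$values, ref_design(5L)$values)
})

test_that("design CSV export carries term labels and run labels", {
  path <- tempfile(fileext = ".csv")
  write_design_csv(ref_design(5L), path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(names(df)[1], "run")
  expect_true(all(c("1", "pH", "pH:temperature", "is_replicate") %in%
                    names(df)))
  expect_equal(nrow(df), 30L)
})
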