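test_that("read-write-read round trip is lossless", {
  obs <- make_obs(3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, f1)
  back <- read_observations(f1)
  expect_equal(as.data.frame(back), as.data.frame(obs),
    tolerance = 1e-12, ignore_attr = TRUE)
  write_observations(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("enums are normalized case-insensitively", {
  obs <- make_obs(2)
  obs$crop <- c("WHEAT", "Wheat")
  obs$pathway <- c("nh3", "NH3")
  obs$n_source <- c("Urea", "UREA")
  f <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, f)
  back <- read_observations(f)
  expect_equal(back$crop, c("wheat", "wheat"))
  expect_equal(back$pathway, c("NH3", "NH3"))
  expect_equal(back$n_source, c("urea", "urea"))
})

test_that("missing mandatory column raises a schema error", {
  obs <- make_obs(2)
  obs$crop <- NULL
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(obs, f)
  expect_error(read_observations(f), class = "nrimpact_schema_error")
})

test_that("invalid rows raise row-indexed validation errors or are dropped", {
  obs <- make_obs(3)
  obs$yield_treat_mean[2] <- 0
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(obs, f)
  expect_error(read_observations(f),
    regexp = "row 2", class = "nrimpact_validation_error"
  )
  back <- suppressWarnings(read_observations(f, on_invalid = "drop"))
  expect_equal(nrow(back), 2)
  diag <- attr(back, "diagnostics")
  expect_equal(unique(diag$row), 2L)
  expect_match(diag$column, "yield_treat_mean", all = FALSE)
})

test_that("reported dispersions are preserved untransformed at read time", {
  obs <- make_obs(1)
  obs$disp_treat_kind <- "SE"
  obs$disp_treat_value <- 1.2
  obs$n_treat <- 4L
  f <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, f)
  back <- read_observations(f)
  expect_equal(back$disp_treat_kind, "SE")
  expect_equal(back$disp_treat_value, 1.2)
})

test_that("rate classification follows the 150/250 cutoffs with half-open intervals", {
  expect_equal(
    as.character(classify_rate(c(100, 149.9, 150, 200, 249.9, 250, 300))),
    c("R1", "R1", "R2", "R2", "R2", "R3", "R3")
  )
  expect_error(classify_rate(0), class = "nrimpact_domain_error")
  expect_error(classify_rate(c(100, -5)), class = "nrimpact_domain_error")
})

test_that("rate classification partitions the positive axis", {
  set.seed(11)
  rates <- c(runif(500, 0.01, 600), 150, 250, 1e6)
  cls <- classify_rate(rates)
  expect_false(any(is.na(cls)))
  expect_setequal(levels(cls), c("R1", "R2", "R3"))
  # each rate maps to exactly one class and the class matches its interval
  expect_true(all((rates < 150) == (cls == "R1")))
  expect_true(all((rates >= 150 & rates < 250) == (cls == "R2")))
  expect_true(all((rates >= 250) == (cls == "R3")))
})

test_that("baseline selection keeps exactly urea/R2/surface/no-amendment rows", {
  obs <- dplyr::bind_rows(
    make_obs(2),                          # qualifies
    make_obs(1, amendment = "biochar"),   # amendment excludes
    make_obs(1, n_rate = 100),            # R1 excludes
    make_obs(1, n_source = "IU"),         # source excludes
    make_obs(1, placement = "subsurface") # placement excludes
  )
  base <- select_baseline(obs)
  expect_equal(nrow(base), 2)
  all_q <- make_obs(4)
  expect_equal(nrow(select_baseline(all_q)), 4)
  expect_error(select_baseline(make_obs(2, n_source = "OA")),
    class = "nrimpact_empty_group"
  )
})

test_that("strategy subsets vary exactly one lever from baseline", {
  obs <- dplyr::bind_rows(
    make_obs(2),
    make_obs(3, n_rate = 100),
    make_obs(2, n_source = "IU"),
    make_obs(2, amendment = "inhibitor"),
    make_obs(1, placement = "subsurface"),
    make_obs(1, n_rate = 100, amendment = "inhibitor") # two levers: in no subset
  )
  expect_equal(nrow(select_strategy(obs, "R1")), 3)
  expect_equal(nrow(select_strategy(obs, "IU")), 2)
  expect_equal(nrow(select_strategy(obs, "inhibitor")), 2)
  expect_equal(nrow(select_strategy(obs, "subsurface")), 1)
  expect_equal(nrow(select_strategy(obs, "mulch")), 0)
})

test_that("the shipped schema descriptor matches the documented columns", {
  sch <- observation_schema("v1")
  expect_equal(sch$version, "v1")
  expect_true(all(c("study_id", "crop", "pathway", "n_rate", "loss_treat_mean",
    "disp_treat_kind", "clay") %in% sch$columns$name))
  expect_error(observation_schema("v99"), class = "nrimpact_schema_error")
})
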