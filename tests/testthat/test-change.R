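test_that("binary_range selects the requested classes and propagates NA", {
  spec <- grid_spec(2, 2, 0, 0, 1)
  cmap <- classify_suitability(matrix(c(0.1, 0.45, 0.65, 0.9), 2, 2), 0.4,
                               spec)
  rng <- binary_range(cmap) # default moderate + high
  expect_identical(as.vector(rng), c(0, 0, 1, 1))
  # low excluded by default; total-suitable mask includes it
  all_suit <- binary_range(cmap, c("low", "moderate", "high"))
  expect_identical(as.vector(all_suit), c(0, 1, 1, 1))
  # all-unsuitable map -> all-zero grid
  flat <- classify_suitability(matrix(0.1, 2, 2), 0.4, spec)
  expect_true(all(binary_range(flat) == 0))
  expect_error(binary_range(cmap, character(0)), "empty")
  expect_error(binary_range(cmap, "great"), "unknown")
})

test_that("change matrix enumerates loss/stable/gain/never", {
  cur <- matrix(c(1, 1, 0, 0), 2, 2)
  fut <- matrix(c(1, 0, 1, 0), 2, 2)
  cm <- change_matrix(cur, fut)
  expect_identical(as.vector(cm), c(2L, 1L, 3L, 0L)) # stable,loss,gain,never
  # identity scenario: no loss, no gain
  expect_true(all(change_matrix(cur, cur) %in% c(0L, 2L)))
  # total turnover: no stable cells
  expect_false(any(change_matrix(cur, 1 - cur) == 2L))
  expect_error(change_matrix(cur, matrix(0, 3, 2)), "alignment")
})

test_that("range-change bookkeeping identities hold exactly", {
  s <- range_change_stats(loss = 10, stable = 90, gain = 4, current = 100,
                          period = "2050", scenario = "SSP126")
  expect_equal(s$future_suitable, 94)
  expect_equal(s$species_range_change_pct, -6)
  expect_equal(s$pct_loss, 10)
  expect_equal(s$pct_gain, 4)
  # balance and total-loss limits
  expect_equal(range_change_stats(5, 95, 5, 100)$species_range_change_pct, 0)
  expect_equal(range_change_stats(100, 0, 0, 100)$species_range_change_pct,
               -100)
  expect_error(range_change_stats(10, 80, 0, 100), "bookkeeping")
  expect_error(range_change_stats(0, 0, 0, 0), "undefined percentage")
})

test_that("published range-change rows are reproduced from their component areas", {
  inputs <- readr::read_csv(
    system.file("extdata", "vormela_range_change_inputs.csv", package = "ensdm"),
    show_col_types = FALSE
  )
  # reported derived cells for the same six scenario rows, to 2 decimals
  reported <- tibble::tribble(
    ~period, ~scenario, ~future, ~src, ~pl, ~pg,
    "2050", "SSP126", 2226.43, -27.43, 31.90, 4.47,
    "2050", "SSP245", 2553.79, -16.76, 21.06, 4.30,
    "2050", "SSP585", 2226.66, -27.42, 30.19, 2.77,
    "2090", "SSP126", 2702.43, -11.91, 17.80, 5.89,
    "2090", "SSP245", 2038.78, -33.55, 35.83, 2.28,
    "2090", "SSP585", 2213.48, -27.85, 31.90, 4.05
  )
  tbl <- scenario_table(purrr::pmap(inputs, function(period, scenario,
                                                     current, loss, stable,
                                                     gain) {
    range_change_stats(loss, stable, gain, current,
                       period = as.character(period), scenario = scenario)
  }))
  merged <- dplyr::inner_join(format_scenario_table(tbl), reported,
                              by = c("period", "scenario"))
  expect_identical(nrow(merged), 6L)
  expect_equal(merged$future_suitable, merged$future)
  expect_equal(merged$species_range_change_pct, merged$src)
  expect_equal(merged$pct_loss, merged$pl)
  expect_equal(merged$pct_gain, merged$pg)
})

test_that("scenario tables are ordered, unique and internally consistent", {
  rows <- list(
    range_change_stats(10, 90, 5, 100, "2090", "SSP245"),
    range_change_stats(10, 90, 5, 100, "2050", "SSP585"),
    range_change_stats(10, 90, 5, 100, "2050", "SSP126")
  )
  tbl <- scenario_table(rows)
  expect_identical(tbl$period, c("2050", "2050", "2090"))
  expect_identical(tbl$scenario[1], "SSP126")
  expect_error(scenario_table(c(rows, rows[3])), "duplicate")
})

test_that("period averaging is the cell-wise mean", {
  spec <- grid_spec(5, 5, 0, 0, 1)
  base <- make_env_stack(spec, 2, seed = 50)
  shifted <- make_future_stack(base, c(env01 = 2))
  avg <- average_period_stacks(list(base, shifted))
  expect_equal(avg$layers$env01, base$layers$env01 + 1)
  expect_equal(avg$layers$env02, base$layers$env02)
  # unit mean and idempotence on identical stacks
  expect_identical(average_period_stacks(list(base)), base)
  expect_equal(average_period_stacks(list(base, base))$layers, base$layers)
  other <- make_env_stack(grid_spec(4, 5, 0, 0, 1), 2, seed = 50)
  expect_error(average_period_stacks(list(base, other)), "share one grid")
})
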