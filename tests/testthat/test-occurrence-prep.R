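write_occ_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

test_that("read_occurrences keeps valid rows, rejects out-of-bounds, keeps duplicates", {
  path <- write_occ_csv(data.frame(
    lon = c(10, 20, 30, 10, 200, 15),
    lat = c(45, 46, 47, 45, 50, 95),
    note = letters[1:6]
  ))
  expect_message(occ <- read_occurrences(path), "rejected 2")
  expect_identical(nrow(occ), 4L)           # duplicate (10, 45) retained
  expect_identical(attr(occ, "n_rejected"), 2L)
  expect_named(occ, c("lon", "lat", "source"))

  # configurable column names
  path2 <- write_occ_csv(data.frame(x = 1, y = 2))
  occ2 <- read_occurrences(path2, lon_col = "x", lat_col = "y")
  expect_identical(nrow(occ2), 1L)

  # all rows invalid -> empty-input error
  path3 <- write_occ_csv(data.frame(lon = 500, lat = 99))
  expect_error(suppressMessages(read_occurrences(path3)), "no valid")
  expect_error(read_occurrences(path2), "not found|column")
})

test_that("thinning keeps one record per cell, first in input order, idempotently", {
  spec <- grid_spec(10, 10, lon_min = 0, lat_min = 0, cell_size = 1)
  # 10 records all in one cell -> 1 retained (the first)
  occ <- tibble::tibble(lon = runif(10, 3.0, 3.9), lat = runif(10, 5.0, 5.9),
                        source = paste0("r", 1:10))
  thin <- thin_to_grid(occ, spec)
  expect_identical(nrow(thin), 1L)
  expect_identical(thin$source, "r1")

  # all distinct cells -> no-op
  occ2 <- tibble::tibble(lon = c(0.5, 1.5, 2.5), lat = c(0.5, 0.5, 0.5),
                         source = "s")
  thin2 <- thin_to_grid(occ2, spec)
  expect_identical(nrow(thin2), 3L)

  # off-grid records dropped and counted
  occ3 <- dplyr::add_row(occ2, lon = -5, lat = 0.5, source = "s")
  expect_message(thin3 <- thin_to_grid(occ3, spec), "dropped 1")
  expect_identical(attr(thin3, "n_off_grid"), 1L)

  # idempotence
  expect_identical(thin_to_grid(thin, spec)$cell_id, thin$cell_id)
})

test_that("pseudo-absence sampling avoids presences and missing data", {
  spec <- grid_spec(10, 10, lon_min = 0, lat_min = 0, cell_size = 1)
  m <- matrix(rnorm(100), 10, 10)
  m[1, 1] <- NA # one incomplete cell
  stack <- env_stack(list(env01 = m, env02 = matrix(rnorm(100), 10, 10)), spec)
  presences <- tibble::tibble(lon = c(2.5, 5.5), lat = c(3.5, 7.5),
                              source = "x")
  tab <- sample_pseudo_absences(stack, presences, n = 50, seed = 9)
  expect_identical(sum(tab$label == 1), 2L)
  expect_identical(sum(tab$label == 0), 50L)
  pres_cells <- tab$cell_id[tab$label == 1]
  abs_cells <- tab$cell_id[tab$label == 0]
  expect_length(intersect(pres_cells, abs_cells), 0)
  expect_false(any(is.na(tab[attr(tab, "predictors")])))
  expect_false(1L %in% abs_cells) # the NA cell (row 1, col 1) never drawn

  # exhaustive draw: every eligible cell selected
  tab_all <- sample_pseudo_absences(stack, presences, n = 97, seed = 9)
  expect_identical(sort(tab_all$cell_id[tab_all$label == 0]),
                   setdiff(1:100, c(1L, pres_cells)))

  # shortfall is named
  expect_error(sample_pseudo_absences(stack, presences, n = 98, seed = 9),
               "short by 1")

  # deterministic by seed
  expect_identical(tab, sample_pseudo_absences(stack, presences, 50, seed = 9))
})

test_that("splits are stratified partitions, reproducible by seed", {
  table <- tibble::tibble(label = c(rep(1L, 101), rep(0L, 1200)))
  splits <- split_train_test(table, train_fraction = 0.7, n_repetitions = 10,
                             seed = 4)
  expect_identical(nrow(splits), 10L * 1301L)
  for (rep_i in 1:10) {
    s <- splits[splits$repetition == rep_i, ]
    train <- s$row_index[s$set == "train"]
    test <- s$row_index[s$set == "test"]
    # partition law
    expect_identical(sort(c(train, test)), 1:1301)
    # stratified counts: round(0.7 * 101) = 71 presences, 840 absences
    expect_identical(sum(table$label[train] == 1), 71L)
    expect_identical(sum(table$label[train] == 0), 840L)
  }
  expect_identical(splits, split_train_test(table, 0.7, 10, seed = 4))
  expect_error(split_train_test(tibble::tibble(label = rep(1L, 5)), seed = 1),
               "both classes")
  expect_error(split_train_test(tibble::tibble(label = c(1L, 0L, 0L)),
                                seed = 1),
               "at least 2")
})
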