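test_that("aggregation sums mapped parishes and tracks availability", {
  tab <- data.frame(unit_id = c("p1", "p2"), year = 1700L,
                    event_type = "baptism", count = c(3, 4))
  map <- data.frame(raw_id = c("p1", "p2"), unit_id = c("U", "U"))
  out <- aggregate_events(tab, map, span = c(1699, 1701))
  expect_equal(unname(out$b["1700", "U"]), 7)
  expect_true(out$avail_b["1700", "U"])
  expect_false(out$avail_b["1699", "U"])
  expect_false(any(out$avail_d))
})

test_that("empty tables give empty availability and no counts", {
  tab <- data.frame(unit_id = character(0), year = integer(0),
                    event_type = character(0), count = numeric(0))
  out <- aggregate_events(tab, NULL, span = c(1700, 1705))
  expect_equal(out$n_units_included, 0L)
  expect_equal(dim(out$b), c(6L, 0L))
})

test_that("grouped fixture matches a hand-computed group-by and conserves totals", {
  tab <- raw_event_fixture()
  map <- unit_map_fixture()
  out <- aggregate_events(tab, map, span = c(1701, 1710))
  # independent oracle: loop-based grouped sums
  lk <- stats::setNames(map$unit_id, map$raw_id)
  for (type in c("baptism", "burial")) {
    m <- if (type == "baptism") out$b else out$d
    for (u in c("A", "B", "C")) {
      for (y in 1701:1710) {
        rows <- tab[tab$event_type == type & tab$year == y &
                      lk[tab$unit_id] == u, ]
        if (nrow(rows) == 0) {
          expect_true(is.na(m[as.character(y), u]))
        } else {
          expect_equal(unname(m[as.character(y), u]), sum(rows$count))
        }
      }
    }
    expect_equal(sum(m, na.rm = TRUE), sum(tab$count[tab$event_type == type]))
  }
})

test_that("unmapped parish ids are a hard error; out-of-span rows warn", {
  tab <- raw_event_fixture()
  map <- unit_map_fixture()[-1, ]
  expect_error(aggregate_events(tab, map, span = c(1701, 1710)), "par1")
  tab2 <- raw_event_fixture()
  tab2$year[1] <- 1600L
  expect_warning(aggregate_events(tab2, unit_map_fixture(),
                                  span = c(1701, 1710)),
                 "outside the study span")
})

test_that("inclusion rule keeps units with at least min_years joint years", {
  # six units with joint-record year counts {3, 9, 10, 12, 0, 50}
  joint <- c(3, 9, 10, 12, 0, 50)
  span <- 1701:1760
  rows <- do.call(rbind, lapply(seq_along(joint), function(i) {
    if (joint[i] == 0) return(NULL)
    yrs <- span[seq_len(joint[i])]
    rbind(data.frame(unit_id = paste0("u", i), year = yrs,
                     event_type = "baptism", count = 5),
          data.frame(unit_id = paste0("u", i), year = yrs,
                     event_type = "burial", count = 4))
  }))
  # unit u5 exists with baptisms only (no joint years)
  rows <- rbind(rows, data.frame(unit_id = "u5", year = span[1:20],
                                 event_type = "baptism", count = 2))
  data <- aggregate_events(rows, NULL, span = range(span))
  kept <- apply_inclusion_rule(data, min_years = 10L)
  expect_setequal(kept$unit_ids, c("u3", "u4", "u6"))
  expect_equal(kept$n_units_included, 3L)
  expect_equal(kept$n_units_total, data$n_units_total)
  # boundary is inclusive (u3 has exactly 10), and the rule is idempotent
  expect_true("u3" %in% kept$unit_ids)
  again <- apply_inclusion_rule(kept, min_years = 10L)
  expect_identical(again$b, kept$b)
  # availability shrinks monotonically under a stricter threshold
  stricter <- apply_inclusion_rule(data, min_years = 12L)
  expect_true(all(stricter$unit_ids %in% kept$unit_ids))
  expect_lte(sum(stricter$avail_b), sum(kept$avail_b))
})

test_that("casualty loader densifies, sums duplicates and rejects negatives", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(year = 1700, deaths = 5000), f,
                   row.names = FALSE)
  s <- load_casualties(f, span = c(1699, 1701))
  expect_equal(unname(s), c(0, 5000, 0))

  utils::write.csv(data.frame(year = integer(0), deaths = numeric(0)), f,
                   row.names = FALSE)
  expect_equal(unname(load_casualties(f, span = c(1699, 1701))), c(0, 0, 0))

  utils::write.csv(data.frame(year = c(1700, 1700), deaths = c(10, 20)), f,
                   row.names = FALSE)
  expect_message(s2 <- load_casualties(f, span = c(1699, 1701)),
                 "duplicate")
  expect_equal(unname(s2[2]), 30)

  utils::write.csv(data.frame(year = 1700, deaths = -1), f,
                   row.names = FALSE)
  expect_error(load_casualties(f, span = c(1699, 1701)), "negative")
})

test_that("CSV round trip preserves counts, availability and benchmarks", {
  scen <- tiny_scenario()
  ds <- simulate_dataset(scen, 11)
  dir <- withr::local_tempdir()
  write_observed_data(ds$data, dir)
  back <- read_observed_data(dir, n_units_total = ds$data$n_units_total)
  expect_equal(back$avail_b, ds$data$avail_b)
  expect_equal(back$avail_d, ds$data$avail_d)
  expect_equal(back$b, ds$data$b)
  expect_equal(back$d, ds$data$d)
  expect_equal(unname(back$C), unname(ds$data$C), tolerance = 1e-12)
  expect_equal(back$s, ds$data$s)
})
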