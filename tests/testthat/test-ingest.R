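write_posts_file <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_posts parses well-formed files and preserves order", {
  path <- write_posts_file(data.frame(date = c("2020-01-23", "2020-01-23"),
                                      topic = c("M2", "P2")))
  recs <- read_posts(path)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$topic, c("M2", "P2"))
  expect_equal(recs$date, as.Date(c("2020-01-23", "2020-01-23")))

  set.seed(41)
  big <- data.frame(
    date = as.character(as.Date("2020-01-23") + sample(0:39, 1000, TRUE)),
    topic = sample(default_topic_set()$code, 1000, TRUE),
    id = sprintf("id%04d", 1:1000))
  path <- write_posts_file(big)
  recs <- read_posts(path)
  expect_equal(nrow(recs), length(readLines(path)) - 1)
  expect_equal(recs$id, big$id)  # file order preserved
})

test_that("read_posts rejects bad topics, bad dates and empty files", {
  path <- write_posts_file(data.frame(date = "2020-01-23", topic = "X9"))
  expect_error(read_posts(path), "X9")
  path <- write_posts_file(data.frame(date = c("2020-01-23", "23/01/2020"),
                                      topic = c("M2", "M2")))
  expect_error(read_posts(path), "row 2")
  path <- write_posts_file(data.frame(date = character(), topic = character()))
  expect_error(read_posts(path), "empty")
  expect_error(read_posts(tempfile()), "not found")
})

test_that("build_daily_proportions divides counts by daily totals", {
  # one day, all posts one topic
  recs <- data.frame(date = as.Date(rep("2020-01-23", 3)), topic = rep("P1", 3))
  ts <- build_daily_proportions(recs, topic_set = c("P1", "P2", "M1"))
  expect_equal(as.numeric(ts$proportions), c(1, 0, 0))

  # counts (2, 1, 1) over 4 posts
  recs <- data.frame(date = as.Date(rep("2020-01-23", 4)),
                     topic = c("P1", "P1", "P2", "M1"))
  ts <- build_daily_proportions(recs, topic_set = c("P1", "P2", "M1"))
  expect_equal(as.numeric(ts$proportions), c(0.5, 0.25, 0.25))
})

test_that("proportions equal counts over totals on a 40x11 synthetic series", {
  corpus <- simulate_corpus(generator_spec(seed = 5))
  ts <- build_daily_proportions(corpus$posts)
  expect_equal(unname(ts$proportions),
               unname(ts$counts / rowSums(ts$counts)), tolerance = 1e-15)
  expect_equal(dim(ts$counts), c(40, 11))
  # row-stochasticity
  expect_true(max(abs(rowSums(ts$proportions) - 1)) <= 1e-12)
  # cell sum equals record count
  expect_equal(sum(ts$counts), nrow(corpus$posts))
})

test_that("record order does not affect the series", {
  corpus <- simulate_corpus(generator_spec(p = 4, n_days = 6,
                                           mean_daily_posts = 30, seed = 2))
  recs <- corpus$posts
  ts1 <- build_daily_proportions(recs, topic_set = corpus$spec$topics)
  set.seed(99)
  ts2 <- build_daily_proportions(recs[sample(nrow(recs)), ],
                                 topic_set = corpus$spec$topics)
  expect_identical(ts1$counts, ts2$counts)
  expect_identical(ts1$proportions, ts2$proportions)
})

test_that("date filtering drops outside records and warns on empty days", {
  recs <- data.frame(date = as.Date(c("2020-01-23", "2020-01-25")),
                     topic = c("P1", "P2"))
  expect_warning(
    ts <- build_daily_proportions(recs, topic_set = c("P1", "P2"),
                                  date_range = c("2020-01-23", "2020-01-25")),
    "no posts")
  expect_equal(length(ts$dates), 2)
  ts <- build_daily_proportions(recs, topic_set = c("P1", "P2"),
                                date_range = c("2020-01-23", "2020-01-23"))
  expect_equal(length(ts$dates), 1)
  expect_error(
    build_daily_proportions(recs, topic_set = c("P1", "P2"),
                            date_range = c("2021-01-01", "2021-01-02")),
    "outside")
})

test_that("topic series survives a write/read round trip", {
  corpus <- simulate_corpus(generator_spec(p = 4, n_days = 8,
                                           mean_daily_posts = 40, seed = 3))
  stem <- tempfile()
  write_topic_series(corpus$series, stem)
  back <- read_topic_series(stem)
  expect_identical(unname(back$counts), unname(corpus$series$counts))
  expect_equal(back$proportions, corpus$series$proportions, tolerance = 1e-15)
})
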