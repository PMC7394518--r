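test_that("port reader enforces the schema, drops environment-less ports, round-trips", {
  w <- tiny_world()
  f <- withr::local_tempfile(fileext = ".csv")
  write_ports(w$ports, f)
  p2 <- read_ports(f)
  expect_equal(p2, w$ports, ignore_attr = TRUE)

  # one port with missing salinity is dropped and counted
  p3 <- w$ports
  p3$salinity[2] <- NA
  write_ports(p3, f)
  expect_message(got <- read_ports(f), "1 port")
  expect_equal(nrow(got), 4L)
  expect_equal(attr(got, "n_dropped"), 1L)

  # duplicate ids are an error naming the id
  p4 <- rbind(w$ports, w$ports[1, ])
  write_ports(p4, f)
  expect_error(read_ports(f), "AAA")

  # unparseable coordinates are an error with the row number
  lines <- readLines(f)[1:6]
  lines[3] <- sub("10,", "not-a-number,", lines[3])
  writeLines(lines, f)
  expect_error(read_ports(f), "row")
})

test_that("voyage reader drops unknown references and rejects inverted dates", {
  w <- tiny_world()
  f <- withr::local_tempfile(fileext = ".csv")
  v <- w$voyages
  v$source[3] <- "ZZZ"                     # unknown port
  v <- rbind(v, data.frame(ship_id = "nope", source = "AAA", dest = "BBB",
                           sail_date = as.Date("2012-06-01"),
                           arrival_date = as.Date("2012-06-03"),
                           discharge = NA))
  v <- rbind(v, data.frame(ship_id = "s2", source = "AAA", dest = "BBB",
                           sail_date = as.Date("2012-06-10"),
                           arrival_date = as.Date("2012-06-01"),
                           discharge = NA))
  write_voyages(v, f)
  expect_warning(
    expect_message(got <- read_voyages(f, w$ports, w$ships), "2 voyage"),
    "arrival before sail")
  expect_equal(nrow(got), 2L)
  expect_equal(attr(got, "n_dropped"), 2L)
  expect_equal(attr(got, "n_rejected"), 1L)

  # empty file: empty table, no error
  writeLines("ship_id,source_port,dest_port,sail_date,arrival_date", f)
  expect_equal(nrow(read_voyages(f, w$ports, w$ships)), 0L)
})

test_that("kinematics: haversine distance, duration floor, symmetry", {
  p <- data.frame(port_id = c("a", "b"), latitude = c(0, 0), longitude = c(0, 90))
  expect_equal(haversine_km(0, 0, 0, 90), 6371 * pi / 2, tolerance = 1e-10)
  v <- data.frame(ship_id = "s", source = "a", dest = "b",
                  sail_date = as.Date("2012-05-01"),
                  arrival_date = as.Date("2012-05-01"), discharge = NA)
  k <- derive_kinematics(v, p, duration_floor = 0.5)
  expect_equal(k$duration, 0.5)
  expect_equal(k$velocity, k$distance / 0.5)
  # self-loop: distance 0, flagged
  v$dest <- "a"
  k <- derive_kinematics(v, p)
  expect_equal(k$distance, 0)
  expect_true(k$self_loop)
  # distance symmetry on random coordinate pairs
  set.seed(1)
  la1 <- runif(50, -90, 90); lo1 <- runif(50, -180, 180)
  la2 <- runif(50, -90, 90); lo2 <- runif(50, -180, 180)
  expect_equal(haversine_km(la1, lo1, la2, lo2), haversine_km(la2, lo2, la1, lo1))
})

test_that("climate zone splits at 35 degrees, boundary inclusive, by source port", {
  expect_equal(climate_zone(0), "tropical")
  expect_equal(climate_zone(35), "tropical")
  expect_equal(climate_zone(-35), "tropical")
  expect_equal(climate_zone(-50), "temperate")
  expect_equal(climate_zone(35.0001), "temperate")
})

test_that("trajectories: visit sequences, self-loop removal, per-ship separation", {
  v <- data.frame(ship_id = "s1", source = c("C", "A"), dest = c("A", "E"),
                  sail_date = as.Date(c("2012-05-01", "2012-05-10")),
                  arrival_date = as.Date(c("2012-05-05", "2012-05-15")))
  expect_equal(unname(unclass(build_trajectories(v))), list(c("C", "A", "E")))

  v2 <- data.frame(ship_id = "s1", source = c("A", "A"), dest = c("A", "B"),
                   sail_date = as.Date(c("2012-05-01", "2012-05-10")),
                   arrival_date = as.Date(c("2012-05-05", "2012-05-15")))
  expect_equal(unname(unclass(build_trajectories(v2))), list(c("A", "B")))

  v3 <- rbind(v, transform(v, ship_id = "s2"))
  expect_equal(length(build_trajectories(v3)), 2L)
})

test_that("trajectory reconstruction is lossless on random voyage sets", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    ports <- paste0("p", 1:8)
    src <- sample(ports, n, replace = TRUE)
    dst <- sample(ports, n, replace = TRUE)
    sail <- as.Date("2012-05-01") + sort(sample(0:200, n, replace = TRUE))
    v <- data.frame(ship_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
                    source = src, dest = dst, sail_date = sail,
                    arrival_date = sail + sample(1:5, n, replace = TRUE))
    v <- v[order(v$ship_id, v$sail_date), ]
    # recover consecutive visit pairs from all trajectory segments
    tr <- suppressWarnings(build_trajectories(v))
    pairs <- do.call(rbind, lapply(tr, function(s) {
      if (length(s) < 2) NULL else cbind(s[-length(s)], s[-1])
    }))
    keep <- v$source != v$dest
    got <- sort(paste(pairs[, 1], pairs[, 2]))
    want <- sort(paste(v$source[keep], v$dest[keep]))
    expect_equal(got, want)
  }
})

test_that("source stays come from consecutive records, default on cold starts", {
  v <- data.frame(ship_id = "s1",
                  source = c("A", "B", "D"), dest = c("B", "C", "E"),
                  sail_date = as.Date(c("2012-05-01", "2012-05-09", "2012-05-20")),
                  arrival_date = as.Date(c("2012-05-04", "2012-05-12", "2012-05-25")))
  got <- annotate_stays(v, default_stay = 7)
  # first record: default; continuous B: 9th - 4th = 5 days; gap (C -> D): default
  expect_equal(got$source_stay, c(7, 5, 7))
})

test_that("dates parse and format as ISO 8601 identity", {
  d <- c("2012-05-01", "1997-12-31", "2008-02-29")
  expect_identical(format(as.Date(d), "%Y-%m-%d"), d)
})
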