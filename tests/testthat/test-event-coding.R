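det_row <- function(tag, ts) {
  data.frame(tag_id = tag, timestamp = as.POSIXct(ts, tz = "UTC"),
             site_id = "SIM", roost_id = "SIM", antenna_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("post-tagging exclusion drops the first days and keeps the rest", {
  dep <- fx_deployments("t1", "2016-04-01 12:00:00")
  det <- do.call(rbind, lapply(c("2016-04-01 20:00:00", "2016-04-02 20:00:00",
                                 "2016-04-03 01:00:00", "2016-04-04 03:00:00"),
                               function(ts) det_row("t1", ts)))
  out <- filter_post_tagging(det, dep, exclusion_days = 3)
  expect_equal(format(out$timestamp), "2016-04-04 03:00:00")
  expect_identical(filter_post_tagging(det, dep, exclusion_days = 0)$timestamp,
                   det$timestamp)
  expect_warning(filter_post_tagging(det, dep, exclusion_days = 30),
                 "exclusion window")
})

test_that("unknown tags are dropped with a warning, or an error in strict mode", {
  dep <- fx_deployments("t1")
  det <- rbind(det_row("t1", "2016-04-10 20:00:00"),
               det_row("zz", "2016-04-10 20:00:00"))
  expect_warning(out <- filter_post_tagging(det, dep), "unknown tag")
  expect_equal(out$tag_id, "t1")
  expect_error(filter_post_tagging(det, dep, unknown_tags = "error"), "unknown tag")
})

test_that("condition window keeps days 4-17 after tagging and Inf is identity", {
  dep <- fx_deployments("t1", "2016-04-01 12:00:00")
  days <- seq(as.Date("2016-04-04"), by = "day", length.out = 60)
  det <- do.call(rbind, lapply(paste(days, "20:00:00"), function(ts) det_row("t1", ts)))
  out <- select_condition_window(det, dep, window_days = 14)
  expect_equal(range(as.Date(out$timestamp, tz = "UTC")),
               as.Date(c("2016-04-04", "2016-04-17")))
  expect_identical(select_condition_window(det, dep, window_days = Inf), det)
  empty <- det[0, ]
  expect_equal(nrow(select_condition_window(empty, dep)), 0)
})

test_that("burst deduplication collapses runs and respects the gap threshold", {
  det <- rbind(det_row("t1", "2016-04-15 19:30:00"),
               det_row("t1", "2016-04-15 19:30:05"),
               det_row("t1", "2016-04-15 19:30:12"))
  p <- deduplicate_bursts(det, burst_gap_s = 60)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_raw_reads, 3L)
  expect_equal(format(p$timestamp), "2016-04-15 19:30:00")

  det2 <- rbind(det_row("t1", "2016-04-15 19:30:00"),
                det_row("t1", "2016-04-15 19:32:00"))
  expect_equal(nrow(deduplicate_bursts(det2, 60)), 2)
  # gap exactly at the threshold joins the burst
  det3 <- rbind(det_row("t1", "2016-04-15 19:30:00"),
                det_row("t1", "2016-04-15 19:31:00"))
  expect_equal(nrow(deduplicate_bursts(det3, 60)), 1)
  # zero threshold: every read its own passage
  expect_equal(nrow(deduplicate_bursts(det, 0)), 3)
  # different tags never merge
  det4 <- rbind(det_row("t1", "2016-04-15 19:30:00"),
                det_row("t2", "2016-04-15 19:30:05"))
  expect_equal(nrow(deduplicate_bursts(det4, 60)), 2)
})

test_that("burst deduplication is idempotent and monotone in the threshold", {
  set.seed(42)
  base <- as.POSIXct("2016-04-15 19:00:00", tz = "UTC")
  det <- data.frame(tag_id = sample(c("a", "b"), 200, TRUE),
                    timestamp = base + cumsum(rexp(200, 1 / 40)),
                    site_id = "SIM", roost_id = "SIM",
                    antenna_id = NA_character_, stringsAsFactors = FALSE)
  p1 <- deduplicate_bursts(det, 60)
  p2 <- deduplicate_bursts(p1, 60)
  expect_equal(p2[names(p1) != "n_raw_reads"], p1[names(p1) != "n_raw_reads"])
  n_passages <- vapply(c(0, 10, 30, 60, 120, 600),
                       function(g) nrow(deduplicate_bursts(det, g)), numeric(1))
  expect_true(all(diff(n_passages) <= 0))
})

test_that("passages join the correct night and daytime reads are dropped", {
  nt <- fx_night()
  make_p <- function(ts) {
    data.frame(tag_id = "t1", timestamp = as.POSIXct(ts, tz = "UTC"),
               site_id = "SIM", roost_id = "SIM", n_raw_reads = 1L,
               stringsAsFactors = FALSE)
  }
  nights <- night_table(fx_site(), as.Date("2016-04-15") + -1:1)
  # 02:00 belongs to the night opened by the previous sunset
  a <- assign_nights(make_p("2016-04-16 02:00:00"), nights)
  expect_equal(a$night_date, as.Date("2016-04-15"))
  expect_false(a$pre_sunset)
  # noon is a daytime read
  expect_message(b <- assign_nights(make_p("2016-04-15 12:00:00"), nights),
                 "daytime")
  expect_equal(nrow(b), 0)
  expect_equal(attr(b, "n_daytime_dropped"), 1L)
  # 10 min before sunset is inside the tolerance band
  cc <- assign_nights(make_p(format(nt$sunset - 600)), nights,
                      sunset_tolerance_min = 30)
  expect_equal(cc$night_date, as.Date("2016-04-15"))
  expect_true(cc$pre_sunset)
  # 40 min before sunset is not
  expect_message(dd <- assign_nights(make_p(format(nt$sunset - 2400)), nights, 30))
  expect_equal(nrow(dd), 0)
})

test_that("directions strictly alternate starting from EXIT", {
  nt <- fx_night()
  p <- data.frame(tag_id = "t1", night_date = nt$night_date, site_id = "SIM",
                  timestamp = nt$sunset + c(30, 120, 150, 300) * 60,
                  roost_id = "SIM", pre_sunset = FALSE, stringsAsFactors = FALSE)
  ev <- code_directions(p)
  expect_equal(ev$direction, c("EXIT", "ENTRY", "EXIT", "ENTRY"))
  expect_equal(ev$ordinal, 1:4)
  lone <- code_directions(p[1, ])
  expect_equal(lone$direction, "EXIT")
  expect_equal(nrow(code_directions(p[0, ])), 0)
})

test_that("alternation invariant holds on random multi-bat streams", {
  set.seed(7)
  nights <- night_table(fx_site(), as.Date("2016-04-15") + 0:4)
  p <- do.call(rbind, lapply(1:30, function(i) {
    nd <- sample(5, 1)
    k <- sample(1:7, 1)
    data.frame(tag_id = sprintf("b%02d", sample(8, 1)),
               night_date = nights$night_date[nd], site_id = "SIM",
               timestamp = nights$sunset[nd] + sort(sample(3600:40000, k)),
               roost_id = "SIM", pre_sunset = FALSE, stringsAsFactors = FALSE)
  }))
  p <- p[!duplicated(p[c("tag_id", "night_date", "timestamp")]), ]
  ev <- code_directions(p)
  by_night <- split(ev, paste(ev$tag_id, ev$night_date))
  for (bn in by_night) {
    expect_equal(bn$direction, rep(c("EXIT", "ENTRY"), length.out = nrow(bn)))
    n_exit <- sum(bn$direction == "EXIT")
    n_entry <- sum(bn$direction == "ENTRY")
    expect_true((n_exit - n_entry) %in% c(0L, 1L))
    expect_true(!is.unsorted(bn$timestamp, strictly = TRUE))
  }
})

test_that("a merged roost complex codes between-roost transfers as exit/entry", {
  cac <- site("CAC", 24.0, -110.1, -7, roost_ids = c("A", "B"), merge_roosts = TRUE)
  nights <- night_table(cac, as.Date("2016-04-15"))
  p <- data.frame(tag_id = "t1", timestamp = nights$sunset + c(1800, 5400),
                  site_id = "CAC", roost_id = c("A", "B"), n_raw_reads = 1L,
                  stringsAsFactors = FALSE)
  m <- merge_roost_complex(p, cac)
  expect_equal(m$roost_id, c("CAC", "CAC"))
  expect_equal(m$roost_id_original, c("A", "B"))
  ev <- code_directions(assign_nights(m, nights))
  expect_equal(ev$direction, c("EXIT", "ENTRY"))
  # merge_roosts = FALSE site is the identity
  plain <- fx_site()
  p2 <- data.frame(tag_id = "t1", timestamp = nights$sunset + 1800,
                   site_id = "SIM", roost_id = "SIM", n_raw_reads = 1L,
                   stringsAsFactors = FALSE)
  expect_identical(merge_roost_complex(p2, plain), p2)
})
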