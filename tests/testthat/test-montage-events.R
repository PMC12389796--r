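test_that("bundled montages satisfy the protocol geometry", {
  m <- load_montage("clinical28")
  expect_equal(nrow(m$channels), 28)
  expect_equal(nrow(m$pairs), 14)
  expect_setequal(unique(m$channels$hemisphere), c("left", "right"))
  hemi <- setNames(m$channels$hemisphere, m$channels$channel)
  expect_true(all(hemi[m$pairs$left_channel] == "left"))
  expect_true(all(hemi[m$pairs$right_channel] == "right"))
  # no channel in more than one pair
  expect_false(anyDuplicated(c(m$pairs$left_channel,
                               m$pairs$right_channel)) > 0)

  h <- load_montage("healthy33")
  expect_equal(nrow(h$channels), 33)
  expect_equal(nrow(h$pairs), 7)
})

test_that("montage validation rejects malformed pair maps", {
  ch <- tibble::tibble(channel = c("A", "B"), emitter = c("a", "b"),
                       detector = c("d", "d"),
                       hemisphere = c("left", "left"))
  expect_error(new_montage("bad", ch,
                           tibble::tibble(left_channel = "A",
                                          right_channel = "B")),
               "opposite hemispheres")
  ch$hemisphere <- c("left", "right")
  expect_error(
    new_montage("bad", rbind(ch, ch[1, ]),
                tibble::tibble(left_channel = "A", right_channel = "B")),
    "duplicate")
})

test_that("clinical schedule has the protocol trial structure", {
  s <- build_schedule("clinical", n_blocks = 4, seed = 1)
  counts <- table(s$phases$label)
  expect_equal(unname(counts["mi_left"]), 8)   # 16 trials, 8 per hand
  expect_equal(unname(counts["mi_right"]), 8)
  expect_equal(unname(counts["rest"]), 16)
  # each trial: 17 s rest phase + 17 s MI phase, tiled back to back
  expect_equal(s$duration, 16 * 34)
  first <- s$phases[s$phases$trial == 1, ]
  expect_equal(first$duration, c(2, 15, 2, 15))
  expect_equal(first$label[1:3], c("prep_rest", "rest", "prep_task"))
  # per block, exactly 2 trials of each hand
  mi <- s$phases[s$phases$label %in% c("mi_left", "mi_right"), ]
  per_block <- table(mi$block, mi$label)
  expect_true(all(per_block == 2))
  # phases are time-ordered and non-overlapping (up to sample rounding)
  expect_true(all(diff(s$phases$onset) > 0))
  gaps <- diff(s$phases$onset) - s$phases$duration[-nrow(s$phases)]
  expect_true(all(abs(gaps) <= 1 / s$fs))
  # cue at the start of every non-preparatory instruction
  expect_equal(nrow(s$cues), 32)
  expect_true(all(s$cues$label %in% c("rest", "mi_left", "mi_right")))
})

test_that("one-block clinical schedule spans 136 s of trial time", {
  s <- build_schedule("clinical", n_blocks = 1, seed = 3)
  expect_equal(s$duration, 4 * (17 + 17))
})

test_that("healthy schedule uses 3 s preparation and 20 s execution", {
  s <- build_schedule("healthy", n_blocks = 3, seed = 2)
  expect_equal(s$fs, 3.9)
  task <- s$phases[s$phases$label %in% c("mi_left", "mi_right", "rest"), ]
  expect_true(all(task$duration == 20))
  prep <- s$phases[startsWith(s$phases$label, "prep"), ]
  expect_true(all(prep$duration == 3))
})

test_that("schedules are seed-deterministic and onsets sample-aligned", {
  a <- build_schedule("clinical", 4, seed = 9)
  b <- build_schedule("clinical", 4, seed = 9)
  expect_identical(a, b)
  c <- build_schedule("clinical", 4, seed = 10)
  expect_false(identical(a$phases$label, c$phases$label))
  expect_equal(a$phases$onset, round(a$phases$onset * a$fs) / a$fs)
  expect_error(build_schedule("clinical", -1), "positive")
})

test_that("schedule round-trips through its TSV serialization", {
  s <- build_schedule("clinical", 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(s, path)
  r <- read_schedule(path, fs = s$fs)
  expect_equal(r$phases$onset, s$phases$onset)
  expect_equal(r$phases$label, s$phases$label)
  expect_equal(r$cues$onset, s$cues$onset)
})

test_that("mirroring swaps pair values for right lesions only", {
  m <- tiny_montage()
  resp <- tiny_responses(c(0.3, 0.5, -0.1, -0.2, 0.8, 0.6, 0.4, 0.2))
  left <- subject_meta("p1", "patient", "left")
  right <- subject_meta("p2", "patient", "right")
  healthy <- subject_meta("h1", "healthy", "none")

  # healthy and left-lesion: identity on channel values
  expect_identical(mirror_responses(resp, healthy, m), resp)
  ml <- mirror_responses(resp, left, m)
  expect_equal(ml$coefficient, resp$coefficient)
  expect_equal(ml$channel, resp$channel)
  # left lesion: affected hand is the right hand
  expect_equal(ml$task[resp$task == "mi_right"][1], "affected")

  # right lesion: pair values swap, e.g. (0.3, -0.1) -> (-0.1, 0.3)
  mr <- mirror_responses(resp, right, m)
  get <- function(tbl, ch, tk) tbl$coefficient[tbl$channel == ch &
                                                 tbl$task == tk]
  expect_equal(get(mr, "L1", "affected"), get(resp, "R1", "mi_left"))
  expect_equal(get(mr, "R1", "affected"), get(resp, "L1", "mi_left"))
  # involution: mirroring twice restores the original channel-value map
  mrr <- mirror_responses(mr, right, m)
  expect_equal(get(mrr, "R1", "affected"), get(resp, "R1", "mi_left"))
  expect_equal(get(mrr, "L2", "intact"), get(resp, "L2", "mi_right"))
  expect_equal(sort(mrr$coefficient), sort(resp$coefficient))

  # unpaired channel with data is dropped with a warning
  resp2 <- rbind(resp, tibble::tibble(channel = "X", task = "mi_left",
                                      chromophore = "HbO",
                                      coefficient = 1))
  expect_warning(out <- mirror_responses(resp2, right, m), "unpaired")
  expect_false("X" %in% out$channel)
})

test_that("subject metadata enforces lesion-side/group consistency", {
  expect_error(subject_meta("s", "healthy", "left"), "none")
  expect_error(subject_meta("s", "patient", "none"), "none")
  expect_error(subject_meta("s", "patient", "left",
                            sessions = tibble::tibble(session_id = 1:2,
                                                      day_index = c(2, 1))),
               "non-decreasing")
})
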