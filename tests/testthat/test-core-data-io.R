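# the printed event table of a one-minute motor run: the fixture for all
# event-model arithmetic
run_events <- function() {
  event_table(
    code = c(1, 3, 1, 2, 1, 2, 1, 3, 1, 3, 1, 2, 1, 3, 1),
    latency = c(1, 1313, 2609, 3921, 5217, 6529, 7825, 9297,
                10593, 11905, 13201, 14513, 15809, 17281, 18577),
    duration = c(672, 656, 672, 656, 672, 656, 672, 656,
                 672, 656, 672, 656, 672, 656, 672))
}

test_that("montage has 64 unique electrodes, FC5 first, none excluded", {
  ch <- channel_map()
  expect_length(as.character(ch), 64L)
  expect_identical(as.character(ch)[1], "FC5")
  expect_false(anyDuplicated(as.character(ch)) > 0)
  expect_silent(validate_channel_map(ch))
  expect_identical(channel_index("FC5"), 1L)
  expect_identical(channel_index("Cz.."), 11L)  # raw-header style label
  expect_error(channel_index("A1"), "unknown")
})

test_that("event tables enforce the three-code alphabet and ordering", {
  expect_error(event_table("e4", 1, 10), "codes")
  expect_error(event_table(c("e1", "e2"), c(5, 1), c(2, 2)), "increasing")
  expect_error(event_table(c("e1", "e2"), c(1, 3), c(5, 2)), "overlap")
  expect_error(event_table("e1", 1, 0), "positive")
  expect_identical(nrow(event_table()), 0L)
})

test_that("event_end follows the inclusive 1-based convention", {
  ev <- run_events()
  expect_identical(event_end(ev[1, ]), 672L)   # starts at 1, lasts until 672
  expect_identical(event_end(event_table("e2", 10, 1)), 10L)
  expect_identical(event_end(ev[2, ]), 1968L)  # 1313 + 656 - 1
})

test_that("intermission reproduces the printed 641-sample gaps", {
  ev <- run_events()
  gaps <- intermission(ev)
  expect_identical(gaps[1], 641L)             # 1313 - 672
  expect_identical(gaps[2], 641L)             # 2609 - 1968
  # adjacency: event ending at n followed by one starting at n + 1
  adj <- event_table(c("e1", "e2"), c(1, 11), c(10, 5))
  expect_identical(intermission(adj), 1L)
  expect_error(intermission(ev[2, ], ev[1, ]), "overlap")
  # identity: gap + duration = latency difference + 1... rearranged
  expect_identical(gaps + ev$duration[-nrow(ev)],
                   diff(ev$latency) + 1L)
})

test_that("segment extraction is per-event, concatenation is per-code", {
  ev <- run_events()
  n_t <- max(event_end(ev))
  sig <- matrix(seq_len(64 * n_t), nrow = 64)
  rec <- recording(sig, 160, ev, participant_id = 1, run_id = 3)

  segs <- extract_segments(rec)
  expect_length(segs, 15L)
  expect_identical(ncol(segs[[1]]$data), 672L)

  cat3 <- extract_segments(rec, concatenate_same_event = TRUE)
  expect_length(cat3, 3L)
  lens <- vapply(cat3, function(s) ncol(s$data), integer(1))
  ev_of <- vapply(cat3, function(s) s$event, integer(1))
  expect_identical(lens[ev_of == 1L], 8L * 672L)
  expect_identical(lens[ev_of == 2L], 3L * 656L)
  expect_identical(lens[ev_of == 3L], 4L * 656L)
  # lossless: event samples + gap samples = run length
  expect_identical(sum(lens) + sum(intermission(ev) - 1L), n_t)

  # concatenation preserves sample values in time order
  e1_rows <- which(ev$code == "e1")
  manual <- do.call(cbind, lapply(e1_rows, function(i) {
    rec$signal[, ev$latency[i]:event_end(ev[i, ]), drop = FALSE]
  }))
  expect_identical(cat3[[which(ev_of == 1L)]]$data, manual)

  bad <- event_table("e1", n_t, 10)
  expect_error(recording(sig, 160, bad), "exceeds")
})

test_that("neutral text container round-trips a recording", {
  ev <- event_table(c("e1", "e3"), c(1, 100), c(50, 60))
  sig <- matrix(round(rnorm(64 * 200), 6), nrow = 64)
  rec <- recording(sig, 160, ev, participant_id = 4, run_id = 2)
  stem <- file.path(withr::local_tempdir(), "p4_r2")
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_identical(back$events, rec$events)
  expect_equal(back$signal, rec$signal, ignore_attr = TRUE)
  expect_identical(back$sampling_rate, 160)
  expect_identical(back$participant_id, 4L)

  tsv <- file.path(withr::local_tempdir(), "ev.tsv")
  write_event_table(ev, tsv)
  expect_identical(read_event_table(tsv), ev)
})

test_that("EDF+ files round-trip signal shape, scale and annotations", {
  ev <- event_table(c("e1", "e3", "e1"), c(1, 161, 321), c(80, 80, 80))
  sig <- matrix(round(rnorm(64 * 400, sd = 30)), nrow = 64)
  path <- file.path(withr::local_tempdir(), "run.edf")
  write_minimal_edf(path, sig, fs = 160, events = ev)
  rec <- read_edf(path)
  expect_identical(dim(rec$signal), dim(sig))
  expect_equal(rec$signal, sig, ignore_attr = TRUE, tolerance = 1e-9)
  expect_identical(rec$sampling_rate, 160)
  expect_identical(rec$events, ev)

  # unknown annotation label is a labelled error
  path2 <- file.path(withr::local_tempdir(), "bad.edf")
  write_minimal_edf(path2, sig, fs = 160, events = ev)
  expect_error(read_edf(path2, code_map = c(T1 = "e2")), "code_map")

  # non-64-channel file rejected unless relaxed
  path3 <- file.path(withr::local_tempdir(), "small.edf")
  write_minimal_edf(path3, sig[1:4, , drop = FALSE], fs = 160,
                    events = event_table(), labels = paste0("ch", 1:4))
  expect_error(read_edf(path3), "64 channels")
  rec3 <- read_edf(path3, relaxed = TRUE)
  expect_identical(nrow(rec3$signal), 4L)
  expect_identical(nrow(rec3$events), 0L)  # zero annotations, no error
})

test_that("pooled rest segment concatenates e1 spans across runs", {
  ev <- event_table(c("e1", "e2"), c(1, 20), c(10, 10))
  mk <- function(seed) {
    set.seed(seed)
    recording(matrix(rnorm(64 * 40), 64), 160, ev, participant_id = 1)
  }
  recs <- list(mk(1), mk(2))
  seg <- pooled_rest_segment(recs)
  expect_identical(seg$task, 15L)
  expect_identical(seg$event, 1L)
  expect_identical(ncol(seg$data), 20L)
})
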