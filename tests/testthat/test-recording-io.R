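# Recording model, label schemes, and container round trips.

test_that("recording invariants are enforced", {
  rec <- make_test_recording()
  expect_s3_class(rec, "eeg_recording")
  expect_identical(n_channels(rec), 3L)

  # channel-name / data-row mismatch
  expect_error(
    eeg_recording(matrix(0, 8, 10), 200, paste0("C", 1:7)),
    "format error")
  # duplicated names
  expect_error(
    eeg_recording(matrix(0, 2, 10), 200, c("A", "A")),
    "channel error")
  # non-positive sampling rate
  expect_error(eeg_recording(matrix(0, 1, 10), 0, "A"), "fs")
  # trial beyond the recording
  expect_error(
    eeg_recording(matrix(0, 1, 10), 200, "A",
                  trials = data.frame(start = 0L, end = 11L, label = 0L)),
    "validation error")
  # inverted trial
  expect_error(
    eeg_recording(matrix(0, 1, 10), 200, "A",
                  trials = data.frame(start = 5L, end = 5L, label = 0L)),
    "validation error")
  # NaN guard
  expect_error(
    eeg_recording(matrix(NaN, 1, 10), 200, "A"),
    "validation error")
  # invalid label code for the scheme
  expect_error(
    eeg_recording(matrix(0, 1, 10), 200, "A",
                  trials = data.frame(start = 0L, end = 5L, label = 2L),
                  scheme = "POS_NEG"),
    "label error")
})

test_that("ordinal mapping is bijective and self-inverting", {
  for (scheme in c("POS_NEG", "POS_NEU_NEG")) {
    codes <- scheme_codes(scheme)
    ords <- label_to_ordinal(codes, scheme)
    expect_identical(ordinal_to_label(ords, scheme), codes)
    expect_identical(length(unique(ords)), length(codes))
    # negative < (neutral) < positive on the ordinal axis
    expect_true(all(diff(ords) > 0))
  }
  expect_identical(label_to_ordinal(0L, "POS_NEU_NEG"), -1L)
  expect_identical(ordinal_to_label(-1L, "POS_NEU_NEG"), 0L)
  expect_error(label_to_ordinal(5L, "POS_NEG"), "label error")
  expect_error(scheme_codes("BOGUS"), "unknown class scheme")
})

test_that("valence binarization thresholds at the scale midpoint", {
  expect_identical(binarize_valence(7.2), 1L)   # above 4.5 -> positive
  expect_identical(binarize_valence(3.1), 0L)   # below 4.5 -> negative
  expect_identical(binarize_valence(4.5), 0L)   # boundary -> negative
  expect_identical(binarize_valence(4.5, boundary = "positive"), 1L)
  expect_error(binarize_valence(0.5), "range error")
  expect_error(binarize_valence(9.7), "range error")

  # monotone: rating1 <= rating2 implies class1 <= class2
  ratings <- sort(runif(100, 1, 9))
  classes <- binarize_valence(ratings)
  expect_true(all(diff(classes) >= 0))
})

test_that("GENERIC container round-trips bit-exactly", {
  rec <- make_test_recording(n_ch = 2, n_samp = 1000)
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, path)
  back <- load_recording(path)
  expect_identical(back$data, rec$data)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(as.integer(back$trials$start), as.integer(rec$trials$start))
  expect_identical(as.integer(back$trials$label), as.integer(rec$trials$label))
  expect_identical(back$scheme, rec$scheme)

  # empty-trials recording round-trips too
  rec0 <- eeg_recording(matrix(rnorm(30), 3, 10), 250, c("A", "B", "C"))
  write_recording(rec0, path)
  back0 <- load_recording(path)
  expect_identical(back0$data, rec0$data)
  expect_identical(nrow(back0$trials), 0L)
})

test_that("dialect conventions map labels and sampling rates", {
  # a SEED-style container: ordinal labels -1/0/1, no fs key
  rec <- eeg_recording(matrix(rnorm(3 * 600), 3, 600), 200, c("A", "B", "C"),
                       trials = data.frame(start = c(0L, 200L, 400L),
                                           end = c(200L, 400L, 600L),
                                           label = c(0L, 1L, 2L)),
                       scheme = "POS_NEU_NEG")
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, path)
  obj <- jsonlite::fromJSON(path)
  expect_identical(as.integer(obj$trials$ordinal_label), c(-1L, 0L, 1L))
  obj$fs <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)

  seed_rec <- load_recording(path, dialect = "SEED")
  expect_identical(seed_rec$fs, 200)                 # dialect default
  expect_identical(seed_rec$scheme, "POS_NEU_NEG")
  # ordinal -1 (negative) came back as code 0
  expect_identical(seed_rec$trials$label, c(0L, 1L, 2L))

  # DEAP-style: valence ratings binarized at 4.5, fs default 128
  obj$valence <- c("7.2", "3.1", "4.5")
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  deap_rec <- load_recording(path, dialect = "DEAP")
  expect_identical(deap_rec$fs, 128)
  expect_identical(deap_rec$scheme, "POS_NEG")
  expect_identical(deap_rec$trials$label, c(1L, 0L, 0L))

  # LUMED rejects neutral ordinals
  expect_error(load_recording(path, dialect = "LUMED"), "label error")
})

test_that("corrupt containers fail with named keys", {
  rec <- make_test_recording()
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, path)
  obj <- jsonlite::fromJSON(path)

  for (key in c("channels", "data", "trials", "n_channels")) {
    broken <- obj; broken[[key]] <- NULL
    jsonlite::write_json(broken, path, auto_unbox = TRUE)
    expect_error(load_recording(path), key)
  }
  # 7 channel names against 8 data rows
  rec8 <- eeg_recording(matrix(0, 8, 10), 200, paste0("C", 1:8))
  write_recording(rec8, path)
  obj <- jsonlite::fromJSON(path)
  obj$channels <- obj$channels[1:7]
  obj$n_channels <- 7
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_recording(path), "format error")

  expect_error(load_recording(tempfile()), "not found")
})

test_that("trial tables export to CSV", {
  rec <- make_test_recording()
  path <- withr::local_tempfile(fileext = ".csv")
  export_trials_csv(rec, path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$class, c("negative", "positive"))
  expect_equal(tab$start_s, c(0, 2))
})

test_that("neutral trials drop out when reducing to two classes", {
  rec <- eeg_recording(matrix(rnorm(600), 1, 600), 200, "A",
                       trials = data.frame(start = c(0L, 200L, 400L),
                                           end = c(200L, 400L, 600L),
                                           label = c(0L, 1L, 2L)),
                       scheme = "POS_NEU_NEG")
  two <- to_pos_neg(rec)
  expect_identical(two$scheme, "POS_NEG")
  expect_identical(two$trials$label, c(0L, 1L))
  expect_identical(two$trials$start, c(0L, 400L))
})
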