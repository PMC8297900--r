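test_that("write/read round-trip is the identity on valid sequences", {
  seq1 <- simulate_child(secure_motion_params(), frames = 128, seed = 42,
                         child_id = "rt1")
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_json(seq1, path)
  seq2 <- read_pose_json(path, missing_threshold = 0)
  expect_equal(seq2$child_id, seq1$child_id)
  expect_equal(seq2$frame_rate, seq1$frame_rate)
  expect_equal(seq2$image_width, seq1$image_width)
  expect_equal(seq2$image_height, seq1$image_height)
  expect_equal(seq2$joints, seq1$joints)
  expect_equal(seq2$frame_index, seq1$frame_index)
  expect_equal(seq2$time, seq1$time)
  expect_equal(seq2$x, seq1$x)
  expect_equal(seq2$y, seq1$y)
  expect_equal(seq2$conf, seq1$conf)
  # parsing never drops frames
  expect_equal(n_frames(seq2), n_frames(seq1))
})

test_that("absences survive the round trip as confidence 0", {
  lc <- rep(0.95, 10); lc[3] <- 0
  seq1 <- make_track_sequence(cbind(1:10, 1:10), cbind(21:30, 1:10),
                              left_conf = lc)
  expect_true(is.na(seq1$x[3, "left_wrist"]))
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_json(seq1, path)
  seq2 <- read_pose_json(path)
  expect_identical(unname(seq2$conf[3, "left_wrist"]), 0)
  expect_true(is.na(seq2$x[3, "left_wrist"]))
  expect_false(is.na(seq2$x[4, "left_wrist"]))
})

test_that("zero-confidence keypoints are always absent", {
  seq1 <- make_track_sequence(cbind(c(0, 0), c(0, 0)),
                              cbind(c(10, 10), c(5, 5)),
                              left_conf = c(0, 0.9))
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_json(seq1, path)
  seq2 <- read_pose_json(path, missing_threshold = 0)
  expect_true(is.na(seq2$x[1, "left_wrist"]))
  expect_false(is.na(seq2$x[2, "left_wrist"]))
})

test_that("absence marking is monotone in the missing threshold", {
  lc <- c(0.05, 0.2, 0.5, 0.9, 0.95)
  seq1 <- make_track_sequence(cbind(1:5, 1:5), cbind(11:15, 1:5),
                              left_conf = lc)
  path <- withr::local_tempfile(fileext = ".json")
  write_pose_json(seq1, path)
  absent_at <- function(thr) {
    s <- read_pose_json(path, missing_threshold = thr)
    which(s$conf[, "left_wrist"] == 0)
  }
  a1 <- absent_at(0.1); a2 <- absent_at(0.3); a3 <- absent_at(0.6)
  expect_true(all(a1 %in% a2))
  expect_true(all(a2 %in% a3))
})

test_that("malformed and degenerate pose files raise errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_pose_json(bad), "malformed")

  empty <- withr::local_tempfile(fileext = ".json")
  file.create(empty)
  expect_error(read_pose_json(empty), "empty")

  # inconsistent joint count across frames
  doc <- list(child_id = "x", fps = 30, width = 100, height = 100,
              frames = list(
                list(frame_index = 0, people = list(
                  list(pose_keypoints_2d = rep(c(1, 1, 0.9), 18)))),
                list(frame_index = 1, people = list(
                  list(pose_keypoints_2d = rep(c(1, 1, 0.9), 17))))))
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, p, auto_unbox = TRUE)
  expect_error(read_pose_json(p), "joint count")
})

test_that("per-frame directory dialect concatenates lexicographically", {
  seq1 <- simulate_child(secure_motion_params(), frames = 4, seed = 5,
                         child_id = "dirkid")
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(child_id = "dirkid", fps = 30,
                            width = seq1$image_width,
                            height = seq1$image_height),
                       file.path(dir, "header.json"), auto_unbox = TRUE)
  for (i in 1:4) {
    v <- as.vector(rbind(seq1$x[i, ], seq1$y[i, ], seq1$conf[i, ]))
    v[is.na(v)] <- 0
    jsonlite::write_json(
      list(frame_index = i - 1,
           people = list(list(pose_keypoints_2d = v))),
      file.path(dir, sprintf("frame_%03d.json", i - 1)),
      auto_unbox = TRUE, digits = NA)
  }
  seq2 <- read_pose_json(dir, missing_threshold = 0)
  expect_equal(n_frames(seq2), 4)
  expect_equal(seq2$x, seq1$x)
  expect_equal(seq2$frame_index, 0:3)
})

test_that("largest-person rule keeps the near subject", {
  small <- rep(c(10, 10, 0.9), 18)
  big <- as.vector(rbind(seq(10, 180, 10), seq(10, 180, 10), rep(0.9, 18)))
  doc <- list(child_id = "two", fps = 30, width = 200, height = 200,
              frames = list(list(frame_index = 0, people = list(
                list(pose_keypoints_2d = small),
                list(pose_keypoints_2d = big)))))
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, p, auto_unbox = TRUE)
  expect_message(seq1 <- read_pose_json(p), "2 detected people")
  expect_equal(unname(seq1$x[1, "nose"]), 10)
  expect_equal(unname(seq1$x[1, "left_ear"]), 180)
})

test_that("label tables validate codes and uniqueness", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,label", "c1,B", "c2,D"), p)
  lt <- read_labels(p)
  expect_equal(nrow(lt), 2)
  expect_equal(label_for(lt, "c2"), "D")

  writeLines(c("child_id,label", "c1,B", "c3,X"), p)
  expect_error(read_labels(p), "row\\(s\\) 2.*X")

  writeLines(c("child_id,label", "c1,B", "c1,A"), p)
  expect_error(read_labels(p), "duplicate child_id: c1")
})

test_that("a cohort-scale label table counts secure cases correctly", {
  # marginal composition: 43 B, 4 A, 10 C, 4 D over 61 children
  labs <- rep(c("B", "A", "C", "D"), c(43, 4, 10, 4))
  lt <- label_table(sprintf("c%02d", 1:61), labs)
  p <- withr::local_tempfile(fileext = ".csv")
  write_labels(lt, p)
  lt2 <- read_labels(p)
  expect_equal(sum(is_secure(lt2$label)), 43)
  expect_equal(sum(!is_organised(lt2$label)), 4)
  expect_equal(nrow(lt2), 61)
})
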