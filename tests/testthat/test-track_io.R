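write_fixture <- function(lines, ext = "csv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("generic CSV parses into one track per id, scaled to um", {
  path <- write_fixture(c(
    "track_id,frame,x,y",
    "1,0,0,0", "1,1,10,0", "1,2,20,0",
    "2,0,5,5", "2,1,5,15", "2,2,5,25"))
  co <- read_tracks(path, "generic_csv", scale = 0.65)
  expect_equal(length(co), 2)
  expect_equal(vapply(co$tracks, function(t) length(t$frames), integer(1)),
               c(3L, 3L))
  expect_equal(co$tracks[[1]]$positions[2, 1], 6.5)
  # scale 0.65 um/px turns x_px = 100 into 65 um
  path2 <- write_fixture(c("track_id,frame,x,y", "7,0,100,0", "7,1,100,0"))
  expect_equal(read_tracks(path2, "generic_csv",
                           scale = 0.65)$tracks[[1]]$positions[1, 1], 65)
})

test_that("Fiji manual-tracking dialect and tab delimiters are handled", {
  path <- write_fixture(c(
    "Track n°\tSlice n°\tX\tY",
    "1\t1\t10\t20", "1\t2\t12\t20", "2\t1\t40\t40", "2\t2\t42\t44"))
  co <- read_tracks(path, "manual_tracking_csv")
  expect_equal(length(co), 2)
  expect_equal(co$tracks[[1]]$frames, 0:1)  # slices are 1-based on disk
  expect_equal(co$tracks[[2]]$positions[2, ], c(42, 44))
})

test_that("header names can be remapped via `columns`", {
  path <- write_fixture(c("cell,t,posx,posy",
                          "a,0,1,1", "a,1,2,2", "b,0,3,3", "b,1,4,4"))
  co <- read_tracks(path, "generic_csv",
                    columns = c(track = "cell", frame = "t",
                                x = "posx", y = "posy"))
  expect_equal(length(co), 2)
  expect_error(read_tracks(path, "generic_csv"), "missing column")
})

test_that("degenerate rows are rejected or dropped as specified", {
  dup <- write_fixture(c("track_id,frame,x,y",
                         "1,0,0,0", "1,1,1,0", "1,1,2,0"))
  expect_error(read_tracks(dup, "generic_csv"), "duplicate")
  short <- write_fixture(c("track_id,frame,x,y",
                           "1,0,0,0", "1,1,1,0", "2,0,9,9"))
  expect_warning(co <- read_tracks(short, "generic_csv"), "dropped")
  expect_equal(length(co), 1)
  withz <- write_fixture(c("track_id,frame,x,y,z",
                           "1,0,0,0,3", "1,1,1,0,4"))
  expect_warning(co <- read_tracks(withz, "generic_csv"), "z column")
  expect_equal(ncol(co$tracks[[1]]$positions), 2)
})

test_that("parsing is row-order independent", {
  rows <- c("1,0,0,0", "1,1,10,0", "1,2,20,0",
            "2,0,5,5", "2,1,5,15", "2,2,5,25")
  a <- read_tracks(write_fixture(c("track_id,frame,x,y", rows)),
                   "generic_csv")
  set.seed(51)
  b <- read_tracks(write_fixture(c("track_id,frame,x,y", sample(rows))),
                   "generic_csv")
  expect_identical(a, b)
})

test_that("summary tables round-trip through write/read losslessly", {
  wf <- vertical_wound(0)
  set.seed(52)
  co <- cohort(lapply(1:4, function(i) random_track(8, id = paste0("t", i))))
  s <- summarize_tracks(co, wf)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary(s, path)
  s2 <- read_summary(path)
  expect_equal(names(s2), names(s))
  for (col in c("d_net", "d_tot", "meandering_index", "mean_speed",
                "mean_v_ap"))
    expect_equal(s2[[col]], s[[col]], tolerance = 1e-9)
  # empty table -> header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_summary(s[0, ], path2)
  expect_length(readLines(path2), 1)
})

test_that("JSON and YAML configs build the same wound frame", {
  js <- write_fixture(c(
    '{"wound_edge": [[0, -150], [0, 150]], "ap_axis": [-1, 0],',
    ' "scale": 0.65, "frame_interval": 1, "t_start": 60}'), ext = "json")
  yml <- write_fixture(c("wound_edge:", "  - [0, -150]", "  - [0, 150]",
                         "ap_axis: [-1, 0]", "scale: 0.65"), ext = "yaml")
  a <- read_config(js)
  b <- read_config(yml)
  expect_equal(a$wound, b$wound)
  expect_equal(a$scale, 0.65)
  expect_equal(a$classify_threshold, 200)  # defaults filled in
  expect_equal(a$arrival_radius, 20)
  expect_equal(b$recruit_band, 200)
  expect_equal(distance_to_wound(c(100, 0), a$wound), 100)
})

test_that("cohorts round-trip through write_tracks/read_tracks", {
  set.seed(53)
  co <- cohort(lapply(1:3, function(i) random_track(6, id = as.character(i))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(co, path)
  back <- read_tracks(path, "generic_csv")
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back$tracks[[i]]$frames, co$tracks[[i]]$frames)
    expect_equal(back$tracks[[i]]$positions, co$tracks[[i]]$positions,
                 tolerance = 1e-9)
  }
})
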