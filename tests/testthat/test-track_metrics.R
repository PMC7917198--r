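test_that("displacement measures match hand-computed geometry", {
  expect_equal(net_displacement(make_track(rbind(c(0, 0), c(3, 4)))), 5)
  loop <- make_track(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  expect_equal(net_displacement(loop), 0)
  expect_equal(total_displacement(loop), 4)
  line3 <- make_track(cbind(0:3, 0))
  expect_equal(net_displacement(line3), 3)
  expect_equal(total_displacement(line3), 3)
  expect_equal(meandering_index(line3), 1)
  # two unit steps at a right angle
  elbow <- make_track(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(total_displacement(elbow), 2)
  expect_equal(net_displacement(elbow), sqrt(2))
  expect_equal(meandering_index(elbow), sqrt(2) / 2)
})

test_that("meandering index of a stationary cell is NA, not coerced", {
  still <- make_track(rbind(c(5, 5), c(5, 5), c(5, 5)))
  expect_message(mi <- meandering_index(still), "undefined")
  expect_true(is.na(mi))
  expect_equal(meandering_index(make_track(rbind(c(0, 0), c(0, 0), c(0, 0),
                                                 c(0, 1)))), 1)
})

test_that("mean speed is path length over elapsed tracking time", {
  expect_equal(mean_speed(make_track(cbind(c(0, 2, 4), 0))), 2)
  expect_equal(mean_speed(make_track(rbind(c(1, 1), c(1, 1), c(1, 1)))), 0)
  # d_tot = 10 um over 4 contiguous 1-min intervals
  expect_equal(mean_speed(make_track(cbind(c(0, 4, 6, 8, 10), 0))), 2.5)
  # gap frames count in elapsed time: step spans the gap, no interpolation
  gappy <- make_track(rbind(c(0, 0), c(2, 0), c(8, 0)), frames = c(0, 1, 4))
  expect_equal(total_displacement(gappy), 8)
  expect_equal(mean_speed(gappy), 8 / 4)
  # halving the frame interval doubles the speed
  expect_equal(mean_speed(make_track(cbind(c(0, 2, 4), 0), dt = 0.5)), 4)
})

test_that("distance to wound is the clamped point-to-segment minimum", {
  wf <- vertical_wound(x = 500)
  expect_equal(distance_to_wound(c(300, 100), wf), 200)
  expect_equal(distance_to_wound(c(500, 0), wf), 0)
  # beyond a segment endpoint the distance is to the endpoint
  expect_equal(distance_to_wound(c(500, 300), wf), 100)
  expect_equal(distance_to_wound(c(510, 300), wf), sqrt(100^2 + 10^2))
  # vectorized over rows
  expect_equal(distance_to_wound(rbind(c(300, 0), c(450, 0)), wf), c(200, 50))
})

test_that("distance to a random polyline agrees with dense-sampling oracle", {
  set.seed(11)
  for (rep in 1:20) {
    verts <- matrix(runif(8, -100, 100), ncol = 2)
    wf <- wound_frame(verts, ap_axis = c(1, 0))
    p <- runif(2, -150, 150)
    expect_equal(distance_to_wound(p, wf),
                 oracle_polyline_distance(p, verts),
                 tolerance = 1e-6)
  }
})

test_that("classification uses only the first frame, boundary inclusive", {
  wf <- vertical_wound(0, toward = c(-1, 0))
  far <- make_track(rbind(c(250, 0), c(10, 0)))
  expect_equal(classify_track(far, wf), "distant")
  expect_equal(classify_track(make_track(rbind(c(200, 0), c(300, 0))), wf),
               "local_resident")  # exactly 200 um is within the band
  expect_equal(classify_track(make_track(rbind(c(20, 0), c(400, 0))), wf),
               "local_resident")
  # truncating after the first step cannot change the category
  expect_equal(classify_track(make_track(far$positions[1:2, ]), wf),
               classify_track(far, wf))
})

test_that("arrival and retention follow the 20 um capture radius", {
  wf <- vertical_wound(0)
  approach <- make_track(cbind(c(100, 50, 20, 5), 0))
  st <- arrival_status(approach, wf)
  expect_true(st$arrived)
  expect_equal(st$first_arrival_time, 2)  # 20 um is inclusive
  expect_true(st$stayed)
  never <- arrival_status(make_track(cbind(c(100, 80, 60), 0)), wf)
  expect_false(never$arrived)
  expect_true(is.na(never$first_arrival_time))
  # touches then leaves
  bounce <- arrival_status(make_track(cbind(c(100, 15, 60, 70), 0)), wf)
  expect_true(bounce$arrived)
  expect_equal(bounce$first_arrival_time, 1)
  expect_false(bounce$stayed)
})

test_that("recruited-cell counting matches hand counts", {
  wf <- vertical_wound(0)
  pts <- cbind(c(50, 150, 300), 0)
  expect_equal(count_recruited(pts, wf), 2)
  expect_equal(count_recruited(matrix(numeric(), 0, 2), wf), 0L)
  expect_equal(count_recruited(cbind(c(10, 199, 200), 0), wf), 3)
})

test_that("metric invariants hold on random tracks", {
  set.seed(21)
  for (rep in 1:200) {
    tr <- random_track(n = sample(3:20, 1))
    dn <- net_displacement(tr); dt_ <- total_displacement(tr)
    expect_lte(dn, dt_ + 1e-12)
    mi <- meandering_index(tr)
    expect_true(mi >= 0 && mi <= 1)
    wf <- vertical_wound(0)
    expect_lte(abs(v_ap(tr, wf)$mean_v_ap), mean_speed(tr) + 1e-12)
  }
})

test_that("d_net, d_tot and speed are rigid-motion invariant", {
  set.seed(22)
  for (rep in 1:50) {
    tr <- random_track(n = 12)
    ang <- runif(1, 0, 2 * pi); shift <- runif(2, -50, 50)
    tr2 <- make_track(rigid_transform(tr$positions, ang, shift))
    expect_equal(net_displacement(tr2), net_displacement(tr))
    expect_equal(total_displacement(tr2), total_displacement(tr))
    expect_equal(mean_speed(tr2), mean_speed(tr))
  }
})

test_that("cohort summary table carries the full metric set", {
  wf <- vertical_wound(0)
  co <- cohort(list(
    make_track(cbind(c(250, 240, 230), 0), id = "a"),
    make_track(cbind(c(100, 50, 10), 0), id = "b")))
  s <- summarize_tracks(co, wf)
  expect_equal(nrow(s), 2)
  expect_named(s, c("track_id", "cell_type", "group", "d_net", "d_tot",
                    "meandering_index", "mean_speed", "mean_v_ap",
                    "category", "arrived", "first_arrival_time",
                    "stayed_at_wound"))
  expect_equal(s$category, c("distant", "local_resident"))
  expect_equal(s$arrived, c(FALSE, TRUE))
  expect_equal(s$mean_v_ap, c(10, 45))
})
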