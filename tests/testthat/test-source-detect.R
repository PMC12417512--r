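# Singularity scan, track clustering, activity, classification, summary
# maps and cohort tallies.

seg_of <- function(field, idx = 1L) {
  structure(list(segment_index = idx, u = field$u, v = field$v),
            class = "segment_flow")
}

test_that("ideal radial and vortex fields yield extreme ring indices", {
  G <- 32
  hp <- egf_params()
  centre <- c(3, 3.5)
  rad <- singularity_scan(seg_of(ideal_field(G, centre, "radial")), hp)
  expect_equal(nrow(rad), 1)
  expect_gte(rad$radial_index, 0.99)
  expect_lte(abs(rad$tangential_index), 0.01)
  expect_lt(grid_distance(c(rad$s, rad$e), centre), 0.5)
  vor <- singularity_scan(seg_of(ideal_field(G, centre, "vortex")), hp)
  expect_equal(nrow(vor), 1)
  expect_gte(abs(vor$tangential_index), 0.99)
  expect_lte(abs(vor$radial_index), 0.01)
  expect_lt(grid_distance(c(vor$s, vor$e), centre), 0.5)
})

test_that("radial + drift field: scan matches the exhaustive grid oracle", {
  G <- 24
  hp <- egf_params(interp_grid = 24L)
  centre <- c(5, 4)
  f <- ideal_field(G, centre, "radial", drift = c(0.3, 0.15))
  got <- singularity_scan(seg_of(f), hp)
  expect_gte(nrow(got), 1)
  oracle <- reference_ring_argmax(f$u, f$v, radius = hp$singularity_radius,
                                  m = hp$ring_samples)
  expect_lt(grid_distance(c(got$s[1], got$e[1]), c(oracle$s, oracle$e)), 1)
  expect_equal(got$radial_index[1], oracle$radial, tolerance = 0.02)
})

test_that("ring indices satisfy the unit-disc bound", {
  set.seed(71)
  G <- 16
  hp <- egf_params(interp_grid = 16L)
  for (rep in 1:5) {
    u <- matrix(rnorm(G * G), G, G); v <- matrix(rnorm(G * G), G, G)
    f <- ring_index_fields(u, v, hp)
    expect_true(all(f$radial^2 + f$tangential^2 <= 1 + 1e-9))
  }
})

test_that("clustering builds tracks with the prevalence arithmetic", {
  hp <- egf_params()
  # same position in all 59 segments -> one track, prevalence 100
  s59 <- data.frame(s = 3, e = 3, radial_index = 0.95, tangential_index = 0.01,
                    segment_index = 1:59)
  tr <- cluster_tracks(s59, 59, hp)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$prevalence_pct, 100)
  # singleton -> 100/59
  s1 <- data.frame(s = 1, e = 1, radial_index = 0.9, tangential_index = 0,
                   segment_index = 17L)
  tr1 <- cluster_tracks(s1, 59, hp)
  expect_equal(tr1[[1]]$prevalence_pct, 100 / 59, tolerance = 1e-12)
  expect_equal(round(tr1[[1]]$prevalence_pct, 1), 1.7)
  # two generators 4 units apart stay two tracks
  g1 <- data.frame(s = 1, e = 2, radial_index = 0.95, tangential_index = 0,
                   segment_index = 1:40)
  g2 <- data.frame(s = 5, e = 2, radial_index = 0.9, tangential_index = 0,
                   segment_index = 5:59)
  tr2 <- cluster_tracks(rbind(g1, g2), 59, hp)
  expect_length(tr2, 2)
  prevs <- sort(vapply(tr2, `[[`, 0, "prevalence_pct"))
  expect_equal(prevs, sort(c(100 * 40 / 59, 100 * 55 / 59)))
  # prevalence of every track lies in [100/n_segments, 100]
  for (t in tr2) {
    expect_gte(t$prevalence_pct, 100 / 59)
    expect_lte(t$prevalence_pct, 100)
  }
})

test_that("centroids use the periodic metric across the H-A seam", {
  hp <- egf_params()
  sng <- data.frame(s = c(7.8, 0.2), e = c(3, 3), radial_index = 0.9,
                    tangential_index = 0, segment_index = 1:2)
  tr <- cluster_tracks(sng, 10, hp)
  expect_length(tr, 1)  # 0.4 apart periodically, not 7.6
  expect_true(tr[[1]]$centroid[["s"]] > 7.9 || tr[[1]]$centroid[["s"]] < 0.1)
})

test_that("activity is the quality-weighted mean detection", {
  hp <- egf_params()
  mk_track <- function(det) {
    structure(list(id = 1L, centroid = c(s = 3, e = 3),
                   members = data.frame(s = 3, e = 3, radial_index = 0.9,
                                        tangential_index = 0,
                                        segment_index = 1L),
                   segments = 1L, n_segments = length(det),
                   prevalence_pct = 100 * mean(det > 0),
                   segment_detection = det,
                   mean_abs_tangential = 0, mean_radial = 0.9,
                   type = "focal", activity_pct = NA_real_,
                   dominant = NA, significant = NA),
              class = "source_track")
  }
  # d = 1 everywhere, all admissible -> 100 %
  expect_equal(activity_of_track(mk_track(rep(1, 50)), NULL, hp), 100)
  # the printed-arithmetic construction: 29 of 100 segment-units -> 29 %
  expect_equal(activity_of_track(mk_track(rep(c(1, 0), c(29, 71))), NULL, hp),
               29)
  # admissibility zero near the source in half the segments (where d = 1),
  # d = 0.5 elsewhere -> weighted mean 50 %
  det <- rep(c(1, 0.5), each = 10)
  qual <- list(admissible = matrix(TRUE, 64, 20))
  near <- which(grid_distance(electrode_grid_positions(),
                              matrix(c(3, 3), 64, 2, byrow = TRUE)) <= hp$cluster_radius)
  qual$admissible[near, 1:10] <- FALSE
  class(qual) <- "quality_mask"
  expect_equal(activity_of_track(mk_track(det), qual, hp), 50)
  # all weights zero -> 0
  qual0 <- list(admissible = matrix(FALSE, 64, 20))
  class(qual0) <- "quality_mask"
  expect_equal(activity_of_track(mk_track(det), qual0, hp), 0)
  # empty track errors
  tr <- mk_track(rep(1, 5)); tr$members <- tr$members[0, ]
  expect_error(activity_of_track(tr, NULL, hp), "empty track")
})

test_that("classification boundaries follow the clinical thresholds", {
  hp <- egf_params()
  base <- structure(list(prevalence_pct = 15, activity_pct = 17,
                         mean_abs_tangential = 0.2),
                    class = "source_track")
  t1 <- classify_and_flag(base, hp)
  expect_false(t1$dominant); expect_false(t1$significant)
  expect_equal(t1$type, "focal")
  t2 <- classify_and_flag(modifyList(base, list(activity_pct = 32,
                                                prevalence_pct = 29)), hp)
  expect_true(t2$significant); expect_true(t2$dominant)
  # dominance is strict at 20; significance closed at 26.5; curl closed at 0.7
  t3 <- classify_and_flag(modifyList(base, list(prevalence_pct = 20)), hp)
  expect_false(t3$dominant)
  t4 <- classify_and_flag(modifyList(base, list(prevalence_pct = 20.01)), hp)
  expect_true(t4$dominant)
  t5 <- classify_and_flag(modifyList(base, list(activity_pct = 26.5)), hp)
  expect_true(t5$significant)
  t6 <- classify_and_flag(modifyList(base, list(mean_abs_tangential = 0.7)), hp)
  expect_equal(t6$type, "rotational")
  t7 <- classify_and_flag(modifyList(base, list(mean_abs_tangential = 0.69)), hp)
  expect_equal(t7$type, "focal")
})

test_that("summary heat reflects per-segment singularity occupancy", {
  hp <- egf_params()
  # persistent singularity: heat ~ 1 at its pixel, decaying outside radius
  s59 <- data.frame(s = 4, e = 3.5, radial_index = 0.95,
                    tangential_index = 0, segment_index = 1:59)
  tracks <- cluster_tracks(s59, 59, hp)
  m <- summary_map(tracks, s59, 59, hp)
  expect_equal(max(m$heat), 1)
  G <- hp$interp_grid
  pc <- egflow:::pixel_coords(G)
  px <- as.matrix(expand.grid(s = pc$s, e = pc$e))
  d <- grid_distance(px, matrix(c(4, 3.5), nrow(px), 2, byrow = TRUE))
  expect_true(all(m$heat[d > hp$cluster_radius] == 0))
  expect_true(all(m$heat[d <= hp$cluster_radius] == 1))
  # no singularities -> all-zero heat
  m0 <- summary_map(list(), s59[0, ], 59, hp)
  expect_equal(max(m0$heat), 0)
  # two tracks at prevalence 0.8 / 0.3: local maxima ratio near 8/3
  set.seed(72)
  segs_a <- sort(sample(1:59, round(0.8 * 59)))
  segs_b <- sort(sample(1:59, round(0.3 * 59)))
  sng <- rbind(
    data.frame(s = 1, e = 2, radial_index = 0.95, tangential_index = 0,
               segment_index = segs_a),
    data.frame(s = 5, e = 5, radial_index = 0.9, tangential_index = 0,
               segment_index = segs_b))
  m2 <- summary_map(cluster_tracks(sng, 59, hp), sng, 59, hp)
  peak_at <- function(p) {
    d <- grid_distance(px, matrix(p, nrow(px), 2, byrow = TRUE))
    max(m2$heat[d < 1])
  }
  ratio <- peak_at(c(1, 2)) / peak_at(c(5, 5))
  expect_gte(ratio, 2.2); expect_lte(ratio, 3.1)
})

test_that("cohort statistics reproduce the dominant-source arithmetic", {
  hp <- egf_params()
  mk_map <- function(pid, atrium, n_dom, n_sub) {
    mk <- function(prev) {
      structure(list(id = 1L, centroid = c(s = 1, e = 1),
                     prevalence_pct = prev, activity_pct = prev,
                     dominant = prev > hp$prevalence_dominant_pct,
                     significant = FALSE, type = "focal",
                     segment_detection = numeric(0)),
                class = "source_track")
    }
    tracks <- c(replicate(n_dom, mk(50), simplify = FALSE),
                replicate(n_sub, mk(10), simplify = FALSE))
    structure(list(heat = matrix(0, 4, 4), tracks = tracks, n_segments = 59,
                   meta = list(patient_id = pid, atrium = atrium)),
              class = "summary_map")
  }
  # 278 dominant tracks across 182 harboring patients -> 1.5 per harborer
  doms <- c(rep(2, 96), rep(1, 86))   # 2*96 + 86 = 278 over 182 patients
  maps <- c(
    lapply(seq_along(doms), function(i) {
      mk_map(sprintf("D%03d", i), if (i %% 2) "LA" else "RA", doms[i], 3)
    }),
    lapply(1:40, function(i) mk_map(sprintf("N%03d", i), "LA", 0, 5))
  )
  cs <- cohort_stats(maps)
  expect_equal(cs$n_dominant, 278)
  expect_equal(cs$n_patients_with_dominant, 182)
  expect_equal(cs$mean_dominant_per_harboring, 1.5)
  expect_equal(cs$n_sources, 278 + 182 * 3 + 40 * 5)
  # 10 patients with exactly 2 dominant each
  cs2 <- cohort_stats(lapply(1:10, function(i) mk_map(paste0("P", i), "LA", 2, 0)))
  expect_equal(cs2$mean_dominant_per_harboring, 2.0)
  expect_equal(cs2$n_patients_with_dominant, 10)
  # zero dominant tracks -> harboring 0, mean reported as NA
  cs0 <- cohort_stats(lapply(1:5, function(i) mk_map(paste0("Q", i), "RA", 0, 2)))
  expect_equal(cs0$n_patients_with_dominant, 0)
  expect_true(is.na(cs0$mean_dominant_per_harboring))
})

test_that("track JSON export carries the full SourceTrack schema", {
  hp <- egf_params()
  s10 <- data.frame(s = 2, e = 2, radial_index = 0.93, tangential_index = 0.05,
                    segment_index = 1:10)
  tracks <- lapply(cluster_tracks(s10, 10, hp), function(t) {
    t$activity_pct <- activity_of_track(t, NULL, hp)
    classify_and_flag(t, hp)
  })
  m <- summary_map(tracks, s10, 10, hp)
  js <- jsonlite::fromJSON(tracks_to_json(m), simplifyVector = FALSE)
  expect_length(js, 1)
  expect_setequal(names(js[[1]]),
                  c("id", "centroid", "prevalence_pct", "activity_pct",
                    "segment_detection", "type", "dominant", "significant"))
  expect_equal(js[[1]]$prevalence_pct, 100)
})
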