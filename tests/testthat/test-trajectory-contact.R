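test_that("distances from multi-model PDBs are Euclidean, in model order", {
  # 3-4-5 triangle in a single model
  p1 <- write_multimodel_pdb(list(rbind(c(0, 0, 0), c(3, 4, 0))))
  s1 <- distance_series_from_models(p1, test_metric())
  expect_equal(s1$distances, 5)

  # coincident atoms in two identical models
  p2 <- write_multimodel_pdb(rep(list(rbind(c(1, 1, 1), c(1, 1, 1))), 2))
  s2 <- distance_series_from_models(p2, test_metric())
  expect_equal(s2$distances, c(0, 0))

  # atom b stepping +1 A along z from 1 A
  coords <- lapply(1:5, function(z) rbind(c(0, 0, 0), c(0, 0, z)))
  s3 <- distance_series_from_models(write_multimodel_pdb(coords),
                                    test_metric(),
                                    frame_times = c(0, 10, 20, 30, 40))
  expect_equal(s3$distances, c(1, 2, 3, 4, 5))
  expect_equal(s3$times, c(0, 10, 20, 30, 40))
})

test_that("model distances are invariant under rigid translation", {
  set.seed(42)
  coords <- lapply(1:8, function(i) matrix(rnorm(6, sd = 4), nrow = 2))
  shift <- c(12.3, -7.1, 99)
  shifted <- lapply(coords, function(m) sweep(m, 2L, -shift))
  d0 <- distance_series_from_models(write_multimodel_pdb(coords),
                                    test_metric())
  d1 <- distance_series_from_models(write_multimodel_pdb(shifted),
                                    test_metric())
  expect_equal(d1$distances, d0$distances, tolerance = 1e-6)
})

test_that("model reader rejects bad selectors and time mismatches", {
  p <- write_multimodel_pdb(list(rbind(c(0, 0, 0), c(3, 4, 0))))
  bad <- contact_metric("x", atom_a = list(resno = 999, elety = "N"),
                        atom_b = list(resno = 900, elety = "PG"),
                        threshold = 5)
  expect_error(distance_series_from_models(p, bad), "matched no atom")
  expect_error(
    distance_series_from_models(p, test_metric(), frame_times = c(0, 1)),
    "2 frame times .* 1 models"
  )
})

test_that("contact fraction counts frames strictly below the threshold", {
  expect_equal(contact_fraction(distance_series(c(4, 4.5, 4.9, 4.2)), 5), 1)
  expect_equal(contact_fraction(distance_series(c(4, 6, 4, 6)), 5), 0.5)
  # ties at the threshold are not in contact
  expect_equal(contact_fraction(distance_series(c(5, 5, 4)), 5), 1 / 3)
})

test_that("contact fraction matches the brute-force oracle and is monotone", {
  set.seed(7)
  for (i in 1:100) {
    d <- runif(sample(1:50, 1), 0, 12)
    thr <- runif(1, 0.5, 12)
    s <- distance_series(d)
    expect_equal(contact_fraction(s, thr), brute_force_fraction(d, thr))
  }
  d <- runif(200, 0, 12)
  s <- distance_series(d)
  fracs <- vapply(seq(0.5, 14, by = 0.5), contact_fraction,
                  numeric(1), series = s)
  expect_true(all(diff(fracs) >= 0))
})

test_that("pooled occupancy is frame-weighted, not replicate-averaged", {
  full <- distance_series(rep(3, 50))
  expect_equal(pooled_contact_fraction(list(full, full, full), 5), 1)

  lo <- distance_series(rep(10, 30))
  hi <- distance_series(rep(3, 30))
  expect_equal(pooled_contact_fraction(list(lo, hi), 5), 0.5)

  # 100 frames all-in-contact + 300 frames none: 100/400
  a <- distance_series(rep(3, 100))
  b <- distance_series(rep(10, 300))
  expect_equal(pooled_contact_fraction(list(a, b), 5), 0.25)

  # k identical replicates pool to the single-series fraction
  s <- distance_series(runif(40, 2, 8))
  expect_equal(pooled_contact_fraction(rep(list(s), 4), 5),
               contact_fraction(s, 5))

  mixed <- list(distance_series(1:3, metric = "lambda"),
                distance_series(1:3, metric = "sigma"))
  expect_error(pooled_contact_fraction(mixed, 5), "mix metrics")
})

test_that("distance summaries pool frames with sample SD", {
  s <- summarize_distances(distance_series(rep(5, 10)), threshold = 7)
  expect_equal(s$mean_distance, 5)
  expect_equal(s$sd_distance, 0)

  two <- summarize_distances(distance_series(c(3, 5)), threshold = 7)
  expect_equal(two$mean_distance, 4)
  expect_equal(two$sd_distance, sqrt(2), tolerance = 1e-6)
  expect_equal(two$n_frames_total, 2)

  expect_error(summarize_distances(list()), "at least one")
})

test_that("summaries recover generator distance parameters", {
  gen <- gen_distance_series(n_frames = 10000, occupancy = 1,
                             mean_contact = 6.6, sd_contact = 0.2,
                             metric = "sigma", seed = 99)
  s <- summarize_distances(gen$series, threshold = 7)
  expect_lt(abs(s$mean_distance - 6.6), 0.05)
  expect_lt(abs(s$sd_distance - 0.2), 0.05)
})

test_that("distance CSV round-trips through disk", {
  series <- list(
    distance_series(c(3.1, 4.2, 5.3), times = c(0, 1, 2),
                    metric = "lambda", replicate_id = "r1"),
    distance_series(c(8, 9), times = c(0, 1),
                    metric = "lambda", replicate_id = "r2")
  )
  path <- tempfile(fileext = ".csv")
  write_distance_csv(series, path)
  back <- read_distance_csv(path)
  expect_length(back, 2)
  key <- vapply(back, `[[`, character(1), "replicate_id")
  expect_setequal(key, c("r1", "r2"))
  expect_equal(back[[which(key == "r1")]]$distances, c(3.1, 4.2, 5.3))
})
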