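test_that("OAV is the concentration / threshold ratio with unit checks", {
  expect_equal(compute_oav(10, 5), 2)
  expect_equal(compute_oav(0, 5), 0)
  expect_equal(compute_oav(5, 5), 1)
  expect_error(compute_oav(1, 0), class = "vinosense_validation_error")
  expect_error(compute_oav(1, -1), class = "vinosense_validation_error")
  expect_error(compute_oav(1, 1, conc_units = "mg/L", opt_units = "ug/L"),
               class = "vinosense_validation_error")
})

test_that("activity flagging uses a strict inequality and scans every cell", {
  tab <- oav_table(matrix(c(0.2, 0.21, 0.19, 0.0), 2, 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))),
                   series_ids = list(1L, 2L))
  fl <- flag_active(tab)
  # column-major fill: a = (0.2, 0.19), b = (0.21, 0.0)
  expect_false(fl$flags["a", "s1"])        # 0.2 exactly: not active
  expect_false(fl$flags["a", "s2"])
  expect_true(fl$flags["b", "s1"])
  expect_identical(fl$active_compounds, "b")

  f <- load_fivewine_fixture()
  ff <- flag_active(f)
  expect_true(ff$flags["Hexanal", "WY"])   # 0.33 > 0.2
  # independent brute-force scan of the packaged matrix
  expect_equal(ff$n_active, sum(apply(f$oav > 0.2, 1L, any)))
  expect_error(flag_active(f, threshold = 0),
               class = "vinosense_validation_error")
})

test_that("series scores are sums of member OAVs, multi-assignment counted fully", {
  f <- load_fivewine_fixture()
  prof <- series_profile(f)

  # green fruit in the spontaneous-fermentation wine: the five member rows
  members <- vapply(f$series_ids, function(s) 3L %in% s, TRUE)
  expect_equal(sum(f$oav[members, "WY"]), 3.4871)
  expect_equal(prof["WY", "green fruit"], 3.4871)

  # a compound assigned to floral and honey contributes fully to both
  both <- f$oav["2-Phenylethyl acetate", "WY"]
  expect_equal(both, 15)
  single <- oav_table(matrix(both, 1, 1, dimnames = list("x", "WY")),
                      list(c(5L, 10L)))
  p1 <- series_profile(single)
  expect_equal(p1[1, "floral"], 15)
  expect_equal(p1[1, "honey"], 15)

  # singleton sum
  one <- oav_table(matrix(2.5, 1, 1, dimnames = list("x", "s")), list(4L))
  expect_equal(unname(series_profile(one)[1, ]),
               c(0, 0, 0, 2.5, rep(0, 7)))
})

test_that("volatile tables must be fully mapped (or explicitly excluded)", {
  vol <- load_volatile_table(tmp_wide_csv())
  map <- load_threshold_map(tmp_threshold_csv(
    c("limonene,0.015,1;7,citrus-like", "hexanal,0.5,4,green")))
  err <- expect_error(series_profile(vol, map),
                      class = "vinosense_validation_error")
  expect_match(conditionMessage(err), "acetoin")
  expect_warning(p <- series_profile(vol, map, exclude_unmapped = "acetoin"),
                 "acetoin")
  expect_equal(unname(p["S1", "citrus"]), 10 / 0.015)
})

test_that("series aggregation is additive, scale-equivariant and conserving", {
  f <- load_fivewine_fixture()
  for (seed in 1:3) {
    set.seed(seed)
    part <- sample(c(TRUE, FALSE), 57, replace = TRUE)
    a <- oav_table(f$oav[part, , drop = FALSE], f$series_ids[part])
    b <- oav_table(f$oav[!part, , drop = FALSE], f$series_ids[!part])
    expect_equal(unclass(series_profile(a)) + unclass(series_profile(b)),
                 unclass(series_profile(f)))
  }
  # scale equivariance
  c_fac <- 3.7
  scaled <- oav_table(f$oav * c_fac, f$series_ids)
  expect_equal(unclass(series_profile(scaled)),
               c_fac * unclass(series_profile(f)))
  # total conservation: row sums equal multiplicity-weighted OAV sums
  prof <- series_profile(f)
  mult <- lengths(f$series_ids)
  expect_equal(unname(rowSums(unclass(prof))),
               unname(colSums(f$oav * mult)))
})

test_that("series summaries reproduce hand-computed means and handle edge cases", {
  f <- load_fivewine_fixture()
  prof <- series_profile(f)
  sm <- series_summary(prof)

  # independent oracle: per-wine member sums, averaged
  oracle_mean <- function(k) {
    members <- vapply(f$series_ids, function(s) k %in% s, TRUE)
    mean(colSums(f$oav[members, , drop = FALSE]))
  }
  expect_equal(sm$mean[sm$series == "creamy"], oracle_mean(6))
  expect_equal(sm$mean[sm$series == "creamy"], 4.264, tolerance = 1e-3)
  expect_equal(sm$mean[sm$series == "waxy"], oracle_mean(11))
  expect_equal(sm$mean[sm$series == "waxy"], 5.657, tolerance = 1e-3)
  expect_true(all(sm$min <= sm$mean & sm$mean <= sm$max))
  expect_true(all(sm$sd >= 0))

  # constant column degenerates to sd 0, min = max = mean
  const <- matrix(2, 4, 11, dimnames = list(paste0("s", 1:4),
                                            odorant_series_names()))
  class(const) <- c("series_profile", class(const))
  smc <- series_summary(const)
  expect_true(all(smc$sd == 0) && all(smc$min == smc$mean))

  expect_error(series_summary(prof[1, , drop = FALSE]),
               class = "vinosense_validation_error")
})
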