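test_that("reader round-trips generated records and preserves every field", {
  rec <- simulate_isotopes(default_study_design(), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_isotope_table(rec, f)
  back <- read_isotope_table(f)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$individual_id, rec$individual_id)
  expect_equal(back$tissue, rec$tissue)
  expect_equal(back$d13C, rec$d13C, tolerance = 1e-12)
  expect_equal(back$d15N, rec$d15N, tolerance = 1e-12)

  # tab dialect round-trips too
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_isotope_table(rec, ft, delim = "\t")
  expect_equal(read_isotope_table(ft, delim = "\t")$d15N, rec$d15N,
               tolerance = 1e-12)
})

test_that("default design emits 111 individuals in the four published group sizes", {
  rec <- simulate_isotopes(default_study_design(), seed = 1)
  expect_equal(length(unique(rec$individual_id)), 111L)
  sizes <- dplyr::count(dplyr::distinct(rec, individual_id, species, season),
                        species, season)
  expect_setequal(sizes$n, c(25L, 18L, 31L, 37L))
  # 3 tissues per non-breeding individual, 2 per breeding individual
  expect_equal(nrow(rec), 3L * (25L + 18L) + 2L * (31L + 37L))
})

test_that("reader reports schema, parse and duplicate errors precisely", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,species,season,campaign,tissue,d13C",
               "a,sp,breeding,c1,plasma,-15"), f)
  expect_error(read_isotope_table(f), class = "nichepart_schema_error")
  expect_error(read_isotope_table(f), "d15N")

  writeLines(c("individual_id,species,season,campaign,tissue,d13C,d15N",
               "a,sp,breeding,c1,plasma,-15,17",
               "b,sp,breeding,c1,plasma,NA,17"), f)
  expect_error(read_isotope_table(f), class = "nichepart_parse_error")
  expect_error(read_isotope_table(f), "row 2")

  writeLines(c("individual_id,species,season,campaign,tissue,d13C,d15N",
               "a,sp,breeding,c1,plasma,-15,17",
               "a,sp,breeding,c2,plasma,-14,16"), f)
  expect_error(read_isotope_table(f), class = "nichepart_validation_error")
})

test_that("standardize centres and scales each tissue with the n-1 divisor", {
  rec <- tibble::tibble(
    individual_id = c("a", "b", "c"), species = "sp", season = "breeding",
    campaign = "c1", tissue = "plasma",
    d13C = c(-14, -15, -16), d15N = c(18, 17, 16)
  )
  std <- standardize(rec)
  expect_equal(std$z13C, c(1, 0, -1))
  expect_equal(std$z15N, c(1, 0, -1))

  rec <- simulate_isotopes(default_study_design(), seed = 2)
  std <- standardize(rec)
  pooled <- std |>
    dplyr::group_by(tissue) |>
    dplyr::summarise(m13 = mean(z13C), s13 = sd(z13C),
                     m15 = mean(z15N), s15 = sd(z15N))
  expect_true(all(abs(pooled$m13) < 1e-10))
  expect_true(all(abs(pooled$m15) < 1e-10))
  expect_true(all(abs(pooled$s13 - 1) < 1e-10))
  expect_true(all(abs(pooled$s15 - 1) < 1e-10))
})

test_that("stored standardisation table reproduces z values and species contrasts scale as Delta/s", {
  rec <- simulate_isotopes(default_study_design(), seed = 3)
  std <- standardize(rec)
  again <- apply_standardization(rec, standardization_table(std))
  expect_equal(again$z13C, std$z13C, tolerance = 1e-12)
  expect_equal(again$z15N, std$z15N, tolerance = 1e-12)

  # two species with means differing by Delta and common raw SD s:
  # the standardized species-mean difference is Delta / s
  one_tissue <- rec |> dplyr::filter(tissue == "plasma")
  delta <- diff(tapply(one_tissue$d13C, one_tissue$species, mean))
  s <- standardization_table(std) |>
    dplyr::filter(tissue == "plasma") |>
    dplyr::pull(sd_d13C)
  stdk <- std |> dplyr::filter(tissue == "plasma")
  delta_z <- diff(tapply(stdk$z13C, stdk$species, mean))
  expect_equal(unname(delta_z), unname(delta) / s, tolerance = 1e-12)
})

test_that("standardize is idempotent up to floating tolerance", {
  rec <- simulate_isotopes(default_study_design(), seed = 4)
  std1 <- standardize(rec)
  rec2 <- std1 |>
    dplyr::mutate(d13C = z13C, d15N = z15N) |>
    dplyr::select(-z13C, -z15N)
  std2 <- standardize(rec2)
  expect_lt(max(abs(std2$z13C - std1$z13C)), 1e-10)
  expect_lt(max(abs(std2$z15N - std1$z15N)), 1e-10)
})

test_that("degenerate tissues are refused by name", {
  rec <- tibble::tibble(
    individual_id = c("a", "b", "c"), species = "sp", season = "breeding",
    campaign = "c1", tissue = c("plasma", "plasma", "feather_x"),
    d13C = c(-14, -15, -16), d15N = c(18, 17, 16)
  )
  expect_error(standardize(rec), class = "nichepart_degenerate_tissue_error")
  expect_error(standardize(rec), "feather_x")
})

test_that("per-season pooling yields one transform per tissue x season", {
  rec <- simulate_isotopes(default_study_design(), seed = 5)
  std <- standardize(rec, per_season = TRUE)
  tab <- standardization_table(std)
  expect_true(all(c("tissue", "season") %in% names(tab)))
  per <- std |>
    dplyr::group_by(tissue, season) |>
    dplyr::summarise(m = mean(z13C), s = sd(z13C), .groups = "drop")
  expect_true(all(abs(per$m) < 1e-10))
  expect_true(all(abs(per$s - 1) < 1e-10))
})
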