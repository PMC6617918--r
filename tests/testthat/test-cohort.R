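test_that("cohort CSV write -> read round trip preserves all fields", {
  plain <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "row.names", "class")]
    x
  }
  cohort <- simulate_cohort(n = 50, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(plain(back), plain(cohort))
  expect_equal(attr(back, "provenance")$source, path)
})

test_that("reader validates schema and reports offending rows and fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::as_tibble(simulate_cohort(n = 5, seed = 1))
  df$surgeon_interface_pct[3] <- 120
  readr::write_csv(df, path)
  expect_error(read_cohort(path), "surgeon_interface_pct.*row.*3",
               class = "gasrisk_validation_error")

  df2 <- dplyr::select(tibble::as_tibble(simulate_cohort(n = 5, seed = 1)),
                       -"destination_altitude_m")
  readr::write_csv(df2, path)
  expect_error(read_cohort(path), "destination_altitude_m",
               class = "gasrisk_schema_error")
  expect_error(read_cohort("no/such/file.csv"), class = "gasrisk_io_error")
})

test_that("missing origin column defaults to the 10 m study site and extras pass through", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::as_tibble(simulate_cohort(n = 4, seed = 2)) |>
    dplyr::select(-"origin_altitude_m") |>
    dplyr::mutate(diagnosis = "RRD")  # unknown extra column
  readr::write_csv(df, path)
  cohort <- read_cohort(path)
  expect_equal(cohort$origin_altitude_m, rep(10, 4))
  expect_equal(cohort$diagnosis, rep("RRD", 4))
})

test_that("risk table emits one row per patient per judge and matches assess_risk", {
  cohort <- simulate_cohort(n = 20, seed = 3)
  risk <- cohort_risk_table(cohort)
  expect_equal(nrow(risk), 40L)
  expect_equal(sort(unique(risk$judge)), c("patient", "surgeon"))
  one <- risk[risk$patient_id == "P001" & risk$judge == "surgeon", ]
  direct <- assess_risk(cohort$surgeon_interface_pct[1],
                        cohort$origin_altitude_m[1],
                        cohort$destination_altitude_m[1])
  expect_equal(one$delta_v, direct$delta_v)
  expect_equal(as.character(one$category), as.character(direct$category))

  # flat routes give identically zero expansion
  flat <- tibble::as_tibble(cohort) |>
    dplyr::mutate(destination_altitude_m = origin_altitude_m)
  risk_flat <- cohort_risk_table(flat)
  expect_true(all(risk_flat$delta_v == 0))
  expect_true(all(risk_flat$category == "none"))

  summ <- cohort_risk_summary(risk)
  med_surgeon <- summ$median[summ$judge == "surgeon" &
                               summ$variable == "delta_v_ml"]
  expect_equal(med_surgeon,
               median(risk$delta_v[risk$judge == "surgeon"]))
})

test_that("cohort agreement bundles the component statistics coherently", {
  cohort <- simulate_cohort(n = 50, seed = 8)
  agr <- cohort_agreement(cohort)
  ba_direct <- bland_altman(tibble::as_tibble(cohort),
                            surgeon_interface_pct, patient_interface_pct)
  expect_equal(agr$bland_altman$bias, ba_direct$bias)
  expect_equal(agr$heights$median[agr$heights$judge == "surgeon"],
               median(cohort$surgeon_interface_pct))
  expect_equal(agr$destination_altitude$max,
               max(cohort$destination_altitude_m))
  expect_equal(sum(agr$travel_mode$count), 50)
  expect_equal(sum(agr$likert$likert_item1$count), 50)
  expect_equal(agr$wilcoxon_heights$method, "approx")

  path <- withr::local_tempfile(fileext = ".json")
  write_agreement_json(agr, path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(out$n, 50)
  expect_equal(out$bland_altman$bias, agr$bland_altman$bias)
})

test_that("interface chart SVG is deterministic with correct shading", {
  expect_identical(render_interface_chart(50), render_interface_chart(50))
  none <- render_interface_chart(0)
  expect_false(grepl("path|#b8d4e8", none))
  full <- render_interface_chart(100)
  expect_true(grepl('<circle[^/]*fill="#b8d4e8"', full))
  half <- render_interface_chart(50)
  expect_true(grepl("<path", half))
  # chord through the centre: y equals cy = 120 for the default size
  expect_true(grepl('y1="120.00"', half))
  expect_error(render_interface_chart(101), class = "gasrisk_domain_error")
  path <- withr::local_tempfile(fileext = ".svg")
  render_interface_chart(75, path = path)
  expect_identical(paste(readLines(path), collapse = "\n"),
                   sub("\n$", "", render_interface_chart(75)))
  expect_s3_class(plot_interface_chart(30), "ggplot")
})
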