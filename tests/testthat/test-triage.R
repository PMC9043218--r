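test_that("extension adds assessment and risk columns without touching the rest", {
  tab <- make_fixture("all_branches")
  model <- fixture_model()
  ext <- extend_reports(tab, model)
  expect_equal(names(ext), c(names(tab), "auto_assess", "risk_s", "risk_t"))
  expect_equal(ext[names(tab)], tab, ignore_attr = TRUE)
  # staircase model: prediction equals the category planted via prov_assess
  expect_equal(ext$auto_assess, tab$prov_assess)
  expect_equal(ext$risk_t, compute_t(ext$auto_assess, tab$ri_assess))

  # idempotent in content
  ext2 <- extend_reports(ext, model)
  expect_equal(ext2$risk_s, ext$risk_s)
  expect_equal(ext2$auto_assess, ext$auto_assess)
})

test_that("risk_t is zero when the reference assessment matches the model", {
  tab <- make_fixture("all_branches")
  model <- fixture_model()
  tab$ri_assess <- predict_category(model, tab)
  ext <- extend_reports(tab, model)
  expect_true(all(ext$risk_t == 0L))
})

test_that("the worked-example fixture reproduces the published signal values", {
  ext <- extend_reports(make_fixture("worked_examples"), fixture_model())
  expect_equal(ext$auto_assess, c(rep(4L, 8), 5L))
  expect_equal(ext$risk_s, c(rep(-12L, 8), -16L))
})

test_that("filters behave as conjunctive brushes", {
  tab <- extend_reports(make_fixture("all_branches"), fixture_model())
  expect_equal(filter_reports(tab, triage_query()), tab, ignore_attr = TRUE)

  contradictory <- triage_query(filter_predicate("suspect", "eq", 1),
                                filter_predicate("suspect", "eq", 0))
  expect_equal(nrow(filter_reports(tab, contradictory)), 0)

  q1 <- triage_query(filter_predicate("risk_s", "lt", 0),
                     filter_predicate("auto_assess", "ge", 4))
  q2 <- triage_query(filter_predicate("auto_assess", "ge", 4),
                     filter_predicate("risk_s", "lt", 0))
  expect_equal(filter_reports(tab, q1), filter_reports(tab, q2))
  once <- filter_reports(tab, q1)
  expect_equal(filter_reports(once, q1), once, ignore_attr = TRUE)

  expect_error(filter_reports(tab, triage_query(
    filter_predicate("no_such_column", "eq", 1))), "unknown column")
  expect_error(filter_predicate("risk_s", "between", c(3, 1)), "lo <= hi")
})

test_that("predicate strings parse to the same filters", {
  tab <- extend_reports(make_fixture("planted_opposite"), fixture_model())
  q_str <- parse_predicates("suspect=1", "risk_s<-8")
  q_obj <- triage_query(filter_predicate("suspect", "eq", 1),
                        filter_predicate("risk_s", "lt", -8))
  expect_equal(filter_reports(tab, q_str), filter_reports(tab, q_obj))
  expect_error(parse_predicates("risk_s <> 3"), "cannot parse")
})

test_that("preset workflows return exactly the planted reports", {
  presets <- triage_presets()
  expect_named(presets, c("opposite_assessments", "unreviewed_certain"))

  tab <- make_fixture("planted_opposite")
  ext <- extend_reports(tab, fixture_model())
  ext$.row <- seq_len(nrow(ext))
  hits <- filter_reports(ext, presets$opposite_assessments)
  expect_equal(nrow(hits), 7)
  expect_equal(sort(hits$.row), sort(attr(tab, "planted")))

  # no unreviewed reports in this fixture
  expect_equal(nrow(filter_reports(ext, presets$unreviewed_certain)), 0)

  # plant unreviewed-certain rows and recover them
  ext2 <- ext
  ext2$prov_assess[c(10, 20)] <- -1L
  ext2$auto_assess[c(10, 20)] <- 5L
  ext2$suspect[c(10, 20)] <- 1L
  hits2 <- filter_reports(ext2, presets$unreviewed_certain)
  expect_equal(nrow(hits2), 2)
})

test_that("filtered results match an exhaustive scan on a large table", {
  tab <- simulate_reports(sim_config(n = 4000, seed = 151))
  ext <- extend_reports(tab, fixture_model())
  q <- triage_query(filter_predicate("suspect", "eq", 1),
                    filter_predicate("risk_s", "lt", -8))
  got <- filter_reports(ext, q)
  keep <- !is.na(ext$risk_s) & ext$suspect == 1 & ext$risk_s < -8
  expect_equal(nrow(got), sum(keep))
  expect_equal(got$risk_s, ext$risk_s[keep])

  q2 <- triage_query(filter_predicate("muni_assess", "in_set", c(2, 4)),
                     filter_predicate("risk_t", "between", c(-1, 1)))
  got2 <- filter_reports(ext, q2)
  keep2 <- ext$muni_assess %in% c(2, 4) & !is.na(ext$risk_t) &
    ext$risk_t >= -1 & ext$risk_t <= 1
  expect_equal(nrow(got2), sum(keep2))
})

test_that("undefined signals are excluded by risk filters", {
  tab <- make_fixture("all_branches")
  tab$ri_assess[1:5] <- -1L
  ext <- extend_reports(tab, fixture_model())
  expect_true(all(is.na(ext$risk_s[1:5])))
  hits <- filter_reports(ext, triage_query(filter_predicate("risk_s", "ge", -99)))
  expect_equal(nrow(hits), 20)
})

test_that("the visualization export carries axes, rows and the color map", {
  ext <- extend_reports(make_fixture("worked_examples"), fixture_model())
  json <- withr::local_tempfile(fileext = ".json")
  html <- withr::local_tempfile(fileext = ".html")
  export_viz(ext, json, html)
  doc <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(doc$axes,
               c("new_ade", "serious_ade", "gender", "r_assess", "ri_assess",
                 "muni_assess", "prov_assess", "suspect", "auto_assess",
                 "risk_s", "risk_t"))
  expect_equal(doc$n, nrow(ext))
  expect_equal(nrow(doc$rows), nrow(ext))
  expect_equal(doc$color_map[["1"]], "#D7191C")  # red end
  expect_equal(doc$color_map[["5"]], "#2C7BB6")  # blue end
  page <- readLines(html, warn = FALSE)
  expect_true(any(grepl("<svg", page)))
  expect_equal(sum(grepl("<polyline", page)), nrow(ext))

  expect_error(export_viz(make_fixture("worked_examples"), json),
               "extended")
})
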