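test_that("the packaged study table loads with 30 fermentors in order", {
  expect_s3_class(table1, "ferm_table")
  expect_equal(nrow(table1), 30)
  expect_equal(table1$ferm_id[c(1, 30)], c("F1", "F30"))
  expect_true(all(c(ferm_condition_cols <- c("nacl_mM", "aa_factor",
                                             "temperature_C", "pH", "aeration"),
                    "od_max", "mu_max") %in% names(table1)))
  expect_false(table1$transcriptome[table1$ferm_id == "F30"])
  expect_true(all(table1$transcriptome[table1$ferm_id != "F30"]))
})

test_that("malformed tables are rejected with informative errors", {
  hdr <- paste(c("ferm_id", "nacl_mM", "aa_factor", "temperature_C", "pH",
                 "aeration", "od_max", "mu_max"), collapse = "\t")
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(hdr, f)
  expect_error(load_fermentation_table(f), class = "fermgenomics_error_validation")

  writeLines(c(hdr, "F1\t0\t1.1\t28\t5.2\tN2\t5.0\t0.5",
               "F1\t0\t1.1\t28\t5.2\tN2\t5.1\t0.6"), f)
  expect_error(load_fermentation_table(f), "F1",
               class = "fermgenomics_error_validation")

  writeLines(c(hdr, "F1\t0\t1.1\t28\t5.2\tN2\tabc\t0.5"), f)
  expect_error(load_fermentation_table(f), "F1",
               class = "fermgenomics_error_parse")

  writeLines(c("ferm_id\tnacl_mM\tod_max\tmu_max", "F1\t0\t5.0\t0.5"), f)
  expect_error(load_fermentation_table(f), class = "fermgenomics_error_format")

  # off-design level rejected under strict, allowed otherwise
  writeLines(c(hdr, "F1\t150\t1.1\t28\t5.2\tN2\t5.0\t0.5"), f)
  expect_error(load_fermentation_table(f), class = "fermgenomics_error_validation")
  expect_equal(load_fermentation_table(f, strict = FALSE)$nacl_mM, 150)
})

test_that("distinct condition counting matches the fractional factorial design", {
  dc <- distinct_conditions(table1)
  expect_equal(dc$n_conditions, 24)
  ctrl <- dc$groups[dc$groups$nacl_mM == 0 & dc$groups$aa_factor == 2.0 &
                      dc$groups$temperature_C == 37 & dc$groups$pH == 5.8 &
                      dc$groups$aeration == "N2", ]
  expect_equal(sort(ctrl$ferm_ids[[1]]), c("F18", "F20", "F30"))

  one <- table1[rep(1, 5), ]
  one$ferm_id <- paste0("X", 1:5)
  expect_equal(distinct_conditions(one)$n_conditions, 1)

  three <- table1[c(1, 2, 1), ]
  three$ferm_id <- c("A", "B", "C")
  dc3 <- distinct_conditions(three)
  expect_equal(dc3$n_conditions, 2)
  expect_equal(sort(dc3$groups$n), c(1L, 2L))
})

test_that("condition groups partition the records on random tables", {
  lv <- list(nacl_mM = c(0, 300), aa_factor = c(1.1, 2), temperature_C = c(28, 37),
             pH = c(5.2, 5.8, 6.4), aeration = c("N2", "O2"))
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:25, 1)
    tab <- tibble::tibble(ferm_id = paste0("R", seq_len(n)))
    for (f in names(lv)) tab[[f]] <- sample(lv[[f]], n, replace = TRUE)
    tab$od_max <- runif(n, 4, 8); tab$mu_max <- runif(n, 0.2, 0.8)
    tab <- fermgenomics:::new_ferm_table(tab)
    dc <- distinct_conditions(tab)
    expect_equal(sum(dc$groups$n), n)
    expect_setequal(unlist(dc$groups$ferm_ids), tab$ferm_id)
  }
})

test_that("phenotype ranges reproduce the recorded growth extremes", {
  mu <- phenotype_range(table1, "mu_max")
  expect_equal(c(mu$min, mu$max), c(0.23, 0.80))
  expect_equal(mu$argmax, "F1")
  expect_equal(mu$argmin, "F16")  # F16 precedes F28 in table order (tie at 0.23)

  od <- phenotype_range(table1, "od_max")
  expect_equal(c(od$min, od$max), c(4.16, 7.74))
  expect_equal(od$argmax, "F17")

  single <- table1[3, ]
  r <- phenotype_range(single, "mu_max")
  expect_equal(r$min, r$max)
  expect_equal(r$argmin, r$argmax)

  expect_error(phenotype_range(table1, "biomass"), class = "fermgenomics_error_key")

  # the extremes bound every value
  for (ph in c("mu_max", "od_max")) {
    r <- phenotype_range(table1, ph)
    expect_true(all(table1[[ph]] >= r$min & table1[[ph]] <= r$max))
  }
})

test_that("design balance reports per-level design-point counts and absences", {
  br <- suppressWarnings(validate_design(table1))
  expect_equal(br$n_design_points, 24)
  nacl <- tidy(br)[tidy(br)$factor == "nacl_mM", ]
  expect_equal(nacl$n_design_points, c(12L, 12L))

  # every NaCl x aeration combination is realized in the design
  mp <- br$missing_pairs
  if (nrow(mp)) {
    expect_false(any(mp$factor1 == "nacl_mM" & mp$factor2 == "aeration"))
  }

  # removing every (pH 6.4, O2) fermentor gets that pair flagged
  cut <- table1[!(table1$pH == 6.4 & table1$aeration == "O2"), ]
  expect_warning(br2 <- validate_design(cut), "pH")
  hit <- br2$missing_pairs[br2$missing_pairs$factor1 == "pH" &
                             br2$missing_pairs$level1 == "6.4" &
                             br2$missing_pairs$factor2 == "aeration" &
                             br2$missing_pairs$level2 == "O2", ]
  expect_equal(nrow(hit), 1)

  f <- withr::local_tempfile(fileext = ".json")
  write_balance_report(br, f)
  expect_equal(jsonlite::read_json(f)$n_design_points, 24)
})

test_that("a study table round-trips through write and load exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fermentation_table(table1, f)
  back <- load_fermentation_table(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(table1))
})
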