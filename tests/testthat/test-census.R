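test_that("census CSV round-trips through read and write", {
  df <- toy_census_df()
  f <- withr::local_tempfile(fileext = ".csv")
  writeCensus(df, f)
  back <- readCensus(f)
  expect_equal(nrow(back), 3L)
  expect_equal(sum(is.na(back$diameter_mm)), 1L)
  expect_equal(back$diameter_mm, df$diameter_mm)
  expect_equal(back$fruits, df$fruits)
  expect_equal(back$year, df$year)
})

test_that("column dialects map nonstandard headers", {
  df <- toy_census_df()
  names(df)[names(df) == "diameter_mm"] <- "ros_diam"
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  back <- readCensus(f, dialect = c(diameter_mm = "ros_diam"))
  expect_equal(back$diameter_mm, c(10, NA, 12.5))
  expect_error(readCensus(f), "not found")
  expect_error(readCensus(f, dialect = c(nope = "x")), "unknown standard columns")
})

test_that("validation rejects duplicate keys, negatives and year gaps", {
  df <- toy_census_df()
  expect_silent(validateCensus(df))
  expect_error(validateCensus(rbind(df, df[1, ])), "duplicated")
  bad <- df; bad$diameter_mm[1] <- -1
  expect_error(validateCensus(bad), "negative diameter")
  bad <- df; bad$fruits[1] <- -2
  expect_error(validateCensus(bad), "negative fruits")
  bad <- df; bad$year[2] <- 1993L
  expect_error(validateCensus(bad), "not consecutive")
})

test_that("reincarnation correction matches the worked example and is local", {
  expect_equal(correctReincarnation("00011101"), "00011111")
  expect_equal(correctReincarnation("1111"), "1111")
  expect_equal(correctReincarnation("0101001"), "0111111")
  # leading and trailing zeros untouched
  expect_equal(correctReincarnation("0010100"), "0011100")
  expect_equal(correctReincarnation("0000"), "0000")
  expect_error(correctReincarnation("0102"), "non-binary")
})

test_that("reincarnation correction is idempotent and preserves endpoints", {
  set.seed(421)
  for (i in 1:200) {
    s <- paste(sample(c("0", "1"), sample(1:12, 1), replace = TRUE),
               collapse = "")
    once <- correctReincarnation(s)
    expect_identical(correctReincarnation(once), once)
    raw <- as.integer(strsplit(s, "")[[1]])
    cor <- as.integer(strsplit(once, "")[[1]])
    if (any(raw == 1L)) {
      expect_identical(min(which(raw == 1L)), min(which(cor == 1L)))
      expect_identical(max(which(raw == 1L)), max(which(cor == 1L)))
    } else {
      expect_identical(once, s)
    }
    # dormancy count equals Hamming distance between raw and corrected
    flags <- scoreDormancy(s, once)
    expect_equal(sum(strsplit(flags, "")[[1]] == "1"), sum(cor != raw))
  }
})

test_that("dormancy is flagged exactly where correction changed the record", {
  expect_equal(scoreDormancy("00011101", "00011111"), "00000010")
  expect_equal(scoreDormancy("1111", "1111"), "0000")
  expect_equal(scoreDormancy("0100101", "0111111"), "0011010")
  expect_error(scoreDormancy("0101", "01111"), "length")
  expect_error(scoreDormancy("0101", "1111"), "not the reincarnation correction")
})

test_that("state classification is a partition of alive plant-years", {
  expect_equal(classifyState(1, 0, 0), "BOLTER")
  expect_equal(classifyState(1, NA, 0), "BOLTER")
  expect_equal(classifyState(1, 12.3, 0), "NORMAL")
  expect_equal(classifyState(1, NA, 1), "DORMANT")
  expect_equal(classifyState(0, NA, 0), "DEAD")
  expect_error(classifyState(0, NA, 1), "requires alive")
  # every alive combination lands in exactly one live state
  alive <- expand.grid(d = c(NA, 0, 5), f = c(0, 1))
  alive <- alive[!(alive$f == 1 & !is.na(alive$d) & alive$d > 0), ]
  st <- classifyState(1, alive$d, alive$f)
  expect_true(all(st %in% c("NORMAL", "BOLTER", "DORMANT")))
})

test_that("cohort summary counts reincarnates and bolters from histories", {
  # engineered histories: 10 plants over 5 years, 3 with dormancy gaps
  years <- 1990:1994
  mk <- function(id, surv, diam) {
    data.frame(population = "A", transect = "T1", quadrat = "Q1",
               plant_id = id, year = years, diameter_mm = diam,
               survival = surv, fruits = NA_real_, stringsAsFactors = FALSE)
  }
  recs <- list()
  for (i in 1:3)  # reincarnates: alive, gap, alive
    recs[[i]] <- mk(paste0("d", i), c(1, 1, 0, 1, 0), c(5, 6, NA, 7, NA))
  for (i in 4:5)  # bolters in year 2
    recs[[i]] <- mk(paste0("b", i), c(1, 1, 1, 0, 0), c(5, NA, 6, NA, NA))
  for (i in 6:10) # plain survivors
    recs[[i]] <- mk(paste0("n", i), c(1, 1, 1, 1, 1), c(5, 6, 7, 8, 9))
  cs <- summarizeCohort(cleanCensus(do.call(rbind, recs)))
  expect_equal(cs$n_plants, 10L)
  expect_equal(cs$n_reincarnates, 3L)
  expect_equal(cs$n_bolters, 2L)
  expect_equal(unname(cs$alive_by_year),
               c(10L, 10L, 10L, 8L, 5L))
  # single always-alive plant
  one <- summarizeCohort(cleanCensus(mk("solo", rep(1, 5), 5:9)))
  expect_equal(c(one$n_plants, one$n_reincarnates, one$n_bolters),
               c(1L, 0L, 0L))
  expect_equal(summarizeCohort(cleanCensus(mk("x", rep(1,5), 5:9))[0, ])$n_plants, 0L)
})

test_that("bolter canonicalization treats diameter 0 as missing size", {
  df <- toy_census_df()
  df$diameter_mm[3] <- 0
  cl <- cleanCensus(df)
  expect_true(is.na(cl$diameter_mm[cl$plant_id == "p2"]))
  expect_equal(cl$state[cl$plant_id == "p2"], "BOLTER")
})

test_that("density conversion divides counts by quadrat area", {
  expect_equal(densityFromCounts(300, 30), 10)
  expect_equal(densityFromCounts(0, 45), 0)
  expect_equal(mean(densityFromCounts(seq(10, 80, by = 10), 10)), 4.5)
  expect_error(densityFromCounts(10, 0), "n_quadrats")
})
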