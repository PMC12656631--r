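test_that("clock strings and decimal hours parse to the same scale", {
  expect_equal(parse_race_time(c("01:30:00", "00:45:00", "2.25")),
               c(1.5, 0.75, 2.25))
  expect_equal(parse_race_time("10:30"), 10.5)
  expect_true(is.na(parse_race_time(NA_character_)))
  expect_error(parse_race_time("soon"), "unparseable")
  expect_equal(format_race_time(1.5), "01:30:00")
  # round trip at 1-second resolution
  h <- c(0.33, 9.987, 18.4)
  expect_equal(parse_race_time(format_race_time(h)), h, tolerance = 1 / 3600)
})

test_that("section times are successive differences with missing propagation", {
  expect_equal(section_times(c(2.0, 3.5, 5.0)), c(2.0, 1.5, 1.5))
  expect_equal(section_times(c(2.0, NA, 5.0)), c(2.0, NA, NA))
  expect_equal(section_times(c(NA, 3, 5)), c(NA, NA, 2))
  expect_error(section_times(c(2, 1.9, 5), runner_id = "r07"), "r07")
  # telescoping: present section times sum back to the last passage time
  set.seed(4)
  for (i in 1:25) {
    cp <- cumsum(runif(5, 0.2, 2))
    drop <- sample(c(TRUE, FALSE), 1)
    if (drop) cp[sample(2:4, 1)] <- NA
    t_n <- section_times(cp)
    last <- max(which(!is.na(cp)))
    if (!anyNA(t_n[seq_len(last)])) {
      expect_equal(sum(t_n[seq_len(last)]), cp[last])
    }
  }
})

test_that("weighted time divides by the difficulty share and guards its domain", {
  expect_equal(weighted_time(2.0, 0.27), 2 / 0.27)
  expect_equal(weighted_time(3.7, 1.0), 3.7) # whole-course section
  expect_error(weighted_time(-1, 0.5), "positive")
  expect_error(weighted_time(1, 0), "\\(0, 1\\]")
  expect_error(weighted_time(1, 1.2), "\\(0, 1\\]")
})

test_that("pacing variability is the relative change between same-slope sections", {
  expect_equal(weighted_time_variability(4, 4), 0)
  expect_equal(weighted_time_variability(4, 5), 0.25)
  expect_equal(weighted_time_variability(4, 2), -0.5)
  expect_error(weighted_time_variability(4, 5, "positive", "negative"),
               "same slope")
})

test_that("checkpoint percentile rank is rank/n with mean-rank ties", {
  times <- c(1.0, 1.2, 1.1)
  expect_equal(checkpoint_percentile_rank(times), c(1, 3, 2) / 3)
  n <- 100
  t100 <- sort(runif(n, 1, 5))
  cpr <- checkpoint_percentile_rank(t100)
  expect_equal(cpr[1], 0.01)   # fastest of 100
  expect_equal(cpr[n], 1)      # slowest
  # two tied runners at ranks 3-4 of 10 share the mean rank 3.5 -> 0.35
  t10 <- c(1.0, 1.1, 1.2, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8)
  expect_equal(checkpoint_percentile_rank(t10)[3:4], c(0.35, 0.35))
  # permutation statistic: depends only on ordering, NA preserved
  perm <- sample(n)
  expect_equal(checkpoint_percentile_rank(t100[perm]), cpr[perm])
  expect_equal(checkpoint_percentile_rank(t100^3), cpr)
  with_na <- c(1.0, NA, 1.2)
  expect_equal(checkpoint_percentile_rank(with_na), c(0.5, NA, 1))
})

test_that("quartile assignment is inclusive at the ceiling(n/4) boundary", {
  cpr947 <- checkpoint_percentile_rank(seq_len(947))
  q <- assign_quartiles(cpr947)
  expect_equal(sum(q == "Q1"), 237) # 237/947 = 0.2503 is still Q1
  expect_equal(sum(q == "Q2_4"), 710)
  q4 <- assign_quartiles(checkpoint_percentile_rank(c(1, 2, 3, 4)))
  expect_equal(as.character(q4), c("Q1", "Q2_4", "Q2_4", "Q2_4"))
  all_tied <- assign_quartiles(checkpoint_percentile_rank(rep(1, 5)))
  expect_equal(length(unique(all_tied)), 1)
  expect_error(assign_quartiles(NA_real_), "non-missing")
})

test_that("feature table joins times, weighted features, ranks and quartiles", {
  courses <- list(`4K` = course_4k(), `8K` = course_8k())
  sp <- toy_splits(n = 8)
  ft <- build_feature_table(sp, courses, quiet = TRUE)
  expect_equal(nrow(ft), 8)
  expect_true(all(c(paste0("T_", 1:5), paste0("WT_", 1:5),
                    "WTV_13", "WTV_24", "WTV_35",
                    paste0("CPR_", 1:3), "quartile", "TT") %in% names(ft)))
  expect_true(!anyNA(ft[setdiff(names(ft), c("sex"))]))
  ir <- course_irdc(course_4k())
  expect_equal(ft$WT_3, ft$T_3 / ir[3])
  expect_equal(ft$WTV_13, ft$WT_3 / ft$WT_1 - 1)
  expect_equal(ft$TT, sp$finish)
  expect_error(build_feature_table(transform(sp, modality = "9K"), courses),
               "9K")
})

test_that("scaling all times scales WT and TT but leaves WTV, CPR, quartile fixed", {
  courses <- list(`4K` = course_4k())
  sp <- toy_splits(n = 10)
  k <- 3.7
  sp2 <- sp
  for (cl in c(paste0("cp_", 1:5), "finish")) sp2[[cl]] <- sp[[cl]] * k
  f1 <- build_feature_table(sp, courses, quiet = TRUE)
  f2 <- build_feature_table(sp2, courses, quiet = TRUE)
  for (n in 1:5) {
    expect_equal(f2[[paste0("WT_", n)]], k * f1[[paste0("WT_", n)]])
  }
  expect_equal(f2$TT, k * f1$TT)
  for (cl in c("WTV_13", "WTV_24", "WTV_35", "CPR_1", "CPR_2", "CPR_3")) {
    expect_equal(f2[[cl]], f1[[cl]], tolerance = 1e-12)
  }
  expect_equal(f2$quartile, f1$quartile)
})

test_that("doubling one runner's times doubles their WT but not their WTV", {
  courses <- list(`4K` = course_4k())
  sp <- toy_splits(n = 6)
  sp2 <- sp
  for (cl in c(paste0("cp_", 1:5), "finish")) sp2[[cl]][6] <- sp[[cl]][6] * 2
  f1 <- build_feature_table(sp, courses, quiet = TRUE)
  f2 <- build_feature_table(sp2, courses, quiet = TRUE)
  expect_equal(f2$WT_1[6], 2 * f1$WT_1[6])
  expect_equal(f2$WTV_13[6], f1$WTV_13[6])
  # runner 6 was already slowest, so pooled ranks are unchanged
  expect_equal(f2$CPR_1, f1$CPR_1)
})

test_that("missing checkpoints void only the features they feed", {
  courses <- list(`4K` = course_4k())
  sp <- toy_splits(n = 6)
  sp$cp_2[3] <- NA
  expect_message(ft <- build_feature_table(sp, courses), "missing features")
  expect_true(is.na(ft$T_2[3]) && is.na(ft$T_3[3]))
  expect_true(is.na(ft$WT_2[3]) && is.na(ft$WTV_13[3]) && is.na(ft$WTV_24[3]))
  expect_false(is.na(ft$WT_1[3]))
  expect_false(is.na(ft$WT_4[3]))
  expect_true(is.na(ft$CPR_2[3]) && !is.na(ft$CPR_1[3]))
  # other runners untouched
  expect_true(!anyNA(ft[-3, setdiff(names(ft), "sex")]))
})

test_that("split CSV reader accepts clock times and bare cp column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "runner_id,modality,sex,cp1,cp2,cp3,cp4,cp5,finish",
    "a1,4K,male,01:30:00,02:45:00,04:00:00,05:00:00,06:00:00,08:30:00",
    "a2,4K,female,1.6,2.9,4.2,5.2,6.3,8.9"
  ), path)
  sp <- read_splits(path)
  expect_equal(names(sp)[4:9], c(paste0("cp_", 1:5), "finish"))
  expect_equal(sp$cp_1, c(1.5, 1.6))
  expect_equal(sp$finish, c(8.5, 8.9))
})
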