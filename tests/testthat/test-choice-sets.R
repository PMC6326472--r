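test_that("choice-set assembly has the stated counts and window bounds", {
  land <- small_landscape(3)
  use <- as.data.frame(riversel:::sample_inchannel(land, 17000, 23000, 20,
                                                   seed = 31))
  ch <- build_choice_sets(use, land, n_avail = 5, seed = 32)
  expect_equal(nrow(ch), 20 * 6)           # 5 available + the use point
  expect_equal(sum(ch$used == 0), 100)
  expect_true(all(tapply(ch$used, ch$set_id, sum) == 1))
  off <- abs(ch$x_m - use$s[ch$set_id])
  expect_lte(max(off), 16000)
  # the use location is a member of its own set, with its own coordinates
  expect_equal(ch$x_m[ch$used == 1], use$s)
  # windows near the landscape end are clipped with a message
  edge <- data.frame(s = c(2000, 20000), t = c(0, 0))
  expect_message(build_choice_sets(edge, land, n_avail = 3, seed = 33),
                 "clipped")
})

test_that("larger designs give the published row counts", {
  land <- small_landscape(4)
  use <- as.data.frame(riversel:::sample_inchannel(land, 0, land$extent_m,
                                                   235, seed = 34))
  ch <- suppressMessages(build_choice_sets(use, land, n_avail = 20,
                                           seed = 35))
  expect_equal(sum(ch$used == 0), 4700)
  expect_equal(length(unique(ch$set_id)), 235)
})

test_that("collinearity screening rejects and admits as constructed", {
  df <- random_choice_data(100, 20, seed = 41)
  # perfectly collinear pair: TCW = 2 * UOCW
  df$tcw_m <- 2 * df$uocw_m
  models <- list(candidate_model("UOCW+TCW", c("UOCW", "TCW")),
                 candidate_model("UOCW+NF", c("UOCW", "NF")),
                 candidate_model("UOCW", "UOCW"))
  scr <- screen_collinearity(df, models)
  expect_equal(vapply(scr$admissible, function(m) m$name, ""),
               c("UOCW+NF", "UOCW"))
  expect_match(scr$rejected$reason[1], "UOCW~TCW")
  expect_equal(scr$cor_matrix["UOCW", "TCW"], 1)

  # independent covariates: every model shape admissible
  df2 <- random_choice_data(100, 20, seed = 42)
  scr2 <- screen_collinearity(df2, riverine_model_list())
  expect_length(scr2$admissible, length(riverine_model_list()))

  # constructed r ~ 0.8 pair is rejected
  df3 <- random_choice_data(100, 20, seed = 43)
  df3$ufcw_m <- 0.8 * scale(df3$uocw_m)[, 1] +
    sqrt(1 - 0.8^2) * rnorm(nrow(df3))
  r <- cor(df3$uocw_m, df3$ufcw_m)
  expect_gt(abs(r), 0.6)
  scr3 <- screen_collinearity(
    df3, list(candidate_model("UOCW+UFCW", c("UOCW", "UFCW"))))
  expect_length(scr3$admissible, 0)

  # constant covariate disqualifies models containing it, with a reason
  df4 <- random_choice_data(50, 10, seed = 44)
  df4$ud_cms_per_m <- 0.2
  scr4 <- screen_collinearity(df4, list(candidate_model("UD", "UD")))
  expect_length(scr4$admissible, 0)
  expect_match(scr4$rejected$reason, "constant")
})

test_that("train/test split rounds to nearest and partitions whole sets", {
  expect_equal(lengths(split_train_test(1:235, seed = 1))[c("train",
                                                            "test")],
               c(train = 157, test = 78))
  expect_equal(lengths(split_train_test(1:3, seed = 1)),
               c(train = 2, test = 1))
  expect_equal(lengths(split_train_test(1:147, seed = 1)),
               c(train = 98, test = 49))
  df <- random_choice_data(30, 5, seed = 45)
  sp <- split_train_test(df, seed = 9)
  expect_equal(sort(unique(c(sp$train$set_id, sp$test$set_id))), 1:30)
  expect_length(intersect(unique(sp$train$set_id),
                          unique(sp$test$set_id)), 0)
  # split is by whole set: every set's rows stay together
  expect_true(all(table(sp$train$set_id) == 5))
  expect_error(split_train_test(1:2), "at least 3")
})
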