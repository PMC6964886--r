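test_that("stomatal index follows its closed form and stays in [0, 100]", {
  expect_identical(stomatalIndex(10, 40), 20)
  expect_identical(stomatalIndex(0, 25), 0)
  expect_identical(stomatalIndex(7, 0), 100)
  # duplicating the counting field leaves the index unchanged
  expect_identical(stomatalIndex(2 * 10, 2 * 40), stomatalIndex(10, 40))
  expect_error(stomatalIndex(0, 0), class = "peelstackInputError")
  expect_error(stomatalIndex(-1, 5), class = "peelstackInputError")
})

test_that("stomatal density is count per unit area", {
  expect_identical(stomatalDensity(24, 0.16), 150)  # 400 um x 400 um ROI
  expect_identical(stomatalDensity(0, 0.16), 0)
  expect_identical(stomatalDensity(24, 0.32), stomatalDensity(24, 0.16) / 2)
  expect_error(stomatalDensity(24, 0), class = "peelstackInputError")
})

ctFixture <- function() {
  data.frame(
    sample_id = c("s1", "s1", "c1", "c1"),
    condition = c("treated", "treated", "control", "control"),
    gene = c("TARGET", "UBC21", "TARGET", "UBC21"),
    ct = c(25, 20, 24, 20),
    reference_gene = "UBC21",
    stringsAsFactors = FALSE
  )
}

test_that("ddCt: a one-cycle shift halves expression; calibrator is exactly 1", {
  out <- relativeExpression(ctFixture(), calibrator = "control")
  expect_identical(out$relative_expression[out$condition == "control"], 1)
  expect_identical(out$relative_expression[out$condition == "treated"], 0.5)
  expect_identical(out$delta_delta_ct[out$condition == "treated"], 1)
})

test_that("ddCt is invariant under a global Ct shift and identical conditions give 1", {
  ct <- ctFixture()
  base <- relativeExpression(ct, "control")
  ct2 <- ct
  ct2$ct <- ct2$ct + 3.7
  expect_equal(relativeExpression(ct2, "control")$relative_expression,
               base$relative_expression)
  same <- ct
  same$ct <- rep(c(25, 20), 2)
  expect_true(all(relativeExpression(same, "control")$relative_expression == 1))
})

test_that("ddCt fold-changes between conditions are efficiency-shift equivariant", {
  # adding log2(k) to the target Ct of every condition rescales all
  # expressions by 1/k relative to nothing: between-condition fold ratios
  # are unchanged
  ct <- simulateCt(c(control = 1, a = 2, b = 8), replicateSigma = 0, seed = 2)
  out <- relativeExpression(ct, "control")
  shifted <- ct
  tgt <- shifted$gene != shifted$reference_gene
  shifted$ct[tgt] <- shifted$ct[tgt] + log2(5)
  out2 <- relativeExpression(shifted, "control")
  ratio <- function(o) o$relative_expression[o$condition == "b"] /
    o$relative_expression[o$condition == "a"]
  expect_equal(ratio(out2), ratio(out))
  expect_equal(out2$relative_expression[out2$condition == "control"], 1)
})

test_that("ddCt replicate aggregation averages dCt, and errors name the culprit", {
  ct <- rbind(ctFixture(), data.frame(
    sample_id = c("s2", "s2"), condition = "treated",
    gene = c("TARGET", "UBC21"), ct = c(27, 20), reference_gene = "UBC21"))
  out <- relativeExpression(ct, "control")
  # dCt treated = mean(5, 7) = 6; ddCt = 2 -> 0.25
  expect_identical(out$relative_expression[out$condition == "treated"], 0.25)
  expect_identical(out$n[out$condition == "treated"], 2L)

  broken <- ctFixture()[-2, ]              # s1 lost its reference row
  err <- tryCatch(relativeExpression(broken, "control"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "s1")
  expect_match(err, "UBC21")
  expect_error(relativeExpression(ctFixture(), "mars"),
               class = "peelstackInputError")
})

test_that("luciferase ratio normalizes firefly by Renilla and is gain-invariant", {
  expect_identical(luciferaseRatio(1000, 500), 2)
  expect_identical(luciferaseRatio(0, 500), 0)
  expect_identical(luciferaseRatio(3 * 1000, 3 * 500),
                   luciferaseRatio(1000, 500))
  expect_error(luciferaseRatio(1000, 0), "transfection-control")
})

test_that("CSV readers validate their schemas", {
  d <- withr::local_tempdir()
  cf <- file.path(d, "counts.csv")
  write.csv(data.frame(sample_id = "a", stomata = 10, epidermal_cells = 40,
                       roi_area_mm2 = 0.16), cf, row.names = FALSE)
  df <- readCountTable(cf)
  expect_identical(stomatalIndex(df$stomata, df$epidermal_cells), 20)
  bad <- file.path(d, "bad.csv")
  write.csv(data.frame(sample_id = "a", stomata = 10), bad, row.names = FALSE)
  expect_error(readCountTable(bad), class = "peelstackInputError")
  expect_error(readCtTable(file.path(d, "missing.csv")),
               class = "peelstackIOError")
  lf <- file.path(d, "luc.csv")
  write.csv(data.frame(sample_id = "a", firefly = 10, renilla = 0), lf,
            row.names = FALSE)
  expect_error(readLucTable(lf), class = "peelstackInputError")
})

test_that("compareConditions delegates to the standard routines", {
  set.seed(7)
  vals <- c(rnorm(10, 5), rnorm(10, 6))
  grp <- rep(c("a", "b"), each = 10)
  w <- compareConditions(vals, grp, method = "welch")
  expect_s3_class(w, "htest")
  a <- compareConditions(c(vals, rnorm(10, 7)),
                         rep(c("a", "b", "c"), each = 10), method = "anova")
  expect_s3_class(a$aov, "aov")
  expect_s3_class(a$tukey, "TukeyHSD")
})
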