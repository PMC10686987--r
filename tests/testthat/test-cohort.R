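# propensity fitting, matching, splitting, summaries

make_records <- function(ages_f, ages_m) {
  data.frame(id = c(sprintf("F%02d", seq_along(ages_f)),
                    sprintf("M%02d", seq_along(ages_m))),
             sex = rep(c("female", "male"), c(length(ages_f), length(ages_m))),
             age = c(ages_f, ages_m), stringsAsFactors = FALSE)
}

test_that("propensity scores are equal when age carries no information", {
  r <- fit_propensity(make_records(rep(50, 4), rep(50, 6)))
  expect_true(all(abs(r$propensity - 0.6) < 1e-8))  # marginal P(male)
})

test_that("perfectly separated ages are rejected", {
  expect_error(fit_propensity(make_records(c(30, 35, 40), c(60, 65, 70))),
               "separated")
  expect_error(fit_propensity(make_records(numeric(0), c(60, 65))), "")
})

test_that("the logistic fit matches a direct likelihood-maximization oracle", {
  rec <- make_records(c(40, 55, 62, 70), c(48, 60, 71, 80))
  r <- fit_propensity(rec)
  y <- as.integer(rec$sex == "male")
  X <- cbind(1, rec$age)
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(y * eta - log(1 + exp(eta)))
  }
  gr <- function(beta) {
    p <- 1 / (1 + exp(-as.numeric(X %*% beta)))
    -as.numeric(crossprod(X, y - p))
  }
  opt <- optim(c(0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  oracle <- 1 / (1 + exp(-as.numeric(X %*% opt$par)))
  expect_equal(r$propensity, oracle, tolerance = 1e-6)
})

test_that("greedy 1:1 matching equals an exhaustive oracle on a small cohort", {
  rec <- make_records(c(40, 52, 60, 67, 75), c(41, 45, 55, 59, 66, 70, 78, 85))
  rec <- fit_propensity(rec)
  seed <- 7
  m <- match_pairs(rec, caliper_sd = 0.2, seed = seed)
  # oracle: same greedy rule, written independently with explicit loops
  caliper <- 0.2 * sd(rec$propensity)
  fem <- rec[rec$sex == "female", ]; mal <- rec[rec$sex == "male", ]
  ord <- withr::with_seed(seed, sample.int(nrow(fem)))
  used <- rep(FALSE, nrow(mal)); oracle <- NULL
  for (i in ord) {
    best_j <- 0; best_d <- Inf
    for (j in seq_len(nrow(mal))) {
      if (used[j]) next
      d <- abs(mal$propensity[j] - fem$propensity[i])
      if (d < best_d - 1e-15 ||
          (abs(d - best_d) <= 1e-15 && best_j > 0 && mal$id[j] < mal$id[best_j])) {
        best_d <- d; best_j <- j
      }
    }
    if (best_j > 0 && best_d <= caliper) {
      used[best_j] <- TRUE
      oracle <- rbind(oracle, data.frame(female_id = fem$id[i],
                                         male_id = mal$id[best_j]))
    }
  }
  expect_equal(m$pairs[order(m$pairs$female_id), ],
               oracle[order(oracle$female_id), ], ignore_attr = TRUE)
  # matched cohort invariants
  expect_equal(sum(m$records$sex == "female"), sum(m$records$sex == "male"))
  pf <- m$records$propensity[match(m$pairs$female_id, m$records$id)]
  pm <- m$records$propensity[match(m$pairs$male_id, m$records$id)]
  expect_true(all(abs(pf - pm) <= m$caliper_used + 1e-12))
})

test_that("identical propensities match every minority member; a gap matches none", {
  rec <- make_records(rep(60, 4), rep(60, 7))
  rec$propensity <- rep(0.5, nrow(rec))
  m <- match_pairs(rec, seed = 1)
  expect_equal(nrow(m$pairs), 4)
  rec2 <- make_records(rep(60, 3), rep(60, 3))
  rec2$propensity <- c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  expect_warning(m2 <- match_pairs(rec2, seed = 1), "no pairs")
  expect_equal(nrow(m2$pairs), 0)
})

test_that("matching is deterministic under a fixed seed", {
  rec <- fit_propensity(make_records(rnorm(20, 60, 10) + 18, rnorm(25, 70, 10) + 18))
  m1 <- match_pairs(rec, seed = 42)
  m2 <- match_pairs(rec, seed = 42)
  expect_identical(m1$pairs, m2$pairs)
})

test_that("split sizes follow the 7:1:2 rounding rule", {
  expect_equal(unname(split_sizes(1234)), c(864L, 124L, 246L))
  expect_equal(unname(split_sizes(10)), c(7L, 1L, 2L))
  expect_equal(unname(split_sizes(20)), c(14L, 2L, 4L))
  rec <- make_records(rnorm(30, 60, 5) + 20, rnorm(30, 60, 5) + 20)
  sp <- split_cohort(rec, seed = 3)
  expect_equal(sum(sp$split == "train"), 42)
  expect_equal(sort(unique(sp$split)), c("test", "train", "val"))
  expect_equal(nrow(sp), 60)
  expect_false(any(duplicated(sp$id)))
  expect_warning(split_cohort(rec[1:6, ], seed = 1), "degenerate")
})

test_that("cohort summaries use linear-interpolation quantiles", {
  rec <- make_records(1:5 + 17, c(30, 40))
  s <- summarize_cohort(rec)
  f <- s[s$sex == "female", ]
  expect_equal(f$median_age, 20)
  expect_equal(f$q1_age, 19)
  expect_equal(f$q3_age, 21)
  one <- summarize_cohort(make_records(33, 50))
  expect_equal(one$median_age[one$sex == "female"], 33)
  expect_equal(one$q1_age[one$sex == "female"], 33)
  # larger sample against the sort-based oracle
  ages <- withr::with_seed(1, round(runif(100, 20, 90), 1))
  s2 <- summarize_cohort(make_records(ages, c(50, 60)))
  expect_equal(s2$median_age[s2$sex == "female"],
               unname(quantile(ages, 0.5, type = 7)))
})

test_that("matching reduces the age imbalance on shifted cohorts", {
  worse <- 0
  for (s in 1:20) {
    co <- generate_cohort(60, 60, params = small_params(),
                          age_model = list(female = list(mean = 68, sd = 10),
                                           male = list(mean = 78, sd = 10)),
                          seed = s, volumes = FALSE)
    rec <- fit_propensity(co$metadata)
    before <- abs(age_smd(rec))
    m <- match_pairs(rec, caliper_sd = 0.2, seed = s)
    after <- abs(age_smd(m$records))
    if (after > before) worse <- worse + 1
    expect_equal(sum(m$records$sex == "female"), sum(m$records$sex == "male"))
  }
  expect_equal(worse, 0)
})
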