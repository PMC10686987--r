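#' Fit propensity scores for age matching
#'
#' Models the probability of the male label given age with a logistic
#' regression fitted by maximum likelihood (the only covariate the study
#' design adjusts for is age). The fitted probability is the propensity score
#' used for 1:1 matching; since matching is symmetric at a 1:1 ratio, the
#' choice of male as the "treatment" label is arbitrary but fixed.
#'
#' @param records data.frame with columns `id`, `sex` (`"female"`/`"male"`),
#'   `age` (years, >= 18).
#' @return `records` with a `propensity` column appended.
#' @export
fit_propensity <- function(records) {
  check_records(records)
  if (length(unique(records$sex)) < 2L) {
    stop("both sexes must be present to fit propensity scores", call. = FALSE)
  }
  af <- records$age[records$sex == "female"]
  am <- records$age[records$sex == "male"]
  if (max(af) < min(am) || max(am) < min(af)) {
    stop("ages are perfectly separated between sexes; logistic MLE does not exist",
         call. = FALSE)
  }
  y <- as.integer(records$sex == "male")
  fit <- suppressWarnings(stats::glm(y ~ age, data = records,
                                     family = stats::binomial()))
  if (!fit$converged) stop("propensity model did not converge", call. = FALSE)
  p <- stats::fitted(fit)
  if (any(p <= 0 | p >= 1)) {
    stop("propensity model is degenerate (fitted probabilities at 0/1)",
         call. = FALSE)
  }
  records$propensity <- as.numeric(p)
  records
}

check_records <- function(records) {
  need <- c("id", "sex", "age")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("'records' must be a data.frame with columns id, sex, age", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("'records' is empty", call. = FALSE)
  if (!all(records$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (any(!is.finite(records$age))) stop("ages must be finite", call. = FALSE)
  if (any(records$age < 18)) {
    stop("ages below 18 are excluded from the study population", call. = FALSE)
  }
  invisible(records)
}

#' 1:1 greedy propensity-score matching with a caliper
#'
#' Pairs each member of the minority sex with the nearest unmatched member of
#' the majority sex on the propensity-score scale, visiting minority members
#' in a seeded random order. Pairs whose propensity difference exceeds the
#' caliper — `caliper_sd` standard deviations of the pooled propensity scores
#' — are not formed, and their minority member is dropped. Ties in distance
#' are broken by the smaller candidate id, so matching is deterministic under
#' a fixed seed.
#'
#' @param records data.frame with a fitted `propensity` column
#'   (see [fit_propensity]).
#' @param caliper_sd caliper width in SDs of the propensity score
#'   (default 0.2).
#' @param seed seed for the greedy visiting order.
#' @return A list of class `matched_cohort`: `pairs` (data.frame
#'   `female_id`, `male_id`), `records` (retained records), `caliper_used`
#'   (absolute propensity-scale width).
#' @export
match_pairs <- function(records, caliper_sd = 0.2, seed = 1L) {
  check_records(records)
  if (is.null(records$propensity)) {
    stop("records have no 'propensity' column; call fit_propensity() first",
         call. = FALSE)
  }
  nf <- sum(records$sex == "female"); nm <- sum(records$sex == "male")
  if (min(nf, nm) == 0L) stop("one sex group is empty", call. = FALSE)
  minority <- if (nf <= nm) "female" else "male"
  majority <- setdiff(c("female", "male"), minority)
  caliper <- caliper_sd * stats::sd(records$propensity)
  mino <- records[records$sex == minority, , drop = FALSE]
  majo <- records[records$sex == majority, , drop = FALSE]
  order_idx <- with_seed(seed, sample.int(nrow(mino)))
  avail <- rep(TRUE, nrow(majo))
  pair_min <- character(0); pair_maj <- character(0)
  for (i in order_idx) {
    d <- abs(majo$propensity - mino$propensity[i])
    d[!avail] <- Inf
    if (!any(is.finite(d))) next
    best <- min(d)
    if (best > caliper) next
    cand <- which(d == best)
    j <- cand[order(majo$id[cand])][1]          # tie-break: smaller id
    avail[j] <- FALSE
    pair_min <- c(pair_min, mino$id[i])
    pair_maj <- c(pair_maj, majo$id[j])
  }
  if (length(pair_min) == 0L) {
    warning("no pairs within the caliper; matched cohort is empty")
  }
  pairs <- if (minority == "female") {
    data.frame(female_id = pair_min, male_id = pair_maj, stringsAsFactors = FALSE)
  } else {
    data.frame(female_id = pair_maj, male_id = pair_min, stringsAsFactors = FALSE)
  }
  keep <- records$id %in% c(pairs$female_id, pairs$male_id)
  structure(list(pairs = pairs,
                 records = records[keep, , drop = FALSE],
                 caliper_used = caliper),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs (caliper %.4g on the propensity scale)\n",
              nrow(x$pairs), x$caliper_used))
  invisible(x)
}

#' Split a matched cohort into train/validation/test
#'
#' Sizes follow the 7:1:2 convention with a fixed rounding rule:
#' `train = floor(0.7 n + 0.5)` (round half up), `test = floor(0.2 n)`,
#' `val = n - train - test`. For n = 1234 this gives (864, 124, 246).
#' Assignment of records to splits is random under the seed.
#'
#' @param matched a `matched_cohort` (or a data.frame of records).
#' @param ratio numeric length-3 train/val/test proportions summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @param seed assignment seed.
#' @return The records data.frame with a `split` column
#'   (`"train"`/`"val"`/`"test"`).
#' @export
split_cohort <- function(matched, ratio = c(0.7, 0.1, 0.2), seed = 1L) {
  records <- if (inherits(matched, "matched_cohort")) matched$records else matched
  n <- nrow(records)
  if (n == 0L) stop("matched cohort is empty", call. = FALSE)
  if (n < 10L) warning("fewer than 10 records; split is degenerate")
  sizes <- split_sizes(n, ratio)
  lab <- rep(c("train", "val", "test"), sizes)
  records$split <- with_seed(seed, sample(lab))
  records
}

#' Train/validation/test sizes for a cohort of n records
#'
#' @param n cohort size.
#' @param ratio proportions as in [split_cohort].
#' @return Named integer vector `(train, val, test)` summing to `n`.
#' @export
split_sizes <- function(n, ratio = c(0.7, 0.1, 0.2)) {
  if (length(ratio) != 3L || any(ratio < 0) || abs(sum(ratio) - 1) > 1e-8) {
    stop("'ratio' must be 3 non-negative proportions summing to 1", call. = FALSE)
  }
  train <- floor(ratio[1] * n + 0.5)
  test <- floor(ratio[3] * n)
  val <- n - train - test
  c(train = as.integer(train), val = as.integer(val), test = as.integer(test))
}

#' Per-sex cohort summary
#'
#' Counts, median age and interquartile range per sex, with quartiles by
#' linear interpolation of order statistics.
#'
#' @param records data.frame with `sex` and `age`.
#' @return data.frame with one row per sex: `sex`, `n`, `median_age`,
#'   `q1_age`, `q3_age`.
#' @export
summarize_cohort <- function(records) {
  check_records(records)
  out <- do.call(rbind, lapply(split(records$age, records$sex), function(a) {
    q <- stats::quantile(a, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(a), median_age = q[2], q1_age = q[1], q3_age = q[3])
  }))
  out <- cbind(sex = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Standardized mean difference of age between sexes
#'
#' `(mean_male - mean_female) / pooled SD`; the balance diagnostic used to
#' verify that matching reduced the age imbalance.
#'
#' @param records data.frame with `sex` and `age`.
#' @return A single number (can be negative).
#' @export
age_smd <- function(records) {
  a <- records$age[records$sex == "male"]
  b <- records$age[records$sex == "female"]
  sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}
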