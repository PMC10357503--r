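mk_cohort <- function(n, ages, A1 = "A*01:01", A2 = "A*03:01",
                      B1 = "B*07:02", B2 = "B*08:01", C1 = "C*07:01",
                      C2 = "C*07:02") {
  data.frame(id = sprintf("i%03d", seq_len(n)), age_dx = ages,
             sex = "male", status = "case", A1 = A1, A2 = A2, B1 = B1,
             B2 = B2, C1 = C1, C2 = C2, stringsAsFactors = FALSE)
}

test_that("age filter keeps the 20-year boundary and drops missing ages", {
  d <- mk_cohort(4, c(19, 20, 45, NA))
  expect_message(f <- filter_cohort(d), "2 individual")
  expect_equal(f$age_dx, c(20, 45))
  empty <- d[0, ]
  expect_identical(filter_cohort(empty), empty)
  ok <- mk_cohort(2, c(30, 40))
  expect_identical(filter_cohort(ok), ok)
})

test_that("carrier status counts allele copies and excludes A*02:01-only carriers", {
  seven <- ai_allele_set()
  d <- mk_cohort(1, 50, B1 = "B*27:05")
  expect_equal(carrier_status(d, seven), list(carrier = TRUE, count = 1))
  # A*02:01 homozygote is a non-carrier under the seven-allele set
  d2 <- mk_cohort(1, 50, A1 = "A*02:01", A2 = "A*02:01")
  expect_equal(carrier_status(d2, seven),
               list(carrier = FALSE, count = 0))
  expect_equal(carrier_status(d2, ai_allele_set("eight_allele"))$count, 2)
  d3 <- mk_cohort(1, 50, C1 = "C*06:02", C2 = "C*06:02")
  expect_equal(carrier_status(d3, seven)$count, 2)
  d4 <- mk_cohort(1, 50, B1 = "notanallele")
  expect_error(carrier_status(d4, seven), "unresolvable allele")
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  r <- mw_age_comparison(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)   # U = 0; 2 of C(6,3)=20 arrangements
  expect_equal(r$median_diff, -3)
  same <- mw_age_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(mw_age_comparison(numeric(), 1:3), "non-empty")
})

test_that("Mann-Whitney null p values are uniform and shifts are detected", {
  set.seed(52)
  ps <- replicate(400, {
    mw_age_comparison(rnorm(60, 58, 13), rnorm(120, 58, 13),
                      exact = FALSE)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)

  hits <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    p <- mw_age_comparison(rnorm(150, 63, 13), rnorm(300, 58, 13),
                           exact = FALSE)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 8)  # power >= 0.8 against a 5-year shift
})

test_that("leave-one-out keeps significance under an even planted effect", {
  cfg <- sim_config(n_individuals = 3000, seed = 61, ai_effect_years = 5)
  coh <- gen_cohort(cfg)
  loo <- leave_one_out(coh)
  expect_equal(nrow(loo), 7)
  expect_false(any(loo$degenerate))
  expect_true(all(loo$p_value < 0.05))
  expect_true(all(loo$median_diff > 0))

  # effect planted on a single allele is ablated by holding that allele out
  set.seed(62)
  n <- 1200
  d <- mk_cohort(n, rnorm(n, 58, 10))
  has <- seq_len(n) %% 6 == 0
  d$B1[has] <- "B*27:05"
  d$age_dx[has] <- d$age_dx[has] + 8
  loo2 <- leave_one_out(d)
  drop_target <- loo2$p_value[loo2$held_out == "B*27:05"]
  expect_true(is.na(drop_target) || drop_target > 0.05)
  # single-allele definition leaves an empty holdout set
  loo3 <- leave_one_out(d, ai = "B*27:05")
  expect_true(loo3$degenerate)
})

test_that("OLS recovers exact and planted coefficients and flags collinearity", {
  d <- mk_cohort(40, 50)
  d$ai_carrier <- rep(0:1, 20)
  d$age_dx <- 50 + 4.76 * d$ai_carrier
  res <- ols_age_model(d, exposure = "ai_carrier")
  expect_equal(res$estimate[res$term == "ai_carrier"], 4.76)

  cfg <- sim_config(n_individuals = 5000, seed = 71, ai_effect_years = 2.6)
  coh <- gen_cohort(cfg)
  res2 <- ols_age_model(coh, exposure = "ai_count")
  row <- res2[res2$term == "ai_count", ]
  expect_true(row$ci_lo <= 2.6 && 2.6 <= row$ci_hi)

  d$dup <- d$ai_carrier
  expect_error(ols_age_model(d, exposure = "ai_carrier",
                             covariates = "dup"), "collinear")
  d$flat <- 1
  expect_error(ols_age_model(d, exposure = "ai_carrier",
                             covariates = "flat"), "zero variance")
})

test_that("permuted exposure labels give a null-centred coefficient", {
  cfg <- sim_config(n_individuals = 2000, seed = 81, ai_effect_years = 2.6)
  coh <- gen_cohort(cfg)
  set.seed(82)
  est <- replicate(30, {
    coh$ai_perm <- sample(coh$ai_count)
    r <- ols_age_model(coh, exposure = "ai_perm")
    r$estimate[r$term == "ai_perm"]
  })
  expect_lt(abs(mean(est)), 0.5)
})

test_that("PRS scoring applies weights and effect-allele orientation", {
  w <- data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "A"),
                  weight = c(0.1, -0.2), stringsAsFactors = FALSE)
  d <- matrix(c(1, 2), nrow = 1, dimnames = list("i1", c("rs1", "rs2")))
  cnt <- c(rs1 = "A", rs2 = "A")
  expect_equal(unname(prs_score(d, w, counted = cnt)), -0.3)
  expect_equal(unname(prs_score(d * 0, w, counted = cnt)), 0)
  # counted allele opposite to effect: dosage 2 contributes 0
  w2 <- data.frame(snp = "rs1", effect_allele = "A", weight = 0.7)
  d2 <- matrix(2, nrow = 1, dimnames = list("i1", "rs1"))
  expect_equal(unname(prs_score(d2, w2, counted = c(rs1 = "G"))), 0)
  expect_error(prs_score(d2, w2), "counted allele unknown")
  # mean imputation of missing dosages
  d3 <- matrix(c(0, 2, NA), ncol = 1, dimnames = list(NULL, "rs1"))
  s3 <- prs_score(d3, w2, counted = c(rs1 = "A"))
  expect_equal(unname(s3[3]), 0.7 * 1)
})

test_that("PRS interaction model recovers distinct slopes by carrier status", {
  set.seed(91)
  n <- 2000
  carrier <- rbinom(n, 1, 0.3)
  prs <- rnorm(n)
  age <- 58 - 7.5 * prs - 9.1 * prs * carrier + 3 * carrier + rnorm(n, 0, 8)
  coh <- data.frame(age_dx = age, ai_carrier = carrier)
  res <- prs_interaction_model(coh, prs)
  row <- res[res$term == "prs:ai_carrier", ]
  expect_true(row$ci_lo <= -9.1 && -9.1 <= row$ci_hi)
  expect_lt(abs(row$estimate + 9.1), 1.5)

  age0 <- 58 - 7.5 * prs + rnorm(n, 0, 8)
  res0 <- prs_interaction_model(data.frame(age_dx = age0,
                                           ai_carrier = carrier), prs)
  expect_gt(res0$p_value[res0$term == "prs:ai_carrier"], 0.001)
  expect_error(prs_interaction_model(
    data.frame(age_dx = age, ai_carrier = 0), prs), "carriers")
})

test_that("logistic OR equals the 2x2 cross-product ratio", {
  d <- data.frame(status = rep(c("case", "case", "control", "control"),
                               c(10, 90, 20, 80)),
                  ai_carrier = rep(c(1, 0, 1, 0), c(10, 90, 20, 80)))
  res <- logistic_or(d)
  expect_equal(res$or, (10 * 80) / (90 * 20), tolerance = 1e-6)
  expect_error(logistic_or(data.frame(status = "case", ai_carrier = 1)),
               "both outcome classes")

  # null exposure at large n gives OR near 1
  set.seed(101)
  n <- 20000
  d2 <- data.frame(status = ifelse(rbinom(n, 1, 0.1) == 1, "case",
                                   "control"),
                   ai_carrier = rbinom(n, 1, 0.3))
  expect_lt(abs(log(logistic_or(d2)$or)), 0.15)
})

test_that("logistic OR recovers a planted protective effect at biobank scale", {
  set.seed(111)
  n <- 200000
  x <- rbinom(n, 1, 0.35)
  p <- plogis(qlogis(0.08) + log(0.96) * x)
  d <- data.frame(status = ifelse(rbinom(n, 1, p) == 1, "case", "control"),
                  ai_carrier = x)
  res <- logistic_or(d)
  expect_true(res$ci_lo <= 0.96 && 0.96 <= res$ci_hi)
})

test_that("Cliff's delta matches exhaustive enumeration and its symmetries", {
  expect_equal(cliffs_d(c(1, 2), c(3, 4)), -1)
  expect_equal(cliffs_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_d(c(1, 2, 3), c(2, 3, 4)), -5 / 9)
  expect_equal(cliffs_d(c(1, 2, 3), c(2, 3, 4)),
               brute_cliffs(c(1, 2, 3), c(2, 3, 4)))
  set.seed(121)
  for (i in 1:25) {
    a <- sample(1:6, sample(1:8, 1), replace = TRUE)
    b <- sample(1:6, sample(1:8, 1), replace = TRUE)
    expect_equal(cliffs_d(a, b), brute_cliffs(a, b))
    expect_equal(cliffs_d(a, b), -cliffs_d(b, a))
    expect_true(abs(cliffs_d(a, b)) <= 1)
  }
})

test_that("Fisher's exact equals the hypergeometric tail sum", {
  tab <- matrix(c(1, 9, 11, 3), nrow = 2, byrow = TRUE)
  res <- fisher_carrier_assoc(table = tab)
  expect_equal(res$p_value, brute_fisher(tab), tolerance = 1e-10)
  expect_equal(round(res$p_value, 6), 0.002759)
  zero <- matrix(c(0, 0, 5, 7), nrow = 2, byrow = TRUE)
  expect_equal(fisher_carrier_assoc(table = zero)$p_value, 1)
  # flag-vector interface builds the same table
  snp <- c(rep(TRUE, 10), rep(FALSE, 14))
  ai <- c(rep(TRUE, 1), rep(FALSE, 9), rep(TRUE, 11), rep(FALSE, 3))
  expect_equal(fisher_carrier_assoc(snp, ai)$p_value, res$p_value)
})

test_that("BH adjustment matches step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(131)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_equal(adj, brute_bh(p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("supertype comparison localizes a concentrated effect", {
  set.seed(141)
  n <- 600
  d <- mk_cohort(n, rnorm(n, 58, 10))
  has <- seq_len(n) %% 4 == 0
  d$B1[has] <- "B*27:05"
  d$age_dx[has] <- d$age_dx[has] + 8
  map <- data.frame(allele = c("B*27:05", "B*07:02", "B*08:01"),
                    supertype = c("B27", "B7", "B8"),
                    stringsAsFactors = FALSE)
  res <- supertype_compare(d, map)
  expect_lt(res$p_adj[res$supertype == "B27"], 0.05)
})

test_that("age-group labels follow the young/intermediate/old cuts", {
  expect_equal(assign_age_groups(c(49, 50, 68, 69, 20)),
               c("young", "intermediate", "intermediate", "old", "young"))
})
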