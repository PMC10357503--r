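clock_muts <- function(contexts, ref = "C", alt = "T", sample = "s1") {
  data.frame(sample = sample, ref = ref, alt = alt, context = contexts,
             stringsAsFactors = FALSE)
}

test_that("UV-corrected SBS1 counting applies the context rule exactly", {
  m <- clock_muts(c("ACG", "CCG", "TCG", "ACT"))
  expect_equal(count_uv_corrected_sbs1(m)$c_to_t_burden, 1L)
  expect_equal(count_uv_corrected_sbs1(clock_muts("GCG"))$c_to_t_burden, 1L)
  # non-C>T records do not count
  m2 <- rbind(clock_muts("ACG"), clock_muts("ACA", alt = "A"))
  expect_equal(count_uv_corrected_sbs1(m2)$c_to_t_burden, 1L)
})

test_that("counting is invariant to record order and strand representation", {
  # G>A at CGT on the purine strand is C>T at ACG after collapsing
  plus <- clock_muts(c("ACG", "GCG", "CCG"))
  minus <- data.frame(sample = "s1", ref = "G", alt = "A",
                      context = c("CGT", "CGC", "CGG"),
                      stringsAsFactors = FALSE)
  expect_equal(count_uv_corrected_sbs1(plus)$c_to_t_burden,
               count_uv_corrected_sbs1(minus)$c_to_t_burden)
  shuf <- plus[c(3, 1, 2), ]
  expect_equal(count_uv_corrected_sbs1(shuf)$c_to_t_burden,
               count_uv_corrected_sbs1(plus)$c_to_t_burden)
})

test_that("malformed contexts are rejected with the offending record", {
  expect_error(count_uv_corrected_sbs1(clock_muts("ACGT")),
               "malformed trinucleotide context")
  expect_error(count_uv_corrected_sbs1(clock_muts("AAG")),
               "malformed trinucleotide context")
})

test_that("individuals without mutation data get the median imputed", {
  m <- rbind(clock_muts(c("ACG", "GCG"), sample = "s1"),
             clock_muts(c("ACG", "ACG", "GCG", "GCG"), sample = "s2"),
             clock_muts("ACG", sample = "s3"))
  cc <- count_uv_corrected_sbs1(m, individuals = c("s1", "s2", "s3", "s4"))
  expect_equal(cc$c_to_t_burden[cc$individual == "s4"], 2L)  # lower median
  expect_true(cc$imputed[cc$individual == "s4"])
  expect_false(any(cc$imputed[cc$individual != "s4"]))
})

test_that("clock model fits exactly on noiseless data and recovers a planted slope", {
  cohort <- data.frame(id = c("a", "b", "c"), age_dx = c(30, 40, 50))
  counts <- data.frame(individual = c("a", "b", "c"),
                       c_to_t_burden = c(30, 40, 50), imputed = FALSE)
  m <- fit_clock_model(cohort, counts)
  expect_equal(m$beta_c_to_t, 1)
  expect_equal(m$pearson_r, 1)

  set.seed(31)
  n <- 400
  burden <- rpois(n, 40)
  age <- 20 + 0.85 * burden + rnorm(n, 0, 5)
  cohort <- data.frame(id = as.character(seq_len(n)), age_dx = age)
  counts <- data.frame(individual = as.character(seq_len(n)),
                       c_to_t_burden = burden, imputed = FALSE)
  m <- fit_clock_model(cohort, counts)
  ci <- stats::confint(m$fit)["c_to_t_burden", ]
  expect_true(ci[1] <= 0.85 && 0.85 <= ci[2])

  counts$c_to_t_burden <- 5
  expect_error(fit_clock_model(cohort, counts), "zero variance")
})

test_that("personalized sojourn follows the shift formula and the onset identity", {
  cohort <- data.frame(id = c("a", "b", "c", "d"),
                       age_dx = c(60, 55, 70, 48),
                       sex = c("male", "male", "female", "male"))
  counts <- data.frame(individual = c("a", "b", "c", "d"),
                       c_to_t_burden = c(41, 40, 45, 40),
                       imputed = c(FALSE, FALSE, FALSE, TRUE))
  model <- structure(list(beta_c_to_t = 0.85), class = "clock_model")
  sbs <- c(male = 8.35, female = 9.64)
  on <- personalized_onset(cohort, counts, sbs, model)
  # median burden (non-imputed: 40, 41, 45 -> lower median 41)
  expect_equal(on$personalized_sojourn[on$id == "a"], 8.35)
  expect_equal(on$personalized_sojourn[on$id == "b"], 8.35 - 0.85)
  expect_equal(on$personalized_sojourn[on$id == "c"], 9.64 + 4 * 0.85)
  # imputed individuals sit exactly at the sex baseline
  expect_equal(on$personalized_sojourn[on$id == "d"], 8.35)
  # onset identity holds exactly
  expect_identical(on$onset_age + on$personalized_sojourn, on$age_dx)

  model0 <- structure(list(beta_c_to_t = 0), class = "clock_model")
  on0 <- personalized_onset(cohort, counts, sbs, model0)
  expect_equal(on0$personalized_sojourn,
               unname(sbs[cohort$sex]))
  expect_error(personalized_onset(cohort, counts, c(male = 8.35), model),
               "female")
})

test_that("a one-mutation deviation shifts sojourn by one clock unit", {
  cohort <- data.frame(id = c("m", "x", "y"), age_dx = c(60, 50, 55),
                       sex = "male")
  counts <- data.frame(individual = c("m", "x", "y"),
                       c_to_t_burden = c(41, 40, 40), imputed = FALSE)
  model <- structure(list(beta_c_to_t = 0.85), class = "clock_model")
  on <- personalized_onset(cohort, counts, c(male = 8.35), model)
  # median burden is 40, so individual m carries one extra clock mutation
  expect_equal(on$personalized_sojourn[on$id == "m"], 9.20)
  expect_equal(on$onset_age[on$id == "m"], 60 - 9.20)
})

test_that("WGD sojourn comparison detects separation and planted shifts", {
  on <- data.frame(id = as.character(1:10),
                   personalized_sojourn = rep(c(12, 6), each = 5))
  wgd <- rep(c(TRUE, FALSE), each = 5)
  res <- compare_wgd_sojourn(on, wgd)
  expect_gt(res$median_wgd, res$median_no_wgd)
  expect_lt(res$p_value, 0.05)

  same <- data.frame(id = as.character(1:10),
                     personalized_sojourn = rep(1:5, 2))
  res2 <- compare_wgd_sojourn(same, rep(c(TRUE, FALSE), each = 5))
  expect_gt(res2$p_value, 0.4)

  expect_error(compare_wgd_sojourn(on, rep(TRUE, 10)), "non-empty")

  # power against a planted +3-year shift at n = 100/group
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    soj <- c(rnorm(100, 11, 3), rnorm(100, 8, 3))
    d <- data.frame(id = as.character(1:200), personalized_sojourn = soj)
    r <- compare_wgd_sojourn(d, rep(c(TRUE, FALSE), each = 100))
    hits <- hits + (r$p_value < 0.05)
  }
  expect_gte(hits, 19)
})
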