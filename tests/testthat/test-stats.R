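test_that("pearson_cor matches the product-moment formula and its t p-value", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  # textbook formula evaluated directly
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- 4
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = n - 2)
  got <- pearson_cor(x, y)
  expect_equal(got$r, r_hand)
  expect_equal(got$p, p_hand)
  expect_equal(got$n, 4L)
})

test_that("pearson_cor handles perfect linearity and invalid input", {
  x <- c(0.3, 1.7, 2, 5.5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(1, 4)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
  expect_error(pearson_cor(1:4, 1:3), "equal length")
})

test_that("pearson_cor is affine-invariant and antisymmetric under negation", {
  set.seed(8)
  x <- rnorm(12); y <- x + rnorm(12, sd = 0.5)
  base <- pearson_cor(x, y)
  shifted <- pearson_cor(3 * x - 7, 0.1 * y + 100)
  expect_equal(shifted$r, base$r)
  expect_equal(pearson_cor(x, -y)$r, -base$r)
})

# minimal trial_result scaffold with prescribed per-step recruited counts
fake_trial <- function(subject, peeps, counts_by_cat) {
  steps <- lapply(seq_along(peeps), function(i) {
    cnt <- c(lung_ee = 100, lung_tidal = 100,
             overinflated = counts_by_cat$overinflated[i],
             cyclic = counts_by_cat$cyclic[i],
             recruited = counts_by_cat$recruited[i])
    structure(list(peep_cmH2O = peeps[i], masks = list(),
                   counts = cnt, percentages = 100 * cnt[3:5] / 200,
                   qc = list(), failed = FALSE),
              class = "step_result")
  })
  structure(list(subject_id = subject, reference_peep_cmH2O = 6,
                 total_lung_pixels = 200, reference_lung_ee = NULL,
                 steps = steps, below_reference = list()),
            class = "trial_result")
}

test_that("correlate_trials recovers exact linear relations per subject", {
  peeps <- seq(9, 30, by = 3)
  trials <- list(); ancs <- list()
  for (s in 1:3) {
    rec <- s * 10 + 4 * seq_along(peeps)
    trials[[s]] <- fake_trial(paste0("pig", s), peeps,
                              list(overinflated = rep(1, 8),
                                   cyclic = rep(1, 8), recruited = rec))
    # PaO2/FiO2 an exact increasing linear function of recruited count
    ancs[[s]] <- data.frame(peep_cmH2O = peeps, pao2_fio2 = 50 + 2.5 * rec)
  }
  res <- correlate_trials(trials, ancs, category = "recruited",
                          variable = "pao2_fio2")
  expect_equal(res$per_subject_r, rep(1, 3))
  expect_equal(res$group_mean_r, 1)
  expect_equal(res$group_sd_r, 0)

  # single subject: SD undefined, reported as NA
  solo <- correlate_trials(trials[1], ancs[1], category = "recruited")
  expect_true(is.na(solo$group_sd_r))
  expect_equal(solo$group_mean_r, 1)
})

test_that("correlate_trials skips subjects with too few matched steps", {
  peeps <- seq(9, 30, by = 3)
  rec <- 4 * seq_along(peeps)
  t_ok <- fake_trial("ok", peeps, list(overinflated = rep(1, 8),
                                       cyclic = rep(1, 8), recruited = rec))
  anc_ok <- data.frame(peep_cmH2O = peeps, pao2_fio2 = 100 + rec)
  t_bad <- fake_trial("bad", c(9, 12), list(overinflated = c(1, 1),
                                            cyclic = c(1, 1),
                                            recruited = c(5, 9)))
  anc_bad <- data.frame(peep_cmH2O = c(9, 12), pao2_fio2 = c(100, 140))
  expect_warning(
    res <- correlate_trials(list(t_ok, t_bad), list(anc_ok, anc_bad),
                            category = "recruited"),
    "skipped")
  expect_equal(res$subjects, "ok")
  expect_equal(res$skipped, "bad")

  expect_error(correlate_trials(list(t_ok), list(anc_ok), variable = "nope"),
               "lacks column")
})

test_that("group mean r on seeded noisy linear data matches a Monte-Carlo oracle", {
  # subjects share a linear count-physiology relation with additive noise;
  # the oracle estimates E[r] for that generative model by brute simulation
  gen_r <- function(seed) {
    set.seed(seed)
    x <- seq(10, 80, length.out = 8)
    y <- 2 * x + rnorm(8, sd = 30)
    stats::cor(x, y)
  }
  oracle <- mean(vapply(1:1000, gen_r, numeric(1)))

  peeps <- seq(9, 30, by = 3)
  trials <- list(); ancs <- list()
  for (s in 1:15) {
    set.seed(5000 + s)
    rec <- seq(10, 80, length.out = 8)
    trials[[s]] <- fake_trial(paste0("p", s), peeps,
                              list(overinflated = rep(1, 8),
                                   cyclic = rep(1, 8), recruited = rec))
    ancs[[s]] <- data.frame(peep_cmH2O = peeps,
                            pao2_fio2 = 2 * rec + rnorm(8, sd = 30))
  }
  res <- correlate_trials(trials, ancs, category = "recruited")
  mc_sd <- stats::sd(vapply(1:1000, gen_r, numeric(1)))
  expect_lt(abs(res$group_mean_r - oracle), 3 * mc_sd / sqrt(15))
})

test_that("crs implements VT over driving pressure", {
  expect_equal(crs(300, 20, 5), 20)
  expect_equal(crs(420, 26, 12), 30)
  expect_error(crs(0, 20, 5), "positive")
  expect_error(crs(300, 5, 5), "exceed PEEP")
})
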