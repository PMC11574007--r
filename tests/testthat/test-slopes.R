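make_balanced <- function(seed, n = 40, nv = 4, sd_res = 0.05,
                          slopes = NULL, intercepts = NULL) {
  set.seed(seed)
  if (is.null(slopes)) slopes <- rnorm(n, 0.02, 0.01)
  if (is.null(intercepts)) intercepts <- rnorm(n, 2, 0.1)
  id <- rep(sprintf("P%03d", 1:n), each = nv)
  tt <- rep(seq_len(nv) - 1, n)
  y <- intercepts[rep(1:n, each = nv)] + slopes[rep(1:n, each = nv)] * tt +
    rnorm(n * nv, 0, sd_res)
  list(data = data.frame(participant_id = id, time = tt, value = y,
                         family_id = rep(sprintf("F%03d", rep(1:10,
                                                              length.out = n)),
                                         each = nv),
                         stringsAsFactors = FALSE),
       slopes = slopes)
}

test_that("noiseless linear subjects recover their exact slopes", {
  g <- make_balanced(1, sd_res = 0)
  sl <- extract_subject_slopes(g$data, "value")
  expect_equal(sl$annualized_slope, unname(g$slopes), tolerance = 1e-6)
  expect_equal(sl$n_visits_used, rep(4L, 40))
})

test_that("empirical-Bayes slopes shrink relative to per-subject OLS", {
  for (s in c(2, 3)) {
    g <- make_balanced(s)
    sl <- extract_subject_slopes(g$data, "value")
    ols <- vapply(split(seq_len(nrow(g$data)), g$data$participant_id),
                  function(ix) coef(lm(value ~ time,
                                       data = g$data[ix, ]))[[2]],
                  numeric(1))
    pop <- mean(sl$annualized_slope)
    # strict variance contraction versus the OLS oracle
    expect_lt(var(sl$annualized_slope), var(ols))
    # slopes move toward the population mean, never past the OLS estimate
    # by more than a small fraction of the OLS spread (the BLUP under a
    # correlated intercept+slope model shrinks toward a conditional mean,
    # so the literal between-property can be crossed slightly)
    expect_lt(mean(abs(sl$annualized_slope - pop)), mean(abs(ols - pop)))
    viol <- pmax(sl$annualized_slope - pmax(ols, pop),
                 pmin(ols, pop) - sl$annualized_slope)
    expect_lt(max(viol), 0.5 * sd(ols - pop))
  }
})

test_that("the population mean slope is recovered at n = 200", {
  g <- make_balanced(4, n = 200)
  sl <- extract_subject_slopes(g$data, "value")
  mc_se <- 0.01 / sqrt(200)  # generating slope SD / sqrt(n)
  expect_lt(abs(mean(sl$annualized_slope) - 0.02), 2 * mc_se + 0.002)
})

test_that("exactly collinear fluids give r2 = 1; too few pairs error", {
  d <- data.frame(csf = 1:10 * 0.3 + 2, plasma = 1:10, group = "MC")
  expect_equal(relate_csf_plasma(d, adjust = FALSE)$r2, 1, tolerance = 1e-12)
  expect_error(relate_csf_plasma(data.frame(csf = 1:2, plasma = 1:2,
                                            group = "NC"), adjust = FALSE),
               "fewer than 3")
})

test_that("independent fluids give near-zero r2 and uniform null p-values", {
  set.seed(5)
  r2s <- numeric(100); ps <- numeric(100)
  for (k in 1:100) {
    d <- data.frame(csf = rnorm(50), plasma = rnorm(50), group = "NC")
    r <- relate_csf_plasma(d, adjust = FALSE)
    r2s[k] <- r$r2; ps[k] <- r$p
  }
  expect_lt(mean(r2s), 0.05)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Akaike weights follow the closed form and sum to one", {
  set.seed(6)
  n <- 120
  d <- data.frame(plasma = rnorm(n), age = rnorm(n, 40, 10),
                  sex = sample(c("male", "female"), n, TRUE),
                  bmi = rnorm(n, 27, 5))
  d$csf <- 1 + 0.5 * d$plasma + 0.02 * d$age + rnorm(n, 0, 0.3)
  tab <- aic_select(d, "csf")
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$cum_weight) >= -1e-12))
  expect_true(all(diff(tab$aic) >= 0))
  # closed form: w_i proportional to exp(-delta_i / 2)
  w_oracle <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  expect_equal(tab$weight, w_oracle, tolerance = 1e-12)
  # two candidates with AIC gap 2 -> weights 1/(1+e^-1), via the same form
  d2 <- tab$aic[1:2]
  w2 <- exp(-(d2 - min(d2)) / 2); w2 <- w2 / sum(w2)
  expect_equal(exp(-1) / (1 + exp(-1)), 0.2689414, tolerance = 1e-6)
  # identical candidates -> equal weights
  tab_eq <- aic_select(d, "csf", candidates = list("age", "age", "age"))
  expect_equal(tab_eq$weight, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("adding a pure-noise covariate does not raise the Akaike weight", {
  set.seed(7)
  w_true <- w_aug <- numeric(20)
  for (k in 1:20) {
    n <- 100
    d <- data.frame(plasma = rnorm(n), age = rnorm(n), noise = rnorm(n))
    d$csf <- 1 + 0.6 * d$plasma + 0.3 * d$age + rnorm(n, 0, 0.4)
    tab <- aic_select(d, "csf", candidates = list("age", c("age", "noise")))
    w_true[k] <- tab$weight[tab$covariates == "age"]
    w_aug[k] <- tab$weight[tab$covariates == "age+noise"]
  }
  expect_gt(mean(w_true), mean(w_aug))
})

test_that("group contrasts are equivariant under relabeling and adjusted p >= raw p", {
  set.seed(8)
  n <- c(NC = 40, presymptomatic_MC = 35, converter_MC = 12,
         symptomatic_MC = 25)
  N <- sum(n)
  d <- data.frame(value = c(rnorm(40, 0, 0.005), rnorm(35, 0.01, 0.005),
                            rnorm(12, 0.02, 0.005), rnorm(25, 0.03, 0.005)),
                  stage = rep(names(n), n),
                  age = rnorm(N, 40, 8),
                  sex = sample(c("male", "female"), N, TRUE),
                  bmi = rnorm(N, 27, 4),
                  family_id = sample(sprintf("F%02d", 1:20), N, TRUE))
  cmp <- compare_groups(d)
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$p_adj >= cmp$p_raw - 1e-15))
  # swapping two labels permutes the corresponding estimates (sign flips
  # when the contrast order flips)
  d2 <- d
  d2$stage[d$stage == "NC"] <- "symptomatic_MC"
  d2$stage[d$stage == "symptomatic_MC"] <- "NC"
  cmp2 <- compare_groups(d2)
  e1 <- cmp$estimate[cmp$contrast == "NC - symptomatic_MC"]
  e2 <- cmp2$estimate[cmp2$contrast == "NC - symptomatic_MC"]
  expect_equal(e1, -e2, tolerance = 1e-8)
  # ordered generation: all NC-vs-later contrasts negative
  later <- grepl("^NC - ", cmp$contrast)
  expect_true(all(cmp$estimate[later] < 0))
})

test_that("tiny groups are omitted with a warning", {
  set.seed(9)
  d <- data.frame(value = rnorm(50),
                  stage = c(rep("NC", 25), rep("presymptomatic_MC", 24),
                            "converter_MC"),
                  age = rnorm(50, 40, 8),
                  sex = sample(c("male", "female"), 50, TRUE),
                  bmi = rnorm(50, 27, 4),
                  family_id = sample(sprintf("F%02d", 1:10), 50, TRUE))
  expect_warning(compare_groups(d), "converter_MC")
  cmp <- suppressWarnings(compare_groups(d))
  expect_equal(nrow(cmp), 1)  # only NC vs presymptomatic remains
})

test_that("plasma/CSF ratio is the absolute-scale quotient and unit consistent", {
  v <- data.frame(participant_id = c("A", "B", "C"), visit_index = 1,
                  plasma_nfl = c(5.8, 7, 10), csf_nfl = c(243.8, 7, 100))
  r <- plasma_csf_ratio(v)
  expect_equal(r$ratio[1], 0.0237899917966, tolerance = 1e-10)
  expect_equal(r$ratio[2], 1)
  v2 <- v
  v2$plasma_nfl <- v$plasma_nfl * 3.7
  v2$csf_nfl <- v$csf_nfl * 3.7
  expect_equal(plasma_csf_ratio(v2)$ratio, r$ratio, tolerance = 1e-12)
  v$csf_nfl[2] <- -1
  expect_error(plasma_csf_ratio(v), "nonpositive")
})
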