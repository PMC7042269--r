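test_that("per-gene fits match lm() exactly", {
  toy <- toy_study(n_genes = 25L, seed = 11L)
  st <- toy$study
  fit <- fit_gene_models(st)
  x <- st$condition
  for (g in sample(rownames(st$values), 10L)) {
    i <- match(g, fit$gene)
    ref <- stats::lm(st$values[g, ] ~ x)
    sm <- summary(ref)
    expect_equal(fit$beta[i], unname(stats::coef(ref)[2L]),
                 tolerance = 1e-10)
    expect_equal(fit$s2[i], sm$sigma^2, tolerance = 1e-10)
    expect_equal(fit$se_unscaled[i] * sqrt(fit$s2[i]),
                 sm$coefficients[2L, 2L], tolerance = 1e-10)
  }
  expect_equal(fit$df[1L],
               stats::df.residual(stats::lm(st$values[1, ] ~ x)))
})

test_that("collinear covariates are rejected with a clear message", {
  toy <- toy_study(n_genes = 10L, n_deg = 3L, seed = 2L)
  st <- toy$study
  bad <- expression_study(st$values, st$condition,
                          covariates = data.frame(dup = st$condition))
  expect_error(fit_gene_models(bad), "dup|rank")
})

test_that("variance moderation recovers a known prior at scale", {
  set.seed(5)
  d0 <- 8; s02 <- 2; df <- 6
  s2 <- s02 * d0 / stats::rchisq(2000, d0) * stats::rchisq(2000, df) / df
  mod <- moderate_variances(s2, df)
  expect_lt(abs(mod$d0 - d0) / d0, 0.25)
  expect_lt(abs(mod$s02 - s02) / s02, 0.25)
  expect_equal(mod$df_total, mod$d0 + rep(df, 2000))
  # moderated values shrink toward the prior
  expect_true(all(pmin(s2, mod$s02) - 1e-9 <= mod$s2_tilde &
                  mod$s2_tilde <= pmax(s2, mod$s02) + 1e-9))
})

test_that("equal sample variances give an infinite prior df", {
  mod <- moderate_variances(rep(1.7, 50), df = 10)
  expect_identical(mod$d0, Inf)
  # all moderated variances collapse onto the prior estimate
  expect_equal(unique(mod$s2_tilde), mod$s02)
})

test_that("bh_adjust matches p.adjust and the step-up oracle", {
  set.seed(3)
  for (i in 1:20) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values|\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("deg_table finds planted shifts and controls the sign", {
  toy <- toy_study(n_genes = 80L, n_deg = 20L, shift = 2.5, seed = 21L)
  tab <- deg_table(toy$study, fdr_threshold = 0.05)
  called <- tab$gene[tab$deg]
  expect_gte(mean(toy$deg_genes %in% called), 0.9)
  expect_true(all(tab$direction[tab$gene %in% toy$deg_genes & tab$deg] == "up"))
  expect_equal(tab$fc, 2^tab$beta)
  expect_true(all(diff(tab$q[order(tab$p)]) >= -1e-12))
  calls <- call_degs(tab)
  expect_setequal(c(calls$up, calls$down), called)
})

test_that("zero-variance genes are never called differential", {
  vals <- matrix(rnorm(40), 8, 5,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  vals[3, ] <- 2
  st <- expression_study(vals, c(0, 0, 1, 1, 1))
  tab <- deg_table(st)
  expect_equal(tab$p[tab$gene == "g3"], 1)
  expect_false(tab$deg[tab$gene == "g3"])
})

test_that("moderated tests agree with limma when it is installed", {
  skip_if_not_installed("limma")
  toy <- toy_study(n_genes = 120L, n_deg = 30L, shift = 1.5, seed = 9L)
  st <- toy$study
  design <- cbind(1, st$condition)
  lf <- limma::eBayes(limma::lmFit(st$values, design))
  tab <- deg_table(st)
  tab <- tab[match(rownames(st$values), tab$gene), ]
  expect_equal(tab$beta, unname(lf$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(attr(tab, "moderation")$d0, lf$df.prior, tolerance = 1e-4)
  expect_equal(tab$p, lf$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})
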