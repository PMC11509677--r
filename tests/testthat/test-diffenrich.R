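make_logmat <- function(n = 200, seed = 1, effect = 0, sd = 0.5,
                        design = default_design()) {
  set.seed(seed)
  base <- stats::rnorm(n, 25, 2)
  lm2 <- sapply(seq_len(nrow(design)), function(j) {
    mu <- base + if (design$bait[j] == "Cav1") effect else 0
    mu + stats::rnorm(n, 0, sd)
  })
  dimnames(lm2) <- list(sprintf("P%04d", 1:n), design$sample_id)
  attr(lm2, "design") <- design
  lm2
}

test_that("with d0 = 0 the moderated t reduces to the ordinary pooled t", {
  lm2 <- make_logmat(n = 300, seed = 2)
  res <- moderated_t_test(lm2, c("Cav1_NT", "NES_NT"),
                          prior = list(d0 = 0, s0_sq = 1))
  design <- attr(lm2, "design")
  nt <- lm2[, group_samples(design, "Cav1_NT")]
  nes <- lm2[, group_samples(design, "NES_NT")]
  for (i in seq(1, 300, by = 7)) {
    tt <- stats::t.test(nt[i, ], nes[i, ], var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("d0 at the infinity cap gives full shrinkage to s0", {
  lm2 <- make_logmat(n = 100, seed = 3)
  res <- moderated_t_test(lm2, c("Cav1_NT", "NES_NT"),
                          prior = list(d0 = 1e6, s0_sq = 0.3))
  expect_true(all(abs(res$s_post_sq - 0.3) < 1e-4))
})

test_that("prior fit returns the cap and the common variance when spread is zero", {
  prior <- fit_fdist_moments(rep(0.25, 100), df = 4)
  expect_equal(prior$d0, 1e6)
  expect_equal(prior$s0_sq, 0.25, tolerance = 1e-12)
  expect_error(fit_fdist_moments(stats::rchisq(10, 4), df = 4), "usable")
})

test_that("prior hyperparameters are recovered from a known scaled-F sample", {
  set.seed(4)
  d0 <- 4; s0 <- 0.05; dg <- 4; n <- 5000
  s2 <- s0 * (stats::rchisq(n, dg) / dg) / (stats::rchisq(n, d0) / d0)
  est <- fit_fdist_moments(s2, df = dg)
  expect_lt(abs(est$d0 - d0) / d0, 0.15)
  expect_lt(abs(est$s0_sq - s0) / s0, 0.15)
})

test_that("prior fit matches limma's estimator on the same variances", {
  skip_if_not_installed("limma")
  set.seed(5)
  s2 <- 0.1 * (stats::rchisq(2000, 4) / 4) / (stats::rchisq(2000, 6) / 6)
  est <- fit_fdist_moments(s2, df = 4)
  ref <- limma::fitFDist(s2, df1 = 4)
  expect_equal(est$d0, ref$df2, tolerance = 1e-6)
  expect_equal(est$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("shrinkage moves t towards the prior in the documented direction", {
  lm2 <- make_logmat(n = 500, seed = 6)
  prior <- fit_variance_prior(lm2)
  mod <- moderated_t_test(lm2, c("Cav1_NT", "NES_NT"), prior)
  ord <- moderated_t_test(lm2, c("Cav1_NT", "NES_NT"),
                          prior = list(d0 = 0, s0_sq = 1))
  noisy <- which(mod$s_g_sq > prior$s0_sq)
  quiet <- which(mod$s_g_sq < prior$s0_sq)
  expect_true(all(abs(mod$t_mod[noisy]) >= abs(ord$t_mod[noisy]) - 1e-12))
  expect_true(all(abs(mod$t_mod[quiet]) <= abs(ord$t_mod[quiet]) + 1e-12))
  # posterior variance lies between the observed and prior variance
  expect_true(all(mod$s_post_sq >= pmin(mod$s_g_sq, prior$s0_sq) - 1e-12))
  expect_true(all(mod$s_post_sq <= pmax(mod$s_g_sq, prior$s0_sq) + 1e-12))
  # sign of t follows sign of logFC
  expect_true(all(sign(mod$t_mod) == sign(mod$logFC), na.rm = TRUE))
})

test_that("proteins with a degenerate group are flagged, not dropped", {
  lm2 <- make_logmat(n = 20, seed = 7)
  lm2[1, group_samples(attr(lm2, "design"), "NES_NT")] <- NA
  lm2[2, group_samples(attr(lm2, "design"), "NES_NT")[1]] <- NA
  res <- moderated_t_test(lm2, c("Cav1_NT", "NES_NT"),
                          prior = list(d0 = 4, s0_sq = 0.2))
  expect_equal(nrow(res), 20)
  expect_false(res$testable[1])
  expect_true(res$testable[2])   # 1 missing still leaves n = 2
  expect_true(is.na(res$p[1]))
  expect_error(moderated_t_test(lm2, c("Cav1_NT", "nope"),
                                prior = list(d0 = 4, s0_sq = 0.2)),
               "unknown group")
})

test_that("enrichment calls use strict p and logFC thresholds", {
  mk <- function(p, lfc) {
    r <- data.frame(protein_id = c("A", "B", "C"), logFC = lfc,
                    s_g_sq = 0.1, d_g = 4, s_post_sq = 0.1,
                    t_mod = sign(lfc), p = p, df_total = 8, testable = TRUE)
    class(r) <- c("diff_result", "data.frame")
    r
  }
  res <- list(NT = mk(c(0.04, 0.04, 0.05), c(1.2, -0.5, 2)),
              HYPO = mk(c(0.5, 0.5, 0.5), c(1, 1, 1)),
              REC = mk(c(0.5, 0.5, 0.5), c(1, 1, 1)))
  calls <- call_enrichment(res)
  expect_identical(unname(calls[, "NT"]), c(TRUE, FALSE, FALSE))

  res$HYPO$protein_id <- c("A", "B", "X")
  expect_error(call_enrichment(res), "universe")
})

test_that("all eight call patterns classify to their categories and partition", {
  pats <- expand.grid(NT = c(FALSE, TRUE), HYPO = c(FALSE, TRUE),
                      REC = c(FALSE, TRUE))
  calls <- as.matrix(pats)
  rownames(calls) <- sprintf("P%d", 1:8)
  cls <- classify_interactome(calls)
  truth <- apply(pats, 1, function(r) {
    on <- c("NT", "HYPO", "REC")[as.logical(r)]
    if (!length(on)) "none"
    else if (length(on) == 1) paste0(on, "_only")
    else paste(on, collapse = "_")
  })
  expect_identical(unname(cls$category), unname(truth))
  # the seven significant categories partition the significant union
  expect_equal(cls$n_significant, sum(cls$counts[names(cls$counts) != "none"]))
  expect_equal(cls$n_significant, 7)
  # co-recovered reading: NT&REC with or without HYPO
  expect_setequal(cls$co_recovered,
                  rownames(calls)[calls[, "NT"] & calls[, "REC"]])
  # order invariance
  perm <- sample(8)
  cls2 <- classify_interactome(calls[perm, ])
  expect_equal(as.vector(cls2$counts), as.vector(cls$counts))
})

test_that("random instances always partition and respect threshold monotonicity", {
  set.seed(8)
  lm2 <- make_logmat(n = 400, seed = 8, effect = 1)
  prior <- fit_variance_prior(lm2)
  res <- lapply(c(NT = "NT", HYPO = "HYPO", REC = "REC"), function(cc)
    moderated_t_test(lm2, c(paste0("Cav1_", cc), "NES_NT"), prior))
  sizes <- c()
  for (p_thresh in c(0.1, 0.05, 0.01, 0.001)) {
    cls <- classify_interactome(call_enrichment(res, p_thresh = p_thresh))
    expect_equal(cls$n_significant,
                 sum(cls$counts[names(cls$counts) != "none"]))
    sizes <- c(sizes, cls$n_significant)
  }
  expect_true(all(diff(sizes) <= 0))  # stricter p never enlarges the union
})

test_that("z-score profiles standardise rows and flag degeneracies", {
  design <- default_design()
  lm2 <- make_logmat(n = 5, seed = 9)
  # per-sample mode on a constructed row
  lm2[1, design$sample_id[design$bait == "Cav1"]] <- rep(c(1, 2, 3), each = 3)
  zp <- zscore_profiles(lm2, mode = "per_condition_mean")
  expect_equal(unname(zp$z[1, ]), c(-1, 0, 1))
  lm2[2, ] <- 7  # constant row
  zp2 <- zscore_profiles(lm2, mode = "per_condition_mean")
  expect_true(zp2$undefined[2])
  expect_true(all(is.na(zp2$z[2, ])))
  # rows have mean 0 and sd 1 over non-missing entries
  zp3 <- zscore_profiles(lm2, mode = "per_sample")
  ok <- !zp3$undefined
  expect_true(all(abs(rowMeans(zp3$z[ok, ], na.rm = TRUE)) < 1e-12))
  expect_true(all(abs(apply(zp3$z[ok, ], 1, stats::sd, na.rm = TRUE) - 1) < 1e-12))
})

test_that("planted tension-sensitive proteins show the depleted-HYPO z pattern", {
  sim <- simulate_lfq_experiment(synth_proteome_config(n_proteins = 2000, seed = 10))
  lm2 <- replicate_presence_filter(log2_transform(sim$table))
  core <- intersect(sim$truth$protein_id[sim$truth$class == "core_caveolar"],
                    rownames(lm2))
  zp <- zscore_profiles(lm2, core, mode = "per_condition_mean")
  hypo_z <- zp$z[!zp$undefined, "HYPO"]
  expect_gt(mean(hypo_z < 0, na.rm = TRUE), 0.95)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:200) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
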