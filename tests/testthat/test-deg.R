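test_that("classical pooled t matches the hand-computed example", {
  m <- rbind(g1 = c(3, 4, 1, 2), g2 = c(1, 1.5, 1.2, 1.3))
  colnames(m) <- paste0("s", 1:4)
  data <- make_integrated(m, c("case", "case", "control", "control"))
  tab <- fit_moderated_t(data, ebayes = FALSE)
  row <- tab[tab$gene == "g1", ]
  expect_equal(row$logFC, 2)
  expect_equal(row$t, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(row$df_resid, 2)
  expect_equal(row$p, 0.1055728, tolerance = 1e-6)
})

test_that("equal group means give t = 0, p = 1", {
  m <- rbind(g1 = c(1, 3, 2, 2), g2 = c(5, 6, 4, 7))
  colnames(m) <- paste0("s", 1:4)
  data <- make_integrated(m, c("case", "case", "control", "control"))
  tab <- fit_moderated_t(data, ebayes = FALSE)
  expect_equal(tab[tab$gene == "g1", "t"], 0)
  expect_equal(tab[tab$gene == "g1", "p"], 1)
})

test_that("a complete-shrinkage prior equal to the gene variance recovers the classical t", {
  st <- make_study(n_genes = 40, seed = 6)
  data <- integrate_studies(list(st))
  plain <- fit_moderated_t(data, ebayes = FALSE)
  # with d0 = Inf the posterior variance is s0_sq for every gene; choosing
  # s0_sq = s2 of one gene makes that gene's moderated t the classical one
  g <- plain$gene[5]
  shrunk <- fit_moderated_t(data, prior = list(d0 = Inf,
                                               s0_sq = plain$s2[plain$gene == g]))
  t_ratio <- shrunk$t[shrunk$gene == g] / plain$t[plain$gene == g]
  expect_equal(t_ratio, 1, tolerance = 1e-12)
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  withr::with_seed(31, {
    x <- matrix(rnorm(400 * 12), 400, 12,
                dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:12)))
    x[1:25, 1:6] <- x[1:25, 1:6] + 1.2
  })
  grp <- rep(c("case", "control"), each = 6)
  mine <- fit_moderated_t(make_integrated(x, grp))
  design <- cbind(control = 1, case_vs_control = as.numeric(grp == "case"))
  fit <- limma::eBayes(limma::lmFit(x, design))
  mine <- mine[match(rownames(x), mine$gene), ]
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-10)
  expect_equal(attr(mine, "s0_sq"), fit$s2.prior, tolerance = 1e-10)
  expect_equal(mine$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-12)
  expect_equal(mine$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up definition and the p.adjust oracle", {
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(17, {
    for (i in 1:1000) {
      p <- runif(sample(1:20, 1))
      expect_equal(adjust_bh(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
    }
  })
})

test_that("DEG calling applies the dual fold-change / adjusted-p threshold", {
  tab <- data.frame(gene = c("PTPRJ_like", "small_fc", "weak_p"),
                    logFC = c(0.78, 0.5, 0.9),
                    p_adj = c(0.03, 0.001, 0.2))
  expect_equal(call_degs(tab), "PTPRJ_like")
  expect_error(call_degs(tab, fc_threshold = 1), "> 1")
  expect_error(call_degs(tab, alpha = 0), "\\(0, 1\\]")
})

test_that("tightening both thresholds never adds genes (nestedness)", {
  for (s in 1:5) {
    sim <- simulate_collection(sim_config(n_genes = 300, seed = s))
    tab <- fit_moderated_t(integrate_studies(sim$studies))
    loose <- call_degs(tab, 1.5, 0.05)
    tight <- call_degs(tab, 2.0, 0.01)
    expect_true(all(tight %in% loose))
  }
})

test_that("recovered effect directions match the simulated signs", {
  agree <- vapply(1:10, function(s) {
    sim <- simulate_collection(sim_config(n_genes = 500, seed = s))
    tab <- fit_moderated_t(integrate_studies(sim$studies))
    degs <- intersect(call_degs(tab), sim$truth$deg_genes)
    est <- tab$logFC[match(degs, tab$gene)]
    mean(sign(est) == sign(sim$truth$effect[degs]))
  }, numeric(1))
  expect_true(mean(agree) >= 0.99)
})

test_that("degenerate inputs are rejected or guarded", {
  m <- rbind(g1 = c(1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  expect_error(fit_moderated_t(make_integrated(m, c("case", rep("control", 3)))),
               ">= 2 samples per group")

  # zero-variance gene falls back to the prior variance
  m2 <- rbind(g1 = c(5, 5, 2, 2), g2 = c(1, 2, 0.5, 1.5),
              g3 = c(3, 1, 2.5, 2))
  colnames(m2) <- paste0("s", 1:4)
  expect_message(
    tab <- fit_moderated_t(make_integrated(m2, rep(c("case", "control"),
                                                   each = 2))),
    "zero-variance")
  expect_true(all(is.finite(tab$t)))
})
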