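test_that("per-array Z-scoring standardizes every column", {
  m <- matrix(c(1, 2, 3, 5, 7, 12), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a1", "a2")))
  st <- expression_study(m, c("case", "control"), "s")
  z <- zscore_transform(st)
  expect_equal(z$values[, "a1"], c(g1 = -1, g2 = 0, g3 = 1))
  expect_equal(colMeans(z$values), c(a1 = 0, a2 = 0), tolerance = 1e-12)
  expect_equal(apply(z$values, 2, sd), c(a1 = 1, a2 = 1), tolerance = 1e-12)

  # random matrices: mean 0 / SD 1 within 1e-9
  st2 <- make_study(n_genes = 200, seed = 4)
  z2 <- zscore_transform(st2)
  expect_true(all(abs(colMeans(z2$values)) < 1e-9))
  expect_true(all(abs(apply(z2$values, 2, sd) - 1) < 1e-9))
})

test_that("Z-scoring is invariant to per-array affine rescaling", {
  st <- make_study(n_genes = 100, seed = 8)
  z <- zscore_transform(st)
  scaled <- st
  scaled$values <- sweep(sweep(st$values, 2, runif(ncol(st$values), 0.5, 3),
                               "*"),
                         2, runif(ncol(st$values), -5, 5), "+")
  expect_equal(zscore_transform(scaled)$values, z$values, tolerance = 1e-9)
})

test_that("constant arrays are rejected by name", {
  m <- matrix(c(5, 5, 5, 1, 2, 3), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("flat", "ok")))
  st <- expression_study(m, c("case", "control"), "s")
  expect_error(zscore_transform(st), "zero variance array: flat")
})

test_that("probe collapse averages multi-probe genes and drops unmapped probes", {
  m <- matrix(c(2, 4, 9, 4, 6, 9), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("a1", "a2")))
  st <- expression_study(m, c("case", "control"), "s")
  pmap <- data.frame(probe = c("p1", "p2"), gene = c("gA", "gA"))
  expect_message(out <- collapse_probes(st, pmap), "dropped 1 unmapped")
  expect_equal(out$values["gA", ], c(a1 = 3, a2 = 5))
  expect_equal(nrow(out$values), 1)

  # single probe per gene: identity
  pmap2 <- data.frame(probe = c("p1", "p2", "p3"),
                      gene = c("g1", "g2", "g3"))
  out2 <- collapse_probes(st, pmap2)
  expect_equal(unname(out2$values[c("g1", "g2", "g3"), ]), unname(m))

  # ambiguous probe
  pmap3 <- data.frame(probe = c("p1", "p1", "p2", "p3"),
                      gene = c("gA", "gB", "gC", "gD"))
  expect_error(collapse_probes(st, pmap3), "more than one gene")
})

test_that("outlier screening flags only clearly discordant arrays", {
  # identical arrays: nothing to flag
  m <- matrix(rep(c(1, 3, 7, 2), 3), ncol = 3,
              dimnames = list(paste0("g", 1:4), paste0("a", 1:3)))
  st <- expression_study(m, c("case", "case", "control"), "s")
  expect_length(detect_outlier_arrays(st), 0)

  # 9 arrays sharing a strong gene profile + 1 independent-noise array
  withr::with_seed(21, {
    profile <- rnorm(300, 0, 2)
    vals <- vapply(1:9, function(i) profile + rnorm(300, 0, 0.5),
                   numeric(300))
    vals <- cbind(vals, rnorm(300, 0, 2))
    dimnames(vals) <- list(sprintf("g%03d", 1:300), sprintf("a%02d", 1:10))
  })
  st2 <- expression_study(vals, rep(c("case", "control"), each = 5), "s")
  expect_equal(detect_outlier_arrays(st2), "a10", ignore_attr = TRUE)

  small <- make_study(n_genes = 10, n_case = 1, n_control = 1)
  expect_warning(res <- detect_outlier_arrays(small), "fewer than 3")
  expect_length(res, 0)
})

test_that("integration concatenates standardized studies on shared genes", {
  cfg <- sim_config(n_genes = 120, seed = 2)
  sim <- simulate_collection(cfg)

  # dataset-C analogue: studies sized 13:0, 14:9, 10:0, 16:0, 7:3
  dc <- integrate_studies(sim$studies[c(2, 3, 5, 6, 7)])
  expect_equal(sum(dc$samples$group == "case"), 60)
  expect_equal(sum(dc$samples$group == "control"), 12)

  dd <- integrate_studies(sim$studies)
  expect_equal(sum(dd$samples$group == "case"), 68)
  expect_equal(sum(dd$samples$group == "control"), 16)
  expect_true(all(abs(colMeans(dd$values)) < 1e-9))
  expect_true(all(abs(apply(dd$values, 2, sd) - 1) < 1e-9))

  # single-study identity composition
  single <- integrate_studies(sim$studies[3])
  expect_equal(single$values,
               zscore_transform(sim$studies[[3]])$values)
})

test_that("integration is order-invariant and gene-monotone", {
  sim <- simulate_collection(sim_config(n_genes = 80, seed = 13))
  a <- integrate_studies(sim$studies[c(3, 4, 7)])
  b <- integrate_studies(sim$studies[c(7, 3, 4)])
  expect_equal(a$values[, colnames(b$values)], b$values)

  # restrict study 4 to a gene subset: adding it can only shrink the gene set
  st4 <- sim$studies[[4]]
  st4$values <- st4$values[1:50, ]
  two <- integrate_studies(list(sim$studies[[3]], sim$studies[[7]]))
  three <- integrate_studies(list(sim$studies[[3]], sim$studies[[7]], st4))
  expect_true(all(rownames(three$values) %in% rownames(two$values)))
  expect_equal(nrow(three$values), 50)

  disjoint <- st4
  rownames(disjoint$values) <- paste0("other_", rownames(disjoint$values))
  expect_error(integrate_studies(list(sim$studies[[3]], disjoint)),
               "shared by all studies")
})
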