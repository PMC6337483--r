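test_that("simulated collections honour the configured study sizes and truth", {
  cfg <- sim_config(n_genes = 200, seed = 11)
  sim <- simulate_collection(cfg)
  expect_length(sim$studies, 7)
  n_case <- sum(vapply(sim$studies, function(s) sum(s$groups == "case"),
                       numeric(1)))
  n_control <- sum(vapply(sim$studies, function(s) sum(s$groups == "control"),
                          numeric(1)))
  expect_equal(n_case, 68)
  expect_equal(n_control, 16)
  expect_length(sim$truth$deg_genes, round(0.05 * 200))
  expect_true(all(sim$truth$deg_genes %in% sim$truth$universe))
  # signs split 50/50
  signs <- sign(sim$truth$effect[sim$truth$deg_genes])
  expect_equal(sum(signs > 0), 5)

  null_sim <- simulate_collection(sim_config(n_genes = 200, frac_deg = 0,
                                             seed = 11))
  expect_length(null_sim$truth$deg_genes, 0)
})

test_that("simulation is deterministic and per-study streams are stable", {
  cfg <- sim_config(n_genes = 100, seed = 42)
  a <- simulate_collection(cfg)
  b <- simulate_collection(cfg)
  expect_identical(a, b)

  # dropping the last study leaves earlier studies' matrices untouched
  shorter <- sim_config(n_genes = 100,
                        study_sizes = list(c(4, 1), c(13, 0)), seed = 42)
  c2 <- simulate_collection(shorter)
  expect_identical(c2$studies[[1]]$values, a$studies[[1]]$values)
  expect_identical(c2$studies[[2]]$values, a$studies[[2]]$values)
})

test_that("invalid simulation configs fail naming the offending field", {
  expect_error(sim_config(n_genes = 1), "n_genes")
  expect_error(sim_config(frac_deg = 1.2), "frac_deg")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(study_sizes = list(c(-1, 2))), "study_sizes")
  expect_error(sim_config(conf_range = c(0.5, 0.2)), "conf_range")
})

test_that("gene-set fixtures carry the planted immune enrichment", {
  cfg <- sim_config(n_genes = 300, frac_deg = 0.1, gene_set_size = 10,
                    immune_enrichment = 1, seed = 5)
  sim <- simulate_collection(cfg)
  sets <- simulate_genesets(sim$truth, cfg)
  immune <- sets[["immune system process (synthetic)"]]
  expect_length(immune, 10)
  expect_true(all(immune %in% sim$truth$deg_genes))

  # fraction 0: membership independent of truth; the mean DEG fraction over
  # seeds matches the binomial expectation |deg| / n_genes
  fracs <- vapply(1:30, function(s) {
    cfg0 <- sim_config(n_genes = 300, frac_deg = 0.1, gene_set_size = 30,
                       immune_enrichment = 0, seed = s)
    sim0 <- simulate_collection(cfg0)
    im <- simulate_genesets(sim0$truth, cfg0)[["immune system process (synthetic)"]]
    mean(im %in% sim0$truth$deg_genes)
  }, numeric(1))
  expect_equal(mean(fracs), 0.1, tolerance = 0.35)

  # GMT round trip
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back[], sets[])
  expect_identical(attr(back, "descriptions"), attr(sets, "descriptions"))
})

test_that("network fixtures plant exact hub degrees and honour edge counts", {
  cfg <- sim_config(n_genes = 200, seed = 3, n_edges = 100,
                    hub_genes = "g00001", hub_degree = 20)
  sim <- simulate_collection(cfg)
  net <- simulate_network(sim$truth, cfg)
  expect_equal(nrow(net), 100)
  expect_equal(sum(net$gene_a == "g00001" | net$gene_b == "g00001"), 20)

  empty_cfg <- sim_config(n_genes = 50, seed = 3, n_edges = 0)
  empty_net <- simulate_network(simulate_collection(empty_cfg)$truth, empty_cfg)
  expect_equal(nrow(empty_net), 0)

  low_cfg <- sim_config(n_genes = 50, seed = 3, n_edges = 30,
                        conf_range = c(0, 0.6))
  low <- simulate_network(simulate_collection(low_cfg)$truth, low_cfg)
  expect_equal(nrow(filter_edges(low, 0.7)), 0)
})

test_that("truth scoring follows the sensitivity/FDR conventions", {
  truth <- simulate_collection(sim_config(n_genes = 100, frac_deg = 0.04,
                                          seed = 9))$truth
  degs <- truth$deg_genes  # 4 genes
  expect_equal(evaluate_against_truth(degs, truth),
               list(sensitivity = 1, fdr = 0))
  other <- setdiff(truth$universe, degs)[1:3]
  expect_equal(evaluate_against_truth(other, truth),
               list(sensitivity = 0, fdr = 1))
  called <- c(degs[1:2], other[1])
  ev <- evaluate_against_truth(called, truth)
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$fdr, 1 / 3)
  expect_error(evaluate_against_truth("not_a_gene", truth), "universe")

  empty_truth <- simulate_collection(sim_config(n_genes = 100, frac_deg = 0,
                                                seed = 9))$truth
  expect_equal(evaluate_against_truth(character(0), empty_truth)$sensitivity, 1)
  expect_true(is.na(evaluate_against_truth(other[1], empty_truth)$sensitivity))
  expect_equal(evaluate_against_truth(character(0), empty_truth)$fdr, 0)
})
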