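test_that("normalization rescales each dataset to the target and pools by mean", {
  profiles <- dplyr::bind_rows(
    tibble::tibble(dataset_id = "d1", gene_id = c("g1", "g2", "g3"),
                   intensity = c(1000, 400, 10)),
    tibble::tibble(dataset_id = "d2", gene_id = c("g1", "g2", "g4"),
                   intensity = c(2000, 1200, 50)))
  pooled <- normalize_and_pool(profiles)
  val <- stats::setNames(pooled$intensity, pooled$gene_id)
  # maxima 1000 and 2000 both rescale to 1000 before pooling
  expect_equal(unname(val["g1"]), 1000)
  # g2: 400 stays 400 in d1; 1200 -> 600 in d2; mean 500
  expect_equal(unname(val["g2"]), 500)
  # genes measured once pass through rescaled
  expect_equal(unname(val["g3"]), 10)
  expect_equal(unname(val["g4"]), 25)

  # single dataset: proportional with max = target
  one <- normalize_and_pool(
    tibble::tibble(dataset_id = "d", gene_id = c("a", "b"),
                   intensity = c(5, 20)), target_scale = 1000)
  expect_equal(sort(one$intensity), c(250, 1000))

  expect_error(normalize_and_pool(tibble::tibble(
    dataset_id = character(), gene_id = character(), intensity = numeric())),
    "no expression data")
  expect_error(normalize_and_pool(tibble::tibble(
    dataset_id = "z", gene_id = "g", intensity = 0)), "all-zero")
})

test_that("reaction mapping applies min/max composition and coverage", {
  m <- two_pathway_model()
  m$reactions$gpr <- c("", "", "ga1 and ga2", "gb or gb2", "(gc1 and gc2) or gc3", "")
  m$genes <- tibble::tibble(id = c("ga1", "ga2", "gb", "gb2", "gc1", "gc2", "gc3"))
  pooled <- tibble::tibble(gene_id = c("ga1", "ga2", "gb", "gb2", "gc1", "gc2", "gc3"),
                           intensity = c(100, 10, 100, 10, 100, 10, 50))
  re <- map_expression_to_reactions(m, pooled)
  sc <- stats::setNames(re$score, re$reaction_id)
  expect_equal(unname(sc["PA"]), 10)      # and -> min
  expect_equal(unname(sc["PB1"]), 100)    # or -> max
  expect_equal(unname(sc["PB2"]), 50)     # (and) or -> max(min(100,10), 50)
  expect_true(is.na(sc["EX_s"]))          # no GPR -> unknown
  expect_equal(attr(re, "coverage"), 1)
})

test_that("GIMME keeps the expressed pathway and drops the silent alternative", {
  m <- two_pathway_model()
  expr <- tibble::tibble(reaction_id = c("PA", "PB1", "PB2"),
                         score = c(900, 10, 10))
  res <- gimme_extract(m, expr, gimme_config(threshold = 250,
                                             threshold_type = "absolute",
                                             growth_fraction = 0.9))
  expect_true("PA" %in% res$kept_reactions)
  expect_setequal(res$removed_reactions, c("PB1", "PB2"))
  expect_gte(fba(res$context_model)$objective_value,
             0.9 * res$parent_optimum - 1e-8)
  # the GIMME objective is zero: the high-expression route carries all flux
  expect_equal(res$inconsistency_score, 0, tolerance = 1e-8)
})

test_that("GIMME with everything above threshold is the identity with zero score", {
  m <- two_pathway_model()
  expr <- tibble::tibble(reaction_id = c("PA", "PB1", "PB2"),
                         score = c(900, 800, 700))
  res <- gimme_extract(m, expr, gimme_config(threshold = 100,
                                             threshold_type = "absolute"))
  expect_setequal(res$kept_reactions, m$reactions$id)
  expect_equal(res$inconsistency_score, 0)
})

test_that("core reactions below threshold are forced into the context model", {
  m <- two_pathway_model()
  expr <- tibble::tibble(reaction_id = c("PA", "PB1", "PB2"),
                         score = c(900, 10, 10))
  res <- gimme_extract(m, expr,
                       gimme_config(threshold = 250, threshold_type = "absolute",
                                    core_reactions = c("PB1", "PB2")))
  expect_true(all(c("PB1", "PB2") %in% res$kept_reactions))
})

test_that("GIMME errors when the growth requirement is unattainable", {
  m <- two_pathway_model()
  m <- set_bounds(m, "DM_p", upper = 0)   # no product, no growth
  expr <- tibble::tibble(reaction_id = "PA", score = 5)
  m2 <- two_pathway_model()
  m2$reactions$lower_bound[m2$reactions$id == "DM_p"] <- 9  # force high growth
  m2 <- set_bounds(m2, "EX_s", lower = -5)                  # but starve it
  expect_error(gimme_extract(m2, expr, gimme_config()), "infeasible|lower fraction")
})

test_that("kept sets are nested as the threshold drops", {
  m <- two_pathway_model()
  expr <- tibble::tibble(reaction_id = c("PA", "PB1", "PB2"),
                         score = c(900, 10, 10))
  kept <- lapply(c(500, 250, 5), function(thr) {
    gimme_extract(m, expr, gimme_config(threshold = thr,
                                        threshold_type = "absolute"))$kept_reactions
  })
  expect_true(all(kept[[1]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[3]]))
})

test_that("growth retention holds on randomized toy models", {
  fracs <- c(0.5, 0.7, 0.9)
  for (seed in 1:12) {
    m <- random_toy_model(seed)
    withr::with_seed(1000 + seed, {
      scores <- tibble::tibble(
        reaction_id = m$reactions$id,
        score = stats::runif(nrow(m$reactions), 0, 1000))
      core <- sample(m$reactions$id, sample(0:2, 1))
      frac <- sample(fracs, 1)
    })
    res <- gimme_extract(m, scores,
                         gimme_config(growth_fraction = frac,
                                      core_reactions = core))
    expect_gte(fba(res$context_model)$objective_value,
               frac * res$parent_optimum - 1e-6)
    expect_true(all(core %in% res$kept_reactions))
  }
})

test_that("pruning removes dangling reactions, keeps consistent chains, idempotent", {
  ch <- chain_model()
  expect_identical(sort(prune_model(ch)$reactions$id), sort(ch$reactions$id))

  # dangling dead-end: consumes b into a metabolite with no outlet
  m <- ch
  m$metabolites <- dplyr::bind_rows(
    m$metabolites, tibble::tibble(id = "x_c", name = "x", formula = "",
                                  charge = NA_integer_, compartment = "c"))
  m$reactions <- dplyr::bind_rows(
    m$reactions, tibble::tibble(id = "DANGLE", name = "DANGLE",
                                lower_bound = 0, upper_bound = 10,
                                subsystem = "", gpr = "", is_exchange = FALSE))
  m$stoichiometry <- dplyr::bind_rows(
    m$stoichiometry, tibble::tibble(reaction_id = "DANGLE",
                                    metabolite_id = c("b_c", "x_c"),
                                    coefficient = c(-1, 1)))
  validate_metabolic_model(m)
  pruned <- prune_model(m)
  expect_false("DANGLE" %in% pruned$reactions$id)
  expect_false("x_c" %in% pruned$metabolites$id)

  p2 <- prune_model(pruned)
  expect_identical(sort(p2$reactions$id), sort(pruned$reactions$id))
})

test_that("every reaction surviving pruning can carry flux at the tolerance", {
  m <- core_fixture()
  spec <- lineage_spec("expansion", seed = 11L)
  pooled <- normalize_and_pool(simulate_expression(m, spec, n_datasets = 2))
  res <- extract_context_model(
    m, pooled, gimme_config(core_reactions = c("BIOMASS", "DM_biomass", "DM_atp")))
  ctx <- res$context_model
  fv <- fva(ctx, fraction = 0)
  expect_true(all(pmax(abs(fv$min_flux), abs(fv$max_flux)) >= 1e-6))
})

test_that("suppressed subsystems are excluded while core survives (planted recovery)", {
  m <- core_fixture()
  core <- c("BIOMASS", "DM_biomass", "DM_atp")
  spec <- lineage_spec("expansion", seed = 11L)
  pooled <- normalize_and_pool(simulate_expression(m, spec, n_datasets = 2))
  res <- extract_context_model(m, pooled, gimme_config(core_reactions = core))
  suppressed <- m$reactions$id[m$reactions$subsystem %in%
    c("TCA cycle", "Oxidative phosphorylation", "Fatty acid oxidation")]
  excluded <- mean(!suppressed %in% res$kept_reactions)
  expect_gte(excluded, 0.9)
  expect_true(all(core %in% res$kept_reactions))
  expect_gte(fba(res$context_model)$objective_value,
             0.9 * res$parent_optimum - 1e-6)
})

test_that("a blocked core reaction is reconnected through removed reactions", {
  # chain s -> m1 -> p; core reaction CORE consumes p but its supplier
  # chain is silent, so reconnection must re-add the supplier
  mets <- tibble::tibble(id = c("s_e", "s_c", "m1_c", "p_c"),
                         compartment = c("e", "c", "c", "c"),
                         formula = "", charge = NA_integer_)
  rxns <- tibble::tibble(
    id = c("EX_s", "St", "A1", "A2", "CORE", "DM_s"),
    lower_bound = c(-10, 0, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000, 1000))
  st <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "EX_s", metabolite_id = "s_e", coefficient = -1),
    tibble::tibble(reaction_id = "St", metabolite_id = c("s_e", "s_c"),
                   coefficient = c(-1, 1)),
    tibble::tibble(reaction_id = "A1", metabolite_id = c("s_c", "m1_c"),
                   coefficient = c(-1, 1)),
    tibble::tibble(reaction_id = "A2", metabolite_id = c("m1_c", "p_c"),
                   coefficient = c(-1, 1)),
    tibble::tibble(reaction_id = "CORE", metabolite_id = "p_c", coefficient = -1),
    tibble::tibble(reaction_id = "DM_s", metabolite_id = "s_c", coefficient = -1))
  m <- metabolic_model(mets, rxns, st, objective_id = "DM_s")
  expr <- tibble::tibble(reaction_id = c("A1", "A2"), score = c(1, 1))
  res <- gimme_extract(m, expr,
                       gimme_config(threshold = 100, threshold_type = "absolute",
                                    core_reactions = "CORE"))
  expect_true(all(c("A1", "A2") %in% res$forced_core_added))
  expect_true("CORE" %in% res$context_model$reactions$id)
  fv <- fva(res$context_model, fraction = 0, reactions = "CORE")
  expect_gte(fv$max_flux, 1e-6)
})
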