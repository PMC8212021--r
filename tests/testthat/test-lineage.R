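test_that("merging identical models is the identity; disjoint models union", {
  ch <- chain_model()
  mm <- build_merged_model(ch, ch)
  expect_setequal(mm$reactions$id, ch$reactions$id)
  expect_equal(mm$reactions$lower_bound[order(mm$reactions$id)],
               ch$reactions$lower_bound[order(ch$reactions$id)])

  # disjoint single-reaction models: target-only reaction closed to [0,0]
  m1 <- metabolic_model(
    tibble::tibble(id = "a_c", compartment = "c", formula = "", charge = NA),
    tibble::tibble(id = "DM_a", lower_bound = 0, upper_bound = 5),
    tibble::tibble(reaction_id = "DM_a", metabolite_id = "a_c",
                   coefficient = -1),
    objective_id = "DM_a", name = "m1")
  m2 <- metabolic_model(
    tibble::tibble(id = "b_c", compartment = "c", formula = "", charge = NA),
    tibble::tibble(id = "DM_b", lower_bound = 0, upper_bound = 7),
    tibble::tibble(reaction_id = "DM_b", metabolite_id = "b_c",
                   coefficient = -1),
    objective_id = "DM_b", name = "m2")
  mm2 <- build_merged_model(target = m2, initial = m1)
  expect_setequal(mm2$reactions$id, c("DM_a", "DM_b"))
  expect_equal(mm2$reactions$lower_bound[mm2$reactions$id == "DM_b"], 0)
  expect_equal(mm2$reactions$upper_bound[mm2$reactions$id == "DM_b"], 0)
  expect_equal(mm2$reactions$upper_bound[mm2$reactions$id == "DM_a"], 5)

  # conflicting stoichiometry for a shared id is an error
  m3 <- m1
  m3$stoichiometry$coefficient <- -2
  expect_error(build_merged_model(m3, m1), "conflicting stoichiometry")
})

test_that("merged reaction count equals the union on fixture variants", {
  m <- core_fixture()
  a <- remove_reactions(m, c("FACOAL", "FAOX1", "FAOX2", "FAOX3", "FAt", "EX_fa"))
  b <- remove_reactions(m, c("LDH", "LACt", "EX_lac"))
  mm <- build_merged_model(target = b, initial = a)
  expect_setequal(mm$reactions$id, union(a$reactions$id, b$reactions$id))
})

test_that("a feasible target needs no relaxation", {
  m <- chain_model(uptake = 10)
  tgt <- tibble::tibble(reaction_id = m$reactions$id,
                        target_flux = c(-1, 1, 1, 1, 1))
  r <- relax_to_target(m, tgt)
  expect_identical(r$n_relaxed, 0L)
  expect_equal(r$achieved_distance, 0, tolerance = 1e-6)
})

test_that("planted single conflicts are relaxed exactly, with magnitude 1", {
  m <- planted_conflict_model(1)
  tgt <- tibble::tibble(
    reaction_id = c("EX_a", "At", "T", "Bt", "EX_b", "Z1", "DMz1"),
    target_flux = c(-2, 2, 1, 1, 1, 1, 1))
  r <- relax_to_target(m, tgt)
  expect_identical(r$relaxed$reaction_id, "Z1")
  expect_equal(r$relaxed$magnitude, 1, tolerance = 1e-6)
  expect_equal(r$achieved_distance, 0, tolerance = 1e-5)
})

test_that("planted 1-3 conflicts match the subset-enumeration oracle", {
  for (k in 1:3) {
    m <- planted_conflict_model(3)
    # route flux through the first k closed branches only
    zflux <- c(rep(1, k), rep(0, 3 - k))
    tgt <- tibble::tibble(
      reaction_id = c("EX_a", "At", "T", "Bt", "EX_b",
                      paste0("Z", 1:3), paste0("DMz", 1:3)),
      target_flux = c(-(1 + k), 1 + k, 1, 1, 1, zflux, zflux))
    r <- relax_to_target(m, tgt)
    planted <- paste0("Z", seq_len(k))
    expect_setequal(r$relaxed$reaction_id, planted)

    # oracle: smallest subsets (<= 3) whose widening admits the target
    S <- stoich_matrix(m)
    ids <- colnames(S)
    target_full <- stats::setNames(rep(0, length(ids)), ids)
    target_full[tgt$reaction_id] <- tgt$target_flux
    admits <- function(subset) {
      lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
      j <- match(subset, ids)
      lb[j] <- -1000; ub[j] <- 1000
      all(target_full >= lb - 1e-9) && all(target_full <= ub + 1e-9) &&
        max(abs(S %*% target_full)) < 1e-9
    }
    minimal <- NULL
    for (size in 0:3) {
      subs <- utils::combn(ids, size, simplify = FALSE)
      ok <- Filter(admits, subs)
      if (length(ok)) { minimal <- ok; break }
    }
    expect_identical(length(minimal[[1]]), length(planted))
    expect_true(any(vapply(minimal, function(s) setequal(s, planted),
                           logical(1))))
  }
})

test_that("applying the relaxed bounds makes the target reachable (soundness)", {
  m <- planted_conflict_model(2)
  tgt <- tibble::tibble(
    reaction_id = c("EX_a", "At", "T", "Bt", "EX_b",
                    paste0("Z", 1:2), paste0("DMz", 1:2)),
    target_flux = c(-3, 3, 1, 1, 1, 1, 1, 1, 1))
  r <- relax_to_target(m, tgt)
  m2 <- m
  for (i in seq_len(nrow(r$relaxed))) {
    m2 <- set_bounds(m2, r$relaxed$reaction_id[i],
                     lower = r$relaxed$new_lower[i],
                     upper = r$relaxed$new_upper[i])
  }
  # minimize L1 distance to the target on the relaxed model
  S <- stoich_matrix(m2)
  n <- ncol(S)
  t_full <- stats::setNames(rep(0, n), colnames(S))
  t_full[tgt$reaction_id] <- tgt$target_flux
  Aeq <- rbind(cbind(S, matrix(0, nrow(S), 2 * n)),
               cbind(diag(n), -diag(n), diag(n)))
  beq <- c(rep(0, nrow(S)), unname(t_full))
  sol <- gemkit:::solve_lp(c(rep(0, n), rep(1, 2 * n)), Aeq = Aeq, beq = beq,
                           lb = c(m2$reactions$lower_bound, rep(0, 2 * n)),
                           ub = c(m2$reactions$upper_bound, rep(2000, 2 * n)),
                           direction = "min")
  expect_identical(sol$status, "optimal")
  expect_lte(sol$objective, r$achieved_distance + 1e-5)
})

test_that("the alpha schedule falls back when the list is too long", {
  m <- planted_conflict_model(3)
  tgt <- tibble::tibble(
    reaction_id = c("EX_a", "At", "T", "Bt", "EX_b",
                    paste0("Z", 1:3), paste0("DMz", 1:3)),
    target_flux = c(-4, 4, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  cfg <- relaxation_config(max_list_length = 2)
  r <- relax_to_target(m, tgt, cfg)
  # three genuine conflicts: every alpha relaxes 3 > 2, so the result
  # reports the last fallback alpha tried
  expect_identical(r$n_relaxed, 3L)
  expect_equal(r$alpha_used, 0.9)
})

test_that("decreasing alpha never grows the relaxed set", {
  m <- planted_conflict_model(2)
  tgt <- tibble::tibble(
    reaction_id = c("EX_a", "At", "T", "Bt", "EX_b",
                    paste0("Z", 1:2), paste0("DMz", 1:2)),
    target_flux = c(-3, 3, 1, 1, 1, 1, 1, 1, 1))
  sizes <- vapply(c(0.99, 0.9, 0.6, 0.3), function(al) {
    relax_to_target(m, tgt, relaxation_config(alpha = al))$n_relaxed
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("relaxed reactions are classified by role and direction", {
  m <- core_fixture()
  rel <- tibble::tibble(
    reaction_id = c("EX_lac", "LACt", "PGI", "DM_atp"),
    old_lower = c(0, 0, -5, 0), old_upper = c(0, 0, 0, 10),
    new_lower = c(-3, 0, 0, 0), new_upper = c(0, 4, 5, 20),
    magnitude = c(3, 4, 5, 10))
  fake <- structure(list(relaxed = rel), class = "relaxation_result")
  cl <- classify_relaxed(fake, m)
  get <- function(rid, col) cl[[col]][cl$reaction_id == rid]
  expect_identical(get("EX_lac", "class"), "exchange/demand")
  expect_identical(get("LACt", "class"), "transport")
  expect_identical(get("PGI", "class"), "internal")
  expect_identical(get("DM_atp", "class"), "exchange/demand")
  expect_identical(get("EX_lac", "direction"), "activate")
  expect_identical(get("LACt", "direction"), "activate")
  # [-5, 0] widened to [0(-eps), 5]: a new flux sign opens up
  expect_identical(get("PGI", "direction"), "reverse")
  expect_identical(get("DM_atp", "direction"), "amplify")
})

test_that("the lineage switch recovers the target-exclusive reactions", {
  m <- core_fixture()
  core <- c("BIOMASS", "DM_biomass", "DM_atp")
  specs <- list(expansion = lineage_spec("expansion", seed = 11L),
                osteogenic = lineage_spec("osteogenic", seed = 22L))
  ctx <- lapply(specs, function(sp) {
    pooled <- normalize_and_pool(simulate_expression(m, sp, n_datasets = 2))
    extract_context_model(m, pooled, gimme_config(core_reactions = core))$context_model
  })
  smp <- sample_flux_space(ctx$osteogenic,
                           sampling_config(n_samples = 300, thinning = 5,
                                           seed = 102))
  merged <- build_merged_model(target = ctx$osteogenic,
                               initial = ctx$expansion)
  r <- relax_to_target(merged, target_state(smp))
  osteo_only <- setdiff(ctx$osteogenic$reactions$id, ctx$expansion$reactions$id)
  tgt <- target_state(smp)
  expected <- intersect(osteo_only,
                        tgt$reaction_id[abs(tgt$target_flux) > 1e-3])
  expect_true(all(expected %in% r$relaxed$reaction_id))
  expect_lt(r$achieved_distance, 1e-5)
})
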