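# Uniform sampling of the steady-state flux polytope and the
# cross-model comparison statistics.

#' Sampling configuration
#'
#' @param n_samples Number of samples to record (default 1000).
#' @param warmup Discarded initial chain steps (default `10 * dim` of
#'   the flux polytope, resolved at run time when `NULL`).
#' @param thinning Chain steps between recorded samples (default 100).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param biomass_fraction_window Two numbers `(low, high)` in `[0, 1]`:
#'   biomass flux is confined to `[low, high]` times its optimum
#'   (default `c(0.5, 1)`).
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(n_samples = 1000L, warmup = NULL, thinning = 100L,
                            seed = 1L, biomass_fraction_window = c(0.5, 1)) {
  w <- biomass_fraction_window
  stopifnot(n_samples >= 1, length(w) == 2, w[1] >= 0, w[2] >= w[1], w[2] <= 1,
            thinning >= 1)
  structure(list(n_samples = as.integer(n_samples), warmup = warmup,
                 thinning = as.integer(thinning), seed = as.integer(seed),
                 biomass_fraction_window = w),
            class = "sampling_config")
}

#' Sample the steady-state flux polytope
#'
#' Artificial-centering hit-and-run: warmup vertices are collected by
#' maximizing and minimizing every reaction flux (the FVA vertices)
#' inside the polytope `{S v = 0, bounds, biomass in the window}`; the
#' chain then repeatedly steps along directions from a stored point to
#' the running center, drawing the step uniformly from the feasible
#' segment. Points are re-projected onto the null space of `S`
#' periodically to stop numerical drift.
#'
#' @param model A feasible `metabolic_model` with a positive biomass
#'   optimum.
#' @param config A [sampling_config()].
#' @return An object of class `flux_sample`: list with `reactions`
#'   (ordered ids), `samples` (`n_samples x n_reactions` matrix),
#'   `model_name` and `config`. Every row satisfies `S v = 0` within
#'   1e-6 and all bounds.
#' @export
sample_flux_space <- function(model, config = sampling_config()) {
  wt <- fba(model)
  if (wt$status != "optimal") stop("model infeasible; cannot sample", call. = FALSE)
  w <- config$biomass_fraction_window
  if (wt$objective_value <= 0 && w[1] > 0) {
    stop("biomass optimum is zero; the requested window is empty", call. = FALSE)
  }
  i_obj <- match(model$objective_id, model$reactions$id)
  model$reactions$lower_bound[i_obj] <-
    max(model$reactions$lower_bound[i_obj], w[1] * wt$objective_value)
  model$reactions$upper_bound[i_obj] <-
    min(model$reactions$upper_bound[i_obj], w[2] * wt$objective_value)
  if (model$reactions$lower_bound[i_obj] >
      model$reactions$upper_bound[i_obj] + 1e-12) {
    stop("empty sampling window", call. = FALSE)
  }

  S <- stoich_matrix(model)
  n <- ncol(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  zero <- rep(0, nrow(S))

  # warmup vertices (FVA corners)
  pts <- matrix(NA_real_, 2 * n, n)
  for (k in seq_len(n)) {
    obj <- as.numeric(seq_len(n) == k)
    lo <- solve_lp(obj, Aeq = S, beq = zero, lb = lb, ub = ub, direction = "min")
    hi <- solve_lp(obj, Aeq = S, beq = zero, lb = lb, ub = ub, direction = "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("sampling warmup LP failed for reaction ", colnames(S)[k],
           call. = FALSE)
    }
    pts[2 * k - 1, ] <- lo$x
    pts[2 * k, ] <- hi$x
  }

  # movable subspace: null space of S augmented with indicator rows for
  # variables pinned by equal bounds, so directions can neither break
  # mass balance nor carry rounding noise into fixed fluxes
  fixed <- which((ub - lb) < 1e-9)
  Saug <- S
  if (length(fixed)) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    Saug <- rbind(S, E)
  }
  sv <- svd(Saug, nu = 0, nv = n)
  keep <- c(sv$d, rep(0, n - length(sv$d))) < 1e-9
  N <- sv$v[, keep, drop = FALSE]
  dim_poly <- ncol(N)
  warmup <- config$warmup %||% (10L * max(dim_poly, 1L))

  x_ref <- pts[1, ]
  project <- function(v) x_ref + as.vector(N %*% crossprod(N, v - x_ref))
  x <- pmin(pmax(project(colMeans(pts)), lb), ub)
  center <- colMeans(pts)
  n_pts <- nrow(pts)
  out <- matrix(NA_real_, config$n_samples, n)
  colnames(out) <- colnames(S)
  total_steps <- warmup + config$n_samples * config$thinning
  recorded <- 0L
  tol <- 1e-10

  withr::with_seed(config$seed, {
    step <- 0L
    for (try_ in seq_len(10L * total_steps)) {
      d <- pts[sample.int(n_pts, 1L), ] - center
      nd <- sqrt(sum(d * d))
      if (nd < 1e-8) next
      # normalizing a small difference vector amplifies rounding error,
      # so the direction is re-projected onto the movable subspace
      d <- as.vector(N %*% crossprod(N, d / nd))
      nd <- sqrt(sum(d * d))
      if (nd < 1e-8) next
      d <- d / nd
      # feasible segment x + t d within bounds
      tmax <- Inf; tmin <- -Inf
      pos <- d > tol; neg <- d < -tol
      if (any(pos)) {
        tmax <- min(tmax, min((ub[pos] - x[pos]) / d[pos]))
        tmin <- max(tmin, max((lb[pos] - x[pos]) / d[pos]))
      }
      if (any(neg)) {
        tmax <- min(tmax, min((lb[neg] - x[neg]) / d[neg]))
        tmin <- max(tmin, max((ub[neg] - x[neg]) / d[neg]))
      }
      if (!is.finite(tmax) || !is.finite(tmin) || tmax < tmin) next
      step <- step + 1L
      t <- stats::runif(1, tmin, tmax)
      x <- x + t * d
      # running center update and point-set enrichment (ACHR)
      center <- center + (x - center) / (n_pts + step)
      if (step %% 50L == 0L) {
        x <- pmin(pmax(project(x), lb), ub)
      }
      if (step > warmup && (step - warmup) %% config$thinning == 0L) {
        recorded <- recorded + 1L
        out[recorded, ] <- x
        pts[sample.int(n_pts, 1L), ] <- x
        if (recorded >= config$n_samples) break
      }
    }
  })
  if (recorded < config$n_samples) {
    out <- out[seq_len(recorded), , drop = FALSE]
    warning("recorded only ", recorded, " samples (degenerate polytope)",
            call. = FALSE)
  }
  res <- list(reactions = colnames(S), samples = out,
              model_name = model$name, config = config,
              biomass_window = c(model$reactions$lower_bound[i_obj],
                                 model$reactions$upper_bound[i_obj]))
  class(res) <- "flux_sample"
  res
}

#' @export
print.flux_sample <- function(x, ...) {
  cat("<flux_sample> ", nrow(x$samples), " samples x ", length(x$reactions),
      " reactions from ", x$model_name, "\n", sep = "")
  invisible(x)
}

#' Tidy a flux sample into long form
#' @param x A `flux_sample`.
#' @param ... Unused.
#' @return Tibble `sample`, `reaction_id`, `flux`.
#' @method tidy flux_sample
#' @export
tidy.flux_sample <- function(x, ...) {
  tibble::tibble(sample = rep(seq_len(nrow(x$samples)), ncol(x$samples)),
                 reaction_id = rep(x$reactions, each = nrow(x$samples)),
                 flux = as.vector(x$samples))
}

#' One-row summary of a flux sample
#' @param x A `flux_sample`.
#' @param ... Unused.
#' @return Tibble with sample counts, seed and biomass window.
#' @method glance flux_sample
#' @export
glance.flux_sample <- function(x, ...) {
  tibble::tibble(model = x$model_name, n_samples = nrow(x$samples),
                 n_reactions = length(x$reactions),
                 seed = x$config$seed,
                 biomass_low = x$biomass_window[1],
                 biomass_high = x$biomass_window[2])
}

#' Comparison configuration
#'
#' @param fold_threshold Minimal fold change of interest (default 5).
#' @param t_test_cutoff Two-tailed Welch t-test p-value cutoff
#'   (default 1e-12).
#' @param epsilon Floor applied to absolute means before forming fold
#'   changes (default 1e-9); reactions with both means under the floor
#'   are "both-inactive" and never significant.
#' @return A list of class `comparison_config`.
#' @export
comparison_config <- function(fold_threshold = 5, t_test_cutoff = 1e-12,
                              epsilon = 1e-9) {
  stopifnot(fold_threshold > 1, t_test_cutoff > 0, t_test_cutoff < 1,
            epsilon > 0)
  structure(list(fold_threshold = fold_threshold,
                 t_test_cutoff = t_test_cutoff, epsilon = epsilon),
            class = "comparison_config")
}

welch_t_p <- function(ma, mb, va, vb, na, nb) {
  se2 <- va / na + vb / nb
  if (se2 <= 0) return(if (isTRUE(all.equal(ma, mb))) 1 else 0)
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  if (!is.finite(df) || df <= 0) return(1)
  2 * stats::pt(-abs(t), df)
}

#' Compare reaction flux distributions between two sampled models
#'
#' Aligns the two samples on the union of their reaction sets (a
#' reaction absent from one model contributes all-zero fluxes there),
#' then per reaction: the fold change between absolute means (floored
#' at `epsilon`, oriented larger over smaller with the direction
#' recorded), a two-tailed Welch t-test and a Wilcoxon rank-sum test.
#' A reaction is significant when the fold change reaches
#' `fold_threshold` and the t-test p-value is below `t_test_cutoff`
#' (the rank-sum p is reported alongside).
#'
#' @param a,b `flux_sample` objects.
#' @param config A [comparison_config()].
#' @return A tibble of class `flux_comparison`: `reaction_id`,
#'   `mean_a`, `mean_b`, `fold_change`, `direction`
#'   (`"up_in_a"`/`"up_in_b"`/`"none"`), `t_p`, `ranksum_p`,
#'   `both_inactive`, `absent_in` (`"a"`, `"b"` or `""`),
#'   `significant`.
#' @export
compare_reaction_fluxes <- function(a, b, config = comparison_config()) {
  stopifnot(inherits(a, "flux_sample"), inherits(b, "flux_sample"))
  na <- nrow(a$samples); nb <- nrow(b$samples)
  if (na < 2 || nb < 2) {
    stop("need at least 2 samples per model (variance undefined)",
         call. = FALSE)
  }
  ids <- union(a$reactions, b$reactions)
  col <- function(s, rid) {
    k <- match(rid, s$reactions)
    if (is.na(k)) numeric(nrow(s$samples)) else s$samples[, k]
  }
  eps <- config$epsilon
  rows <- lapply(ids, function(rid) {
    va <- col(a, rid); vb <- col(b, rid)
    ma <- mean(va); mb <- mean(vb)
    fa <- max(abs(ma), eps); fb <- max(abs(mb), eps)
    both_inactive <- abs(ma) < eps && abs(mb) < eps
    fold <- max(fa, fb) / min(fa, fb)
    direction <- if (both_inactive || fold == 1) "none"
                 else if (fa >= fb) "up_in_a" else "up_in_b"
    t_p <- welch_t_p(ma, mb, stats::var(va), stats::var(vb), na, nb)
    r_p <- tryCatch(
      suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value),
      error = function(e) NA_real_)
    if (is.na(r_p)) r_p <- 1
    tibble::tibble(reaction_id = rid, mean_a = ma, mean_b = mb,
                   fold_change = fold, direction = direction,
                   t_p = t_p, ranksum_p = r_p,
                   both_inactive = both_inactive,
                   absent_in = if (!rid %in% a$reactions) "a"
                               else if (!rid %in% b$reactions) "b" else "",
                   significant = !both_inactive &&
                     fold >= config$fold_threshold &&
                     t_p < config$t_test_cutoff)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flux_comparison", class(out))
  attr(out, "config") <- config
  attr(out, "models") <- c(a = a$model_name, b = b$model_name)
  out
}

#' Subsystem enrichment of changed reactions
#'
#' Upper-tail hypergeometric test per subsystem: the probability of
#' drawing at least the observed number of subsystem members in
#' `|changed|` draws without replacement from the universe, with
#' Benjamini-Hochberg adjustment across subsystems; subsystems with
#' adjusted p below 0.05 are flagged.
#'
#' @param changed Character vector of changed reaction ids (must be a
#'   subset of `universe`).
#' @param universe Character vector of all reaction ids considered.
#' @param grouping Named character vector or tibble
#'   (`reaction_id`, `subsystem`) mapping reactions to subsystems.
#' @return A tibble of class `enrichment_result`: `subsystem`,
#'   `enriched_set_size`, `total_set_size`, `raw_p`, `adjusted_p`,
#'   `flagged`, ordered by `raw_p`.
#' @export
flux_enrichment <- function(changed, universe, grouping) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (length(setdiff(changed, universe))) {
    stop("'changed' must be a subset of 'universe'", call. = FALSE)
  }
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(grouping$subsystem, grouping$reaction_id)
  }
  grp <- grouping[universe]
  grp[is.na(grp) | !nzchar(grp)] <- "(ungrouped)"
  N <- length(universe)
  nch <- length(changed)
  sub_tab <- table(grp)
  rows <- lapply(names(sub_tab), function(ss) {
    K <- sub_tab[[ss]]
    k <- sum(grp[match(changed, universe)] == ss)
    p <- stats::phyper(k - 1, K, N - K, nch, lower.tail = FALSE)
    tibble::tibble(subsystem = ss, enriched_set_size = k,
                   total_set_size = K, raw_p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = "BH")
  out$flagged <- out$adjusted_p < 0.05
  out <- out[order(out$raw_p), ]
  class(out) <- c("enrichment_result", class(out))
  out
}
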