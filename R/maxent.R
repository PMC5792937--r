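#' Fit a maximum-entropy species distribution model
#'
#' Finds the Gibbs distribution `P(cell) = exp(lambda . f(cell)) / Z` over the
#' background cells that maximizes the L1-penalized log-likelihood of the
#' presence sample — equivalently, the distribution of maximum entropy
#' (closest to uniform) whose expected feature values match their empirical
#' presence averages, relaxed by the penalty. The per-feature penalty is
#' `reg_multiplier * beta_class * s_j / sqrt(m)` with `s_j` the
#' presence-sample standard deviation of feature `j` (floored at 0.05 — 5%
#' of the scaled feature range — so that features constant over the presence
#' sample, which would otherwise carry no penalty at all, remain regularized)
#' and `m` the presence count.
#'
#' The penalized objective is convex; it is minimized by an active-set
#' strategy: the subgradient optimality (KKT) conditions are screened over
#' all features, the violating and non-zero features form the active set,
#' and the objective is solved on that subspace (split-variable
#' `lambda = lambda+ - lambda-` formulation under box-constrained L-BFGS,
#' which handles the L1 kink exactly); screening and subspace solves
#' alternate until no feature violates the conditions. The objective is
#' non-increasing across accepted iterations (`trace`). With a zero penalty
#' and linear features only, the fitted expected feature values equal the
#' presence means (moment matching).
#'
#' @param features a [build_features()] matrix.
#' @param presence_cells integer cell ids of the presence localities (repeats
#'   allowed); all must lie in the valid domain.
#' @param reg_multiplier global regularization multiplier (0 = no penalty).
#' @param max_iterations cap on total optimizer iterations across subspace
#'   solves (default 500).
#' @param tolerance convergence tolerance on the maximum violation of the
#'   subgradient optimality conditions (the penalized objective's gradient).
#' @param beta_table named per-class penalty constants.
#' @param lambda_cap bound on `|lambda|`; hitting it flags non-convergence
#'   (complete separation guard).
#' @return object of class `maxent_model`: feature descriptors, `lambda`,
#'   penalties, `log_z` (log-normalizer over the background), iteration
#'   count, `converged` flag, the presence feature means, and the
#'   per-sweep objective `trace`.
#' @export
fit_maxent <- function(features, presence_cells, reg_multiplier = 1,
                       max_iterations = 500, tolerance = 1e-5,
                       beta_table = c(linear = 1, quadratic = 1, product = 1,
                                      hinge = 0.5, threshold = 1,
                                      categorical = 0.25),
                       lambda_cap = 50) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!length(presence_cells)) stop("at least one presence cell is required")
  X <- features$X
  idx <- feature_rows(features, presence_cells)
  m <- length(idx)
  K <- ncol(X)
  N <- nrow(X)
  pbar <- colMeans(X[idx, , drop = FALSE])
  s <- if (m == 1) rep(0, K) else apply(X[idx, , drop = FALSE], 2, stats::sd)
  s <- pmax(s, 0.05)
  # hinge/threshold features are penalized by sample size only: sd-scaled
  # penalties vanish on the many near-constant knots and let compensating
  # pairs of adjacent knots blow up (the reference implementations do the same)
  s[features$descriptors$class %in% c("hinge", "threshold")] <- 1
  beta <- reg_multiplier * unname(beta_table[features$descriptors$class]) *
    s / sqrt(m)
  beta[is.na(beta)] <- reg_multiplier * s[is.na(beta)] / sqrt(m)

  # complete-separation guard: an unpenalized feature whose presence mean
  # sits on its background extreme has no finite optimum (the constraint
  # E_P[f] = pbar is only attained as |lambda| -> Inf)
  separated <- beta == 0 &
    (pbar >= apply(X, 2, max) - 1e-12 | pbar <= apply(X, 2, min) + 1e-12) &
    apply(X, 2, function(v) max(v) > min(v))
  if (any(separated))
    warning("complete separation on feature(s) ",
            paste(which(separated), collapse = ", "),
            "; weights capped at ", lambda_cap,
            " and model flagged non-converged")

  lambda <- numeric(K)
  objective <- function(lam) {
    eta <- drop(X %*% lam)
    -m * sum(pbar * lam) + m * lse(eta) + sum(beta * abs(lam))
  }
  trace <- objective(lambda)
  converged <- FALSE
  iters_used <- 0L

  kkt <- function(lam) {
    eta <- drop(X %*% lam)
    p <- exp(eta - lse(eta))
    g <- m * (drop(crossprod(X, p)) - pbar)
    ifelse(lam == 0, pmax(abs(g) - beta, 0), abs(g + beta * sign(lam)))
  }

  for (outer in 1:50) {
    viol <- kkt(lambda)
    if (max(viol) <= tolerance) { converged <- TRUE; break }
    if (iters_used >= max_iterations) break
    # grafting: grow the support by at most 20 worst violators per round,
    # so each subspace stays near the (sparse) final support
    support <- which(lambda != 0)
    cand <- setdiff(which(viol > tolerance), support)
    cand <- cand[order(-viol[cand])]
    active <- sort(union(support, utils::head(cand, 20)))
    Xa <- X[, active, drop = FALSE]
    ka <- length(active)
    ba <- beta[active]
    pa <- pbar[active]
    fn <- function(th) {
      la <- th[1:ka] - th[(ka + 1):(2 * ka)]
      eta <- drop(Xa %*% la)
      -m * sum(pa * la) + m * lse(eta) + sum(ba * (th[1:ka] + th[(ka + 1):(2 * ka)]))
    }
    gr <- function(th) {
      la <- th[1:ka] - th[(ka + 1):(2 * ka)]
      eta <- drop(Xa %*% la)
      p <- exp(eta - lse(eta))
      g <- m * (drop(crossprod(Xa, p)) - pa)
      c(g + ba, -g + ba)
    }
    th0 <- c(pmax(lambda[active], 0), pmax(-lambda[active], 0))
    budget <- max_iterations - iters_used
    opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                        lower = 0, upper = lambda_cap,
                        control = list(maxit = budget,
                                       pgtol = tolerance / 2, factr = 10))
    iters_used <- iters_used + unname(opt$counts[1])
    lam_new <- lambda
    lam_new[active] <- opt$par[1:ka] - opt$par[(ka + 1):(2 * ka)]
    if (objective(lam_new) <= trace[length(trace)]) {
      lambda <- lam_new
      trace <- c(trace, objective(lambda))
    } else break   # no further progress possible
  }
  obj <- objective(lambda)
  eta <- drop(X %*% lambda)
  lz <- lse(eta)
  capped <- any(abs(lambda) >= lambda_cap - 1e-8)
  if (capped && !any(separated))
    warning("weights hit the cap (possible complete separation); model flagged non-converged")
  if (capped || any(separated)) converged <- FALSE
  structure(
    list(descriptors = features$descriptors, lambda = lambda, beta = beta,
         reg_multiplier = reg_multiplier, iterations = iters_used,
         converged = converged, log_z = lz,
         presence_means = pbar, n_presences = m,
         objective = obj, trace = trace, tolerance = tolerance),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d feature(s), %d presence(s), reg = %g, %s (%d fn evals)\n",
              length(x$lambda), x$n_presences, x$reg_multiplier,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  non-zero weights: %d, log Z = %.4f\n",
              sum(x$lambda != 0), x$log_z))
  invisible(x)
}

#' Predict the raw suitability surface
#'
#' Evaluates `P(cell)` over the valid cells and normalizes to sum to 1: the
#' model's relative probability of occurrence per grid cell ("raw" output).
#'
#' @param model a [fit_maxent()] model.
#' @param features the [build_features()] matrix the model was fitted on (or
#'   one with identical descriptors).
#' @return object of class `suitability`: list with `p` (probabilities in
#'   `valid_cells` order, summing to 1), `cell_ids`, and grid geometry.
#' @export
predict_raw <- function(model, features) {
  stopifnot(inherits(model, "maxent_model"), inherits(features, "feature_matrix"))
  if (!identical(dim(model$descriptors), dim(features$descriptors)) ||
      !isTRUE(all.equal(model$descriptors, features$descriptors,
                        check.attributes = FALSE)))
    stop("feature descriptors do not match the model")
  eta <- drop(features$X %*% model$lambda)
  p <- exp(eta - lse(eta))
  structure(
    list(p = p / sum(p), cell_ids = features$cell_ids,
         nrows = features$nrows, ncols = features$ncols,
         xmin = features$xmin, ymin = features$ymin,
         cellsize = features$cellsize),
    class = "suitability")
}

#' Convert a suitability surface to a raster grid
#' @param map a [predict_raw()] surface.
#' @param name layer name.
#' @return a [raster_grid()] with `NA` outside the valid domain.
#' @export
suitability_grid <- function(map, name = "suitability") {
  v <- matrix(NA_real_, map$nrows, map$ncols)
  rc <- cell_rowcol(map$cell_ids, map$ncols)
  v[rc] <- map$p
  raster_grid(v, xmin = map$xmin, ymin = map$ymin, cellsize = map$cellsize,
              name = name)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random presence score exceeds a random background
#' score, ties counting one half — the area under the ROC curve.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (!m || !n) stop("both score lists must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Fit and score one species' SDM
#'
#' Convenience wrapper: fits the model on the species' presence cells,
#' predicts the raw surface, and computes the presence-versus-background AUC
#' (background = all valid cells of the feature matrix).
#'
#' @inheritParams fit_maxent
#' @param ... passed to [fit_maxent()].
#' @return list with `model`, `map` (suitability) and `auc`.
#' @export
fit_species_sdm <- function(features, presence_cells, ...) {
  model <- fit_maxent(features, presence_cells, ...)
  map <- predict_raw(model, features)
  pres <- map$p[feature_rows(features, presence_cells)]
  list(model = model, map = map,
       auc = compute_auc(pres, map$p))
}

#' Serialize a maxent model to a plain-text table
#'
#' Writes a metadata block (`#`-prefixed) followed by a TSV of feature
#' descriptors, penalties and weights.
#'
#' @param model a [fit_maxent()] model.
#' @param path output file.
#' @export
write_maxent_model <- function(model, path) {
  meta <- c(sprintf("# phyloniche maxent model"),
            sprintf("# n_presences\t%d", model$n_presences),
            sprintf("# reg_multiplier\t%g", model$reg_multiplier),
            sprintf("# iterations\t%d", model$iterations),
            sprintf("# converged\t%s", model$converged),
            sprintf("# log_z\t%.12g", model$log_z))
  tab <- cbind(model$descriptors,
               beta = model$beta, lambda = model$lambda)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
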