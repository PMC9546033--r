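#' @title Presence-background maximum-entropy model
#' @description The modelling core: an L1-regularized maximum-entropy
#'   (MaxEnt) model over a finite set of presence and background points,
#'   restricted to linear and quadratic features, with cloglog output and
#'   a presence/background-only AICc.  The fitted distribution is
#'   normalized over the training points (presences plus background)
#'   rather than over all raster cells, which makes fitting and AICc
#'   mutually consistent and reflects the actually sampled environment.
#' @name maxent-core
NULL

# ---- feature expansion -----------------------------------------------------

#' Build a linear/quadratic feature map from training data
#'
#' Each variable is min-max scaled to `[0, 1]` on the training points;
#' the quadratic feature is the square of the scaled value.  Scaling
#' bounds are stored so projections reuse them; out-of-range values are
#' clipped when clamping is on and extrapolate linearly otherwise.
#' Zero-variance variables are excluded with a warning.
#'
#' @param data data.frame holding the raw predictor columns (training
#'   presences plus background).
#' @param vars variable names to expand.
#' @param classes subset of `c("linear", "quadratic")`.
#' @return object of class `feature_map`.
#' @export
feature_map <- function(data, vars,
                        classes = c("linear", "quadratic")) {
  stopifnot(length(classes) >= 1,
            all(classes %in% c("linear", "quadratic")))
  lo <- vapply(vars, function(v) min(data[[v]]), 0)
  hi <- vapply(vars, function(v) max(data[[v]]), 0)
  bad <- !is.finite(lo) | !is.finite(hi) | hi <= lo
  if (any(bad)) {
    warning("excluding zero-variance variable(s): ",
            paste(vars[bad], collapse = ", "))
    vars <- vars[!bad]; lo <- lo[!bad]; hi <- hi[!bad]
  }
  structure(list(vars = vars, classes = classes, lo = lo, hi = hi),
            class = "feature_map")
}

feature_names <- function(fmap) {
  out <- character(0)
  if ("linear" %in% fmap$classes) out <- c(out, paste0(fmap$vars, ".l"))
  if ("quadratic" %in% fmap$classes) out <- c(out, paste0(fmap$vars, ".q"))
  out
}

# features of one variable (column indices in the design matrix)
features_of <- function(fmap, var) {
  which(sub("\\.[lq]$", "", feature_names(fmap)) == var)
}

#' Expand raw predictor values into the design matrix
#'
#' @param fmap a [feature_map()].
#' @param data data.frame with the raw predictor columns.
#' @param clamp clip scaled values into `[0, 1]` (TRUE) or extrapolate
#'   beyond the training range (FALSE).
#' @return numeric matrix, one column per feature.
#' @export
build_features <- function(fmap, data, clamp = FALSE) {
  if (length(fmap$vars) == 0)
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  scaled <- vapply(seq_along(fmap$vars), function(i) {
    s <- (data[[fmap$vars[i]]] - fmap$lo[i]) / (fmap$hi[i] - fmap$lo[i])
    if (clamp) pmin(1, pmax(0, s)) else s
  }, numeric(nrow(data)))
  scaled <- matrix(scaled, nrow = nrow(data))
  out <- NULL
  if ("linear" %in% fmap$classes) out <- scaled
  if ("quadratic" %in% fmap$classes) out <- cbind(out, scaled^2)
  colnames(out) <- feature_names(fmap)
  out
}

# ---- optimizer -------------------------------------------------------------

soft_threshold <- function(x, t) sign(x) * pmax(0, abs(x) - t)

# Minimize  h(lambda) + sum(beta * |lambda|)  with
# h = log sum_S exp(F lambda) - mean_P (F lambda)  by FISTA with
# backtracking and monotone restart.  Soft-thresholding yields exact
# zeros, which is what the Lambda = 0 variable-removal rule keys on.
maxent_fit_core <- function(F, p_idx, beta, iter_cap = 500, tol = 1e-8,
                            lambda0 = NULL) {
  N <- nrow(F); K <- ncol(F)
  if (K == 0L) {
    return(list(lambda = numeric(0), logZ = log(N), H = log(N),
                objective = log(N), iters = 0L, converged = TRUE))
  }
  b <- colMeans(F[p_idx, , drop = FALSE])
  smooth_at <- function(l) {
    eta <- drop(F %*% l)
    mx <- max(eta)
    lse <- mx + log(sum(exp(eta - mx)))
    list(h = lse - sum(l * b), q = exp(eta - lse), lse = lse)
  }
  lam <- if (is.null(lambda0)) numeric(K) else lambda0
  st <- smooth_at(lam)
  o <- st$h + sum(beta * abs(lam))
  if (!is.finite(o)) stop("non-finite maxent objective")
  yv <- lam; tmom <- 1; L <- max(1, sum(apply(F, 2, stats::var)) / 4)
  converged <- FALSE; iters <- 0L
  prox_step <- function(y, sy) {
    g <- drop(crossprod(F, sy$q)) - b
    repeat {
      lnew <- soft_threshold(y - g / L, beta / L)
      snew <- smooth_at(lnew)
      dd <- lnew - y
      if (snew$h <= sy$h + sum(g * dd) + L / 2 * sum(dd^2) + 1e-12 ||
          L > 1e14) break
      L <<- L * 2
    }
    list(l = lnew, s = snew)
  }
  for (it in seq_len(iter_cap)) {
    iters <- it
    ps <- prox_step(yv, smooth_at(yv))
    onew <- ps$s$h + sum(beta * abs(ps$l))
    if (onew > o + 1e-12) {          # momentum overshoot: restart
      yv <- lam; tmom <- 1
      ps <- prox_step(lam, st)
      onew <- ps$s$h + sum(beta * abs(ps$l))
    }
    if (!is.finite(onew)) stop("non-finite maxent objective")
    done <- abs(o - onew) < tol * (1 + abs(onew))
    tnew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    yv <- ps$l + ((tmom - 1) / tnew) * (ps$l - lam)
    lam <- ps$l; st <- ps$s; o <- min(o, onew); tmom <- tnew
    L <- L * 0.9
    if (done && it > 1) { converged <- TRUE; break }
  }
  q <- st$q
  H <- -sum(q * log(pmax(q, 1e-300)))
  list(lambda = stats::setNames(lam, colnames(F)), logZ = st$lse,
       H = H, objective = o, iters = iters, converged = converged)
}

# ---- fitting front end -----------------------------------------------------

#' Fit a presence-background maximum-entropy model
#'
#' Maximizes the penalized presence log-likelihood
#' `mean_P(lambda . f) - ln Z(lambda) - sum_j beta_j |lambda_j|` with
#' `Z(lambda) = sum_{x in S} exp(lambda . f(x))` over the training point
#' set S = presences + background, and per-feature penalties
#' `beta_j = rm * s_j / sqrt(m)` (`s_j` = feature SD over S, `m` =
#' presence count).  The objective is concave, so the optimizer's
#' contract is the global optimum.  The normalization constant `Z` and
#' the entropy `H` of the fitted distribution over S are stored for raw
#' and cloglog prediction.
#'
#' @param swd an `swd` table (see [extract_swd()]) with a `class` column;
#'   alternatively any data.frame with `class` plus predictor columns.
#' @param vars predictor variables to use (default: all SWD predictors).
#' @param classes feature classes, subset of `c("linear", "quadratic")`.
#' @param rm regularization multiplier (default 1).
#' @param iter_cap optimizer iteration limit (default 500).
#' @param tol convergence tolerance on the objective (default 1e-8).
#' @param clamp clip projected features to the training range?  Off by
#'   default, matching projection into non-analogue climates where the
#'   response is left to extrapolate.
#' @param lambda_init optional warm-start coefficient vector.
#' @return object of class `maxent` with components `lambda`, `beta`,
#'   `feature_map`, `rm`, `iter_cap`, `Z`, `H`, `k` (nonzero
#'   coefficients), `n_presence`, `n_background`, `loglik`, `objective`,
#'   `converged`, `iters`.
#' @seealso [predict.maxent()], [aicc()], [tune_maxent()],
#'   [permutation_importance()]
#' @examples
#' swd <- data.frame(class = rep(c("presence", "background"), c(30, 200)),
#'                   bio1 = c(rnorm(30, -2), rnorm(200, 0, 2)))
#' m <- maxent(swd, vars = "bio1", rm = 0.5)
#' coef(m)
#' @export
maxent <- function(swd, vars = NULL,
                   classes = c("linear", "quadratic"), rm = 1,
                   iter_cap = 500, tol = 1e-8, clamp = FALSE,
                   lambda_init = NULL) {
  vars <- vars %||% swd_predictors(swd)
  p_idx <- which(swd$class == "presence")
  m <- length(p_idx)
  if (m < 2) stop("need at least 2 presence points")
  if (!any(swd$class == "background"))
    stop("need at least 1 background point")
  fmap <- feature_map(swd, vars, classes)
  F <- build_features(fmap, swd, clamp = TRUE)  # training values are in range
  s_j <- apply(F, 2, stats::sd)
  beta <- rm * s_j / sqrt(m)
  init <- NULL
  if (!is.null(lambda_init)) {
    init <- stats::setNames(numeric(ncol(F)), colnames(F))
    common <- intersect(names(lambda_init), colnames(F))
    init[common] <- lambda_init[common]
  }
  fit <- maxent_fit_core(F, p_idx, beta, iter_cap = iter_cap, tol = tol,
                         lambda0 = init)
  eta_p <- if (length(fit$lambda))
    drop(F[p_idx, , drop = FALSE] %*% fit$lambda) else numeric(m)
  structure(list(call = match.call(), feature_map = fmap,
                 lambda = fit$lambda, beta = beta, rm = rm,
                 iter_cap = iter_cap, tol = tol, clamp = clamp,
                 Z = exp(fit$logZ), logZ = fit$logZ, H = fit$H,
                 k = sum(fit$lambda != 0),
                 n_presence = m,
                 n_background = sum(swd$class == "background"),
                 loglik = sum(eta_p - fit$logZ),
                 objective = fit$objective, iters = fit$iters,
                 converged = fit$converged,
                 species = if (!is.null(swd$species) && nrow(swd))
                   swd$species[1] else NA_character_),
            class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf(paste0("maxent model (%s): %d/%d features nonzero over %d",
                     " variables\n  rm = %g, classes = %s, m = %d",
                     " presences, %d background\n",
                     "  lnZ = %.4f, H = %.4f, presence lnL = %.2f%s\n"),
              x$species, x$k, length(x$lambda),
              length(x$feature_map$vars), x$rm,
              paste(x$feature_map$classes, collapse = "+"),
              x$n_presence, x$n_background, x$logZ, x$H, x$loglik,
              if (x$converged) "" else "  [iteration cap reached]"))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambda

#' @export
summary.maxent <- function(object, ...) {
  fm <- object$feature_map
  tab <- data.frame(feature = names(object$lambda),
                    variable = sub("\\.[lq]$", "", names(object$lambda)),
                    lambda = unname(object$lambda),
                    beta = unname(object$beta))
  structure(list(model = object, coefficients = tab,
                 retained = unique(tab$variable[tab$lambda != 0])),
            class = "summary.maxent")
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat("\nRetained variables:",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Predict suitability from a fitted maxent model
#'
#' `type = "raw"` returns the relative occurrence rate
#' `q(x) = exp(lambda . f(x)) / Z` (summing to 1 over the training
#' points); `"cloglog"` the suitability `1 - exp(-e^H * q(x))` in (0, 1);
#' `"link"` the linear predictor `lambda . f(x)`.
#'
#' @param object a fitted [maxent()] model.
#' @param newdata data.frame with the model's raw predictor columns.
#' @param type one of `"cloglog"`, `"raw"`, `"link"`.
#' @param clamp override the model's clamping setting.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("cloglog", "raw", "link"),
                           clamp = object$clamp, ...) {
  type <- match.arg(type)
  F <- build_features(object$feature_map, newdata, clamp = clamp)
  eta <- if (length(object$lambda)) drop(F %*% object$lambda)
  else numeric(nrow(F))
  switch(type,
         link = eta,
         raw = exp(eta - object$logZ),
         cloglog = 1 - exp(-exp(object$H) * exp(eta - object$logZ)))
}

#' Response curves of a fitted maxent model
#'
#' Plots cloglog suitability against each raw variable over its training
#' range, holding the other variables at their training midpoint.
#'
#' @param x a fitted [maxent()] model.
#' @param vars variables to plot (default: retained variables).
#' @param n curve resolution.
#' @param ... passed to [graphics::plot()].
#' @export
plot.maxent <- function(x, vars = NULL, n = 100, ...) {
  fm <- x$feature_map
  vars <- vars %||% unique(sub("\\.[lq]$", "",
                               names(x$lambda)[x$lambda != 0]))
  if (!length(vars)) vars <- fm$vars[1]
  mid <- stats::setNames((fm$lo + fm$hi) / 2, fm$vars)
  op <- graphics::par(mfrow = c(ceiling(length(vars) / 2),
                                min(2, length(vars))))
  on.exit(graphics::par(op))
  for (v in vars) {
    grid_v <- seq(fm$lo[v], fm$hi[v], length.out = n)
    nd <- as.data.frame(lapply(mid, rep, n))
    nd[[v]] <- grid_v
    graphics::plot(grid_v, predict(x, nd, type = "cloglog"),
                   type = "l", xlab = v, ylab = "suitability",
                   ylim = c(0, 1), ...)
  }
  invisible(x)
}

# ---- AICc ------------------------------------------------------------------

#' Presence/background-only AICc of a maxent model
#'
#' The presence log-likelihood `sum_P ln q(x)` uses `q` normalized over
#' the presence + background points of the supplied table (not over all
#' raster cells); `k` counts nonzero feature coefficients;
#' `AICc = 2k - 2 lnL + 2k(k+1)/(m - k - 1)` with `m` the presence
#' count.  Returns `NA` (invalid) when `m - k - 1 <= 0`.
#'
#' @param model a fitted [maxent()] model.
#' @param swd the training `swd` table.
#' @return AICc value, or `NA_real_` when invalid.
#' @export
aicc <- function(model, swd) {
  m <- sum(swd$class == "presence")
  k <- model$k
  if (m - k - 1 <= 0) return(NA_real_)
  eta <- predict(model, swd, type = "link", clamp = TRUE)
  lse <- max(eta) + log(sum(exp(eta - max(eta))))
  lnL <- sum(eta[swd$class == "presence"] - lse)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (m - k - 1)
}

# ---- permutation importance ------------------------------------------------

#' Permutation importance of model variables
#'
#' For each variable, its raw values are permuted jointly across all
#' points (both its linear and quadratic features rebuilt) and the drop
#' in training AUC (presences vs background on the model score) is
#' averaged over `n_perm` permutations.  Negative drops are clipped to 0
#' and the result normalized to percentages summing to 100.
#'
#' @param model a fitted [maxent()] model.
#' @param swd the training `swd` table.
#' @param n_perm number of permutations (default 10).
#' @param seed integer RNG seed.
#' @return named numeric vector of percentages.
#' @export
permutation_importance <- function(model, swd, n_perm = 10, seed = 1) {
  fm <- model$feature_map
  vars <- fm$vars
  if (length(vars) == 0) stop("model has no variables")
  F <- build_features(fm, swd, clamp = TRUE)
  eta <- if (length(model$lambda)) drop(F %*% model$lambda)
  else numeric(nrow(F))
  is_p <- swd$class == "presence"
  base <- auc(eta[is_p], eta[!is_p])
  drops <- with_seed(seed, vapply(vars, function(v) {
    cols <- features_of(fm, v)
    if (all(model$lambda[cols] == 0)) return(0)
    mean(vapply(seq_len(n_perm), function(i) {
      pv <- swd[[v]][sample.int(nrow(swd))]
      # rebuild only this variable's columns with the original bounds
      sc <- (pv - fm$lo[v]) / (fm$hi[v] - fm$lo[v])
      sc <- pmin(1, pmax(0, sc))
      reb <- cbind(l = sc, q = sc^2)
      etap <- eta
      for (jj in seq_along(cols)) {
        cl <- if (grepl("\\.l$", colnames(F)[cols[jj]])) "l" else "q"
        etap <- etap + (reb[, cl] - F[, cols[jj]]) *
          model$lambda[cols[jj]]
      }
      base - auc(etap[is_p], etap[!is_p])
    }, 0))
  }, 0))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    if (length(vars) == 1) return(stats::setNames(100, vars))
    return(stats::setNames(rep(0, length(vars)), vars))
  }
  100 * drops / sum(drops)
}

# ---- greedy tuning ---------------------------------------------------------

#' Tune a maxent model by AICc
#'
#' Three-step procedure: (A) fit the full linear+quadratic model at each
#' regularization multiplier in `rm_grid` and keep the minimum-AICc one;
#' (B) remove every variable whose features all have `lambda = 0`;
#' (C) greedy loop over single moves — change the regularization
#' multiplier, toggle linear-only vs linear+quadratic features, change
#' the iteration cap, or drop the variable with the lowest permutation
#' importance — accepting the move with the largest AICc decrease until
#' none decreases it.  The trace records every accepted step.
#'
#' @param swd_train training `swd` table.
#' @param vars candidate predictor variables (default: all).
#' @param rm_grid regularization multiplier grid (default
#'   `c(0.25, 0.5, 1, 2, 4)`).
#' @param iter_grid iteration-cap grid (default `c(240, 260, 300, 500)`).
#' @param seed integer RNG seed (permutation importance).
#' @param n_perm permutations for the importance ranking inside the loop.
#' @return list with `model` (the selected [maxent()] fit) and `trace`
#'   (data.frame `step`, `rm`, `classes`, `iter_cap`, `n_vars`, `k`,
#'   `aicc`; AICc non-increasing across accepted steps).
#' @export
tune_maxent <- function(swd_train, vars = NULL,
                        rm_grid = c(0.25, 0.5, 1, 2, 4),
                        iter_grid = c(240, 260, 300, 500),
                        seed = 1, n_perm = 10) {
  stopifnot(length(rm_grid) >= 1, length(iter_grid) >= 1)
  vars <- vars %||% swd_predictors(swd_train)
  iter0 <- max(iter_grid)
  # Step A: regularization multiplier on the full LQ model
  cls <- c("linear", "quadratic")
  fitsA <- lapply(rm_grid, function(r)
    maxent(swd_train, vars = vars, classes = cls, rm = r,
           iter_cap = iter0))
  aiccA <- vapply(fitsA, aicc, 0, swd = swd_train)
  if (all(is.na(aiccA))) stop("insufficient presences for tuning")
  best_i <- which.min(aiccA)
  rm_cur <- rm_grid[best_i]; iter_cur <- iter0
  model <- fitsA[[best_i]]; a_cur <- aiccA[best_i]
  trace <- data.frame(step = "A: select rm", rm = rm_cur,
                      classes = "LQ", iter_cap = iter_cur,
                      n_vars = length(vars), k = model$k, aicc = a_cur,
                      stringsAsFactors = FALSE)
  # Step B: drop variables with all-zero coefficients
  nz <- unique(sub("\\.[lq]$", "",
                   names(model$lambda)[model$lambda != 0]))
  vars_cur <- intersect(vars, nz)
  if (length(vars_cur) < length(vars)) {
    model <- maxent(swd_train, vars = vars_cur, classes = cls,
                    rm = rm_cur, iter_cap = iter_cur,
                    lambda_init = model$lambda)
    a_cur <- aicc(model, swd_train)
    trace <- rbind(trace, data.frame(
      step = "B: drop lambda=0 variables", rm = rm_cur, classes = "LQ",
      iter_cap = iter_cur, n_vars = length(vars_cur), k = model$k,
      aicc = a_cur))
  }
  cls_cur <- cls
  # Step C: greedy single-move loop
  repeat {
    cands <- list()
    for (r in setdiff(rm_grid, rm_cur))
      cands[[length(cands) + 1]] <- list(
        label = sprintf("C: rm -> %g", r), vars = vars_cur,
        classes = cls_cur, rm = r, iter = iter_cur)
    alt_cls <- if (length(cls_cur) == 2) "linear"
    else c("linear", "quadratic")
    cands[[length(cands) + 1]] <- list(
      label = sprintf("C: classes -> %s",
                      if (length(alt_cls) == 2) "LQ" else "L"),
      vars = vars_cur, classes = alt_cls, rm = rm_cur, iter = iter_cur)
    # iteration-cap moves can only matter if the fit hit the cap
    if (!model$converged || model$iters >= min(iter_grid))
      for (itc in setdiff(iter_grid, iter_cur))
        cands[[length(cands) + 1]] <- list(
          label = sprintf("C: iter_cap -> %d", itc), vars = vars_cur,
          classes = cls_cur, rm = rm_cur, iter = itc)
    if (length(vars_cur) >= 1) {
      imp <- if (length(vars_cur) > 1 && model$k > 0)
        permutation_importance(model, swd_train, n_perm = n_perm,
                               seed = seed)
      else stats::setNames(rep(0, length(vars_cur)), vars_cur)
      drop_var <- names(imp)[which.min(imp)]
      cands[[length(cands) + 1]] <- list(
        label = sprintf("C: drop %s", drop_var),
        vars = setdiff(vars_cur, drop_var), classes = cls_cur,
        rm = rm_cur, iter = iter_cur)
    }
    fits <- lapply(cands, function(cn)
      maxent(swd_train, vars = cn$vars, classes = cn$classes,
             rm = cn$rm, iter_cap = cn$iter,
             lambda_init = model$lambda))
    aiccs <- vapply(fits, aicc, 0, swd = swd_train)
    if (all(is.na(aiccs)) || min(aiccs, na.rm = TRUE) >= a_cur - 1e-9)
      break
    j <- which.min(aiccs)
    model <- fits[[j]]; a_cur <- aiccs[j]
    vars_cur <- cands[[j]]$vars; cls_cur <- cands[[j]]$classes
    rm_cur <- cands[[j]]$rm; iter_cur <- cands[[j]]$iter
    trace <- rbind(trace, data.frame(
      step = cands[[j]]$label, rm = rm_cur,
      classes = if (length(cls_cur) == 2) "LQ" else "L",
      iter_cap = iter_cur, n_vars = length(vars_cur), k = model$k,
      aicc = a_cur))
    if (length(vars_cur) == 0) break
  }
  rownames(trace) <- NULL
  list(model = model, trace = trace)
}

# ---- virtual-species null check --------------------------------------------

#' Virtual-species null-model check
#'
#' Distributes `n_records` records uniformly at random over the
#' landscape, runs the full pipeline (thin to cells, buffered background,
#' SWD extraction, checkerboard split, AICc tuning) and reports whether a
#' valid model was obtained.  With no species-environment relationship
#' the tuned model is expected to retain zero variables and the test AUC
#' to sit near 0.5; a retained model would indicate method- or
#' bias-driven artefacts.
#'
#' @param landscape a [synthetic_landscape()].
#' @param n_records number of uniform random records (default 10000).
#' @param n_background background points (default 10000).
#' @param seed integer RNG seed.
#' @param vars candidate predictors (default: landscape predictor stack).
#' @param test_partition held-out checkerboard partition.
#' @param n_perm permutations inside tuning.
#' @return list with `valid_model` (TRUE iff the tuned model retains at
#'   least one variable), `n_variables`, `test_auc`, `trace`, `model`.
#' @export
null_model_check <- function(landscape, n_records = 10000,
                             n_background = 10000, seed = 1,
                             vars = NULL, test_partition = 4,
                             n_perm = 10) {
  grid <- landscape$grid
  vars <- vars %||% names(landscape$predictors)
  years <- landscape$years
  recs <- with_seed(seed, {
    data.frame(record_id = seq_len(n_records), species = "virtual",
               x = stats::runif(n_records, grid$origin_x,
                                grid$origin_x + grid$n_cols *
                                  grid$cell_size),
               y = stats::runif(n_records,
                                grid$origin_y - grid$n_rows *
                                  grid$cell_size, grid$origin_y),
               year = sample(years, n_records, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  thin <- thin_to_cells(recs, grid)
  bg <- buffer_background(thin$presences, n_points = n_background,
                          grid = grid, seed = seed + 1)
  swd <- extract_swd(thin$presences, bg,
                     landscape$predictors[vars],
                     landscape$climate$bio1_by_year, grid)
  parts <- split_train_test(swd, test_partition)
  tuned <- tune_maxent(parts$train, vars = vars, seed = seed + 2,
                       n_perm = n_perm)
  sc <- predict(tuned$model, parts$test, type = "cloglog")
  test_auc <- auc(sc[parts$test$class == "presence"],
                  sc[parts$test$class == "background"])
  list(valid_model = length(unique(sub("\\.[lq]$", "",
         names(tuned$model$lambda)[tuned$model$lambda != 0]))) > 0,
       n_variables = length(unique(sub("\\.[lq]$", "",
         names(tuned$model$lambda)[tuned$model$lambda != 0]))),
       test_auc = test_auc, trace = tuned$trace, model = tuned$model)
}

# ---- serialization ---------------------------------------------------------

#' Serialize / deserialize a maxent model as JSON
#'
#' Stores variables, feature classes, scaling bounds, coefficients,
#' penalties, regularization multiplier, iteration cap, `Z`, `H` and the
#' clamping flag at full precision; the round trip is deterministic.
#'
#' @param model a fitted [maxent()] model.
#' @param path JSON file path.
#' @export
write_maxent <- function(model, path) {
  doc <- list(vars = model$feature_map$vars,
              classes = model$feature_map$classes,
              lo = as.list(stats::setNames(model$feature_map$lo,
                                           model$feature_map$vars)),
              hi = as.list(stats::setNames(model$feature_map$hi,
                                           model$feature_map$vars)),
              lambda = as.list(model$lambda),
              beta = as.list(stats::setNames(model$beta,
                                             names(model$lambda))),
              rm = model$rm, iter_cap = model$iter_cap, tol = model$tol,
              Z = model$Z, logZ = model$logZ, H = model$H,
              clamp = model$clamp, k = model$k,
              n_presence = model$n_presence,
              n_background = model$n_background,
              loglik = model$loglik, objective = model$objective,
              species = if (is.na(model$species)) NULL
              else model$species)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_maxent
#' @return `read_maxent`: a [maxent()] object.
#' @export
read_maxent <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fmap <- structure(list(vars = doc$vars, classes = doc$classes,
                         lo = stats::setNames(unlist(doc$lo), doc$vars),
                         hi = stats::setNames(unlist(doc$hi), doc$vars)),
                    class = "feature_map")
  structure(list(call = NULL, feature_map = fmap,
                 lambda = stats::setNames(unlist(doc$lambda),
                                          names(doc$lambda)),
                 beta = stats::setNames(unlist(doc$beta),
                                        names(doc$beta)),
                 rm = doc$rm, iter_cap = doc$iter_cap, tol = doc$tol,
                 Z = doc$Z, logZ = doc$logZ, H = doc$H,
                 clamp = doc$clamp, k = doc$k,
                 n_presence = doc$n_presence,
                 n_background = doc$n_background, loglik = doc$loglik,
                 objective = doc$objective, iters = NA_integer_,
                 converged = TRUE,
                 species = doc$species %||% NA_character_),
            class = "maxent")
}
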