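# Sphere estimation: alternating closed-form radius / gradient-descent centre
# updates for a fixed coordinate subset, exhaustive subset search, and the l1
# relaxation with capped-simplex projected gradient plus rounding-and-refit.

#' Fitting options
#'
#' Collects the optimizer's tunable parameters.
#'
#' @param search Subset-search strategy: `"auto"` picks exhaustive search when
#'   `choose(d, d'+1) <= combo_budget` and the l1 relaxation otherwise.
#' @param max_outer_iters Cap on alternating (radius, centre) cycles.
#' @param center_gd_max_iters Cap on gradient-descent steps per centre update.
#' @param step_shrink Backtracking shrink factor.
#' @param armijo Sufficient-decrease constant for the line search.
#' @param tol_loss Relative loss-change convergence tolerance.
#' @param r_max_factor Radius cap as a multiple of the data diameter
#'   (bounding-box diagonal); keeps near-planar fits finite.
#' @param combo_budget Subset-count threshold for the automatic policy.
#' @param n_starts Number of seeded starts for the l1 relaxation.
#' @param l1_max_iters Projected-gradient iteration cap per l1 start.
#' @param seed Seed for every stochastic element (l1 multi-start, ICA).
#' @param init Centre initialization: `"mean"` (column means), `"spca"`
#'   (algebraic sphere fit on the retained coordinates), `"plane"`
#'   (large-radius sphere tangent to the flattest retained coordinate, so the
#'   planar limit of the sphere family is reachable), or `"both"` (all three,
#'   keep the best).
#' @return A list of class `srca_options`.
#' @export
fit_options <- function(search = c("auto", "exhaustive", "l1"),
                       max_outer_iters = 200L,
                       center_gd_max_iters = 500L,
                       step_shrink = 0.5,
                       armijo = 1e-4,
                       tol_loss = 1e-10,
                       r_max_factor = 1e6,
                       combo_budget = 500L,
                       n_starts = 5L,
                       l1_max_iters = 200L,
                       seed = 0L,
                       init = c("both", "mean", "spca", "plane")) {
  search <- match.arg(search)
  init <- match.arg(init)
  stopifnot(max_outer_iters >= 1L, center_gd_max_iters >= 1L,
            tol_loss > 0, step_shrink > 0, step_shrink < 1,
            r_max_factor > 0, combo_budget >= 1L, n_starts >= 1L)
  structure(list(search = search, max_outer_iters = as.integer(max_outer_iters),
                 center_gd_max_iters = as.integer(center_gd_max_iters),
                 step_shrink = step_shrink, armijo = armijo,
                 tol_loss = tol_loss, r_max_factor = r_max_factor,
                 combo_budget = as.integer(combo_budget),
                 n_starts = as.integer(n_starts),
                 l1_max_iters = as.integer(l1_max_iters),
                 seed = as.integer(seed), init = init),
            class = "srca_options")
}

# Bounding-box diagonal, an O(nd) stand-in for the data diameter.
.data_diameter <- function(X) {
  rng <- apply(X, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}

#' Closed-form radius update
#'
#' For fixed centre and index set the geometric loss is exactly minimized by
#' the mean in-subspace distance,
#' \eqn{r = (1/n) \sum_i \sqrt{(x_i - c)^T W^T I_I W (x_i - c)}}.
#'
#' @inheritParams geometric_loss
#' @return The optimal radius (positive scalar).
#' @export
update_radius <- function(X, center, index_set, weight = NULL) {
  X <- .as_data_matrix(X)
  idx <- .check_index_set(index_set, ncol(X))
  W <- .check_weight(weight, ncol(X))
  Xc <- sweep(X, 2L, as.numeric(center))
  if (is.null(W)) {
    radical <- sqrt(rowSums(Xc[, idx, drop = FALSE]^2))
  } else {
    B <- Xc %*% W
    radical <- sqrt(rowSums(B[, idx, drop = FALSE]^2))
  }
  r <- mean(radical)
  if (r <= .Machine$double.eps * max(1, .data_diameter(X)))
    stop("data collapsed to center: radius update is degenerate")
  r
}

# Gradient descent on the retained-coordinate centre, identity weight.
# The complement is at its closed form, so the objective reduces to
# sum_i (||x_{i,I} - c_I|| - r)^2. Works with the precomputed row square
# norms Xsq = rowSums(XI^2); returns the updated c_I.
.center_gd_identity <- function(XI, Xsq, radius, cI, opts) {
  n <- nrow(XI)
  dens <- function(cI) {
    q <- Xsq - 2 * drop(XI %*% cI) + sum(cI^2)
    q[q < 0] <- 0
    sqrt(q)
  }
  den <- dens(cI)
  f <- sum((den - radius)^2)
  t_step <- 1 / n
  for (it in seq_len(opts$center_gd_max_iters)) {
    w <- (den - radius) / pmax(den, .Machine$double.xmin)  # zero rows: subgradient 0
    w[den == 0] <- 0
    g <- -2 * (drop(crossprod(XI, w)) - cI * sum(w))
    gsq <- sum(g^2)
    if (gsq <= 1e-30 * max(1, f)) break
    t_try <- t_step
    accepted <- FALSE
    for (bt in 1:60) {
      cand <- cI - t_try * g
      den_cand <- dens(cand)
      f_cand <- sum((den_cand - radius)^2)
      if (f_cand <= f - opts$armijo * t_try * gsq) {
        accepted <- TRUE
        break
      }
      t_try <- t_try * opts$step_shrink
    }
    if (!accepted) break
    rel_change <- (f - f_cand) / max(1, abs(f))
    cI <- cand
    den <- den_cand
    f <- f_cand
    t_step <- t_try * 2
    if (rel_change < opts$tol_loss) break
  }
  cI
}

# Alternating fit restricted to the retained coordinates, identity weight.
# The exact closed-form radius update is interleaved between single
# backtracking gradient steps on the centre, so the radius is always at its
# conditional optimum (profiled descent); every accepted step is monotone.
# XI = X[, idx]; loss_off is the constant off-subspace part. Returns NULL
# when the initialization fails.
.fit_identity_from <- function(XI, Xsq, loss_off, cI, r0, r_cap, opts) {
  n <- nrow(XI)
  dens <- function(cI) {
    q <- Xsq - 2 * drop(XI %*% cI) + sum(cI^2)
    q[q < 0] <- 0
    sqrt(q)
  }
  den <- dens(cI)
  r <- if (is.null(r0)) mean(den) else r0
  if (r <= .Machine$double.eps) return(NULL)
  clamped <- FALSE
  if (r > r_cap) { r <- r_cap; clamped <- TRUE }
  loss_in <- sum((den - r)^2)
  max_steps <- opts$max_outer_iters * 25L
  trace <- numeric(max_steps + 2L)
  trace[1L] <- loss_off + loss_in
  n_trace <- 1L
  converged <- FALSE
  t_step <- 1 / n
  window_loss <- loss_in
  for (it in seq_len(max_steps)) {
    # radius at its closed-form optimum (rejected if the cap would raise loss)
    r_prop <- mean(den)
    if (r_prop > r_cap) { r_prop <- r_cap; clamped <- TRUE }
    if (r_prop > .Machine$double.eps) {
      loss_r <- sum((den - r_prop)^2)
      if (loss_r <= loss_in) { r <- r_prop; loss_in <- loss_r }
    }
    # one backtracking gradient step on the centre
    w <- 1 - r / den            # zero-radical rows get subgradient 0
    w[!is.finite(w)] <- 0
    g <- -2 * (drop(crossprod(XI, w)) - cI * sum(w))
    gsq <- sum(g^2)
    if (gsq <= 1e-30 * max(1, loss_in)) { converged <- TRUE; break }
    t_try <- t_step
    accepted <- FALSE
    for (bt in 1:60) {
      cand <- cI - t_try * g
      den_cand <- dens(cand)
      f_cand <- sum((den_cand - r)^2)
      if (f_cand <= loss_in - opts$armijo * t_try * gsq) {
        accepted <- TRUE
        break
      }
      t_try <- t_try * opts$step_shrink
    }
    if (!accepted) { converged <- TRUE; break }
    rel_change <- (loss_in - f_cand) / max(1, loss_off + loss_in)
    cI <- cand
    den <- den_cand
    loss_in <- f_cand
    t_step <- t_try * 2
    n_trace <- n_trace + 1L
    trace[n_trace] <- loss_off + loss_in
    if (rel_change < opts$tol_loss) { converged <- TRUE; break }
    if (it %% 25L == 0L) {
      # plateau: a whole window of steps moved the loss by < 1e-6 relative
      # (relative to the loss itself, so exact fits are never truncated)
      if ((window_loss - loss_in) < 1e-6 * (loss_off + loss_in)) {
        converged <- TRUE
        break
      }
      window_loss <- loss_in
    }
  }
  # final radius touch-up at the converged centre
  r_prop <- min(mean(den), r_cap)
  if (r_prop > .Machine$double.eps) {
    loss_r <- sum((den - r_prop)^2)
    if (loss_r <= loss_in) {
      r <- r_prop
      loss_in <- loss_r
      n_trace <- n_trace + 1L
      trace[n_trace] <- loss_off + loss_in
    }
  }
  list(cI = cI, radius = r, loss = loss_off + loss_in,
       trace = trace[seq_len(n_trace)],
       converged = converged, clamped = clamped)
}

# Gradient descent on the full centre vector for a general weight matrix.
.center_gd_weighted <- function(X, radius, index_set, W, cvec, opts) {
  fval <- function(cvec) sum(.sphere_sqdist_rows(X, cvec, radius, index_set, W))
  f <- fval(cvec)
  t_step <- 1 / nrow(X)
  for (it in seq_len(opts$center_gd_max_iters)) {
    Xc <- sweep(X, 2L, cvec)
    B <- Xc %*% W
    q <- sqrt(rowSums(B[, index_set, drop = FALSE]^2))
    inv_q <- ifelse(q > 0, 1 / q, 0)
    BI <- matrix(0, nrow(X), ncol(X))
    BI[, index_set] <- B[, index_set, drop = FALSE] * inv_q
    g <- -2 * colSums(B) + 2 * radius * drop(crossprod(W, colSums(BI)))
    gsq <- sum(g^2)
    if (gsq <= 1e-30 * max(1, f)) break
    accepted <- FALSE
    t_try <- t_step
    for (bt in 1:60) {
      cand <- cvec - t_try * g
      f_cand <- fval(cand)
      if (f_cand <= f - opts$armijo * t_try * gsq) {
        accepted <- TRUE
        break
      }
      t_try <- t_try * opts$step_shrink
    }
    if (!accepted) break
    rel_change <- (f - f_cand) / max(1, abs(f))
    cvec <- cand
    f <- f_cand
    t_step <- t_try * 2
    if (rel_change < opts$tol_loss) break
  }
  cvec
}

#' Centre update by gradient descent
#'
#' With the identity weight the coordinates outside the index set have the
#' closed-form optimum (the column means); the retained coordinates are
#' updated by backtracking gradient descent on the geometric loss. With a
#' general weight all coordinates enter the gradient system.
#'
#' @inheritParams geometric_loss
#' @param radius Fixed positive radius.
#' @param center_init Starting centre (d-vector).
#' @param options An [fit_options()] list.
#' @return Updated centre (d-vector); the loss at the result never exceeds
#'   the loss at `center_init`.
#' @export
update_center <- function(X, radius, index_set, weight = NULL,
                          center_init = colMeans(X), options = fit_options()) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  idx <- .check_index_set(index_set, d)
  W <- .check_weight(weight, d)
  cvec <- as.numeric(center_init)
  if (length(cvec) != d) stop("'center_init' must have length ncol(X)")
  if (is.null(W)) {
    if (length(idx) < d)
      cvec[-idx] <- colMeans(X[, -idx, drop = FALSE])
    XI <- X[, idx, drop = FALSE]
    cvec[idx] <- .center_gd_identity(XI, rowSums(XI^2), radius,
                                     cvec[idx], options)
    cvec
  } else {
    .center_gd_weighted(X, radius, idx, W, cvec, options)
  }
}

# Initial centres/radii for a fixed subset.
.subset_inits <- function(X, idx, opts) {
  d <- ncol(X)
  mu <- colMeans(X)
  inits <- list()
  if (opts$init %in% c("mean", "both"))
    inits$mean <- list(center = mu, radius = NULL)
  if (opts$init %in% c("spca", "both")) {
    sp <- tryCatch(algebraic_sphere_fit(X[, idx, drop = FALSE]),
                   error = function(e) NULL, warning = function(w) {
                     tryCatch(suppressWarnings(
                       algebraic_sphere_fit(X[, idx, drop = FALSE])),
                       error = function(e) NULL)
                   })
    if (!is.null(sp) && is.finite(sp$radius) && sp$radius > 0 &&
        all(is.finite(sp$center))) {
      cvec <- mu; cvec[idx] <- sp$center
      inits$spca <- list(center = cvec, radius = sp$radius)
    }
  }
  # no plane-limit starts here: this branch serves general weights, where a
  # weight eigenvalue above 1 makes the weighted loss unbounded in the
  # large-radius limit (the identity-weight path owns the planar regime)
  if (length(inits) == 0L) inits$mean <- list(center = mu, radius = NULL)
  inits
}

#' Fit the sphere for a fixed index set
#'
#' Alternates the closed-form radius update with gradient descent on the
#' centre, from each requested initialization, and returns the best. The
#' loss trace is non-increasing across accepted steps; the radius is capped
#' at `r_max_factor` times the data diameter (clamping recorded in the
#' result).
#'
#' @inheritParams update_center
#' @param index_set Strictly increasing integers in 1..d.
#' @return List with `center`, `radius`, `loss`, `trace` (per outer
#'   iteration), `converged`, `clamped`, and `init` (winning start).
#' @export
fit_fixed_subset <- function(X, index_set, weight = NULL,
                             options = fit_options()) {
  X <- .as_data_matrix(X)
  idx <- .check_index_set(index_set, ncol(X))
  if (nrow(X) < length(idx)) stop("need at least |index_set| rows")
  W <- .check_weight(weight, ncol(X))
  r_cap <- options$r_max_factor * max(.data_diameter(X), .Machine$double.eps)
  if (is.null(W)) return(.fit_fixed_identity(X, idx, r_cap, options))
  best <- NULL
  inits <- .subset_inits(X, idx, options)
  for (init_name in names(inits)) {
    ini <- inits[[init_name]]
    res <- tryCatch(
      .fit_fixed_from(X, idx, W, ini$center, ini$radius, r_cap, options),
      error = function(e) NULL)
    if (is.null(res)) next
    res$init <- init_name
    if (is.null(best) || res$loss < best$loss) best <- res
  }
  if (is.null(best)) stop("sphere fit failed from every initialization")
  best
}

# Identity-weight subset fit: the loss splits into a constant off-subspace
# part plus sum_i (||x_{i,I} - c_I|| - r)^2, so the alternation runs entirely
# in the retained coordinates. The plane-limit initialization is attempted
# only when its starting loss already undercuts the converged mean/spca fits
# (the near-planar regime it exists for).
.fit_fixed_identity <- function(X, idx, r_cap, opts) {
  n <- nrow(X)
  mu <- colMeans(X)
  XI <- X[, idx, drop = FALSE]
  Xsq <- rowSums(XI^2)
  colSS <- colSums(X^2) - n * mu^2
  loss_off <- max(sum(colSS) - sum(colSS[idx]), 0)
  best <- NULL
  consider <- function(res, init_name) {
    if (is.null(res)) return()
    res$init <- init_name
    if (is.null(best) || res$loss < best$loss) best <<- res
  }
  if (opts$init %in% c("mean", "both"))
    consider(.fit_identity_from(XI, Xsq, loss_off, mu[idx], NULL, r_cap, opts),
             "mean")
  if (opts$init %in% c("spca", "both")) {
    sp <- tryCatch(suppressWarnings(algebraic_sphere_fit(XI)),
                   error = function(e) NULL)
    if (!is.null(sp) && all(is.finite(sp$center)) && is.finite(sp$radius) &&
        sp$radius > 0)
      consider(.fit_identity_from(XI, Xsq, loss_off, sp$center,
                                  min(sp$radius, r_cap), r_cap, opts),
               "spca")
  }
  if (opts$init == "both" && !isTRUE(opts$.skip_ring)) {
    # deterministic ring of starts around the mean, one sd out along each
    # retained axis: reaches off-centre basins the central starts miss
    sds <- sqrt(colSS[idx] / (n - 1))
    for (j in seq_along(idx)) for (sgn in c(-1, 1)) {
      cI <- mu[idx]
      cI[j] <- cI[j] + sgn * sds[j]
      consider(.fit_identity_from(XI, Xsq, loss_off, cI, NULL, r_cap, opts),
               sprintf("ring_%d%s", j, if (sgn < 0) "-" else "+"))
    }
  }
  if (opts$init %in% c("plane", "both")) {
    diam <- max(.data_diameter(X), .Machine$double.eps)
    r_big <- min(1e5 * diam, r_cap)
    vars <- colSS[idx] / (n - 1)
    a <- which.min(vars)
    for (sgn in c(-1, 1)) {
      cI <- mu[idx]
      cI[a] <- cI[a] + sgn * r_big
      den <- sqrt(pmax(Xsq - 2 * drop(XI %*% cI) + sum(cI^2), 0))
      loss0 <- loss_off + sum((den - r_big)^2)
      if (is.null(best) || loss0 < best$loss)
        consider(.fit_identity_from(XI, Xsq, loss_off, cI, r_big, r_cap, opts),
                 if (sgn < 0) "plane_neg" else "plane_pos")
    }
  }
  if (is.null(best))
    best <- .fit_identity_from(XI, Xsq, loss_off, mu[idx], NULL, r_cap, opts)
  if (is.null(best)) stop("sphere fit failed from every initialization")
  center <- mu
  center[idx] <- best$cI
  list(center = center, radius = best$radius, loss = best$loss,
       trace = best$trace, converged = best$converged,
       clamped = best$clamped, init = best$init)
}

.fit_fixed_from <- function(X, idx, W, c0, r0, r_cap, opts) {
  cvec <- c0
  r <- if (is.null(r0)) update_radius(X, cvec, idx, W) else r0
  clamped <- FALSE
  if (r > r_cap) { r <- r_cap; clamped <- TRUE }
  loss <- sum(.sphere_sqdist_rows(X, cvec, r, idx, W))
  trace <- loss
  converged <- FALSE
  for (it in seq_len(opts$max_outer_iters)) {
    r_prop <- tryCatch(update_radius(X, cvec, idx, W), error = function(e) NA_real_)
    if (is.finite(r_prop)) {
      if (r_prop > r_cap) { r_prop <- r_cap; clamped <- TRUE }
      loss_r <- sum(.sphere_sqdist_rows(X, cvec, r_prop, idx, W))
      if (loss_r <= loss) { r <- r_prop; loss <- loss_r }  # reject clamp-induced increase
    }
    cvec <- update_center(X, r, idx, W, cvec, opts)
    new_loss <- sum(.sphere_sqdist_rows(X, cvec, r, idx, W))
    if (new_loss > loss) new_loss <- loss  # numerical guard; centre update is monotone
    trace <- c(trace, new_loss)
    if ((loss - new_loss) <= opts$tol_loss * max(1, abs(loss))) {
      loss <- new_loss
      converged <- TRUE
      break
    }
    loss <- new_loss
  }
  list(center = cvec, radius = r, loss = loss, trace = trace,
       converged = converged, clamped = clamped)
}

#' Automatic search policy
#'
#' Exhaustive subset search when the number of candidate index sets,
#' `choose(d, d'+1)`, is within the budget; the l1 relaxation otherwise.
#'
#' @param d Ambient dimension.
#' @param retained_dim Intrinsic dimension d'.
#' @param combo_budget Subset-count threshold (default 500).
#' @return `"exhaustive"` or `"l1"`.
#' @export
auto_search_policy <- function(d, retained_dim, combo_budget = 500L) {
  stopifnot(retained_dim >= 1L, retained_dim + 1L <= d)
  if (choose(d, retained_dim + 1L) <= combo_budget) "exhaustive" else "l1"
}

#' Exhaustive subset search
#'
#' Fits the sphere on every size-(d'+1) coordinate subset and returns the one
#' with minimal geometric loss; ties go to the lexicographically smallest
#' index set.
#'
#' @inheritParams update_center
#' @param retained_dim Intrinsic dimension d'.
#' @param force Run even when the subset count exceeds `combo_budget`.
#' @return List with `index_set`, `center`, `radius`, `loss`, `trace`,
#'   `n_subsets_evaluated`, `converged`.
#' @export
exhaustive_search <- function(X, retained_dim, weight = NULL,
                              options = fit_options(), force = FALSE) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  s <- retained_dim + 1L
  if (s > d) stop("retained_dim must be at most d - 1")
  n_comb <- choose(d, s)
  if (n_comb > options$combo_budget && !force)
    stop(sprintf(paste0("%d subsets exceed the budget of %d; use the l1 ",
                        "search (search = \"l1\") or force = TRUE"),
                 n_comb, options$combo_budget))
  subsets <- utils::combn(d, s)
  n_comb <- ncol(subsets)
  # screen every subset with a short iteration budget (each screened loss is
  # an upper bound on that subset's optimum), then polish the leaders fully
  screen_opts <- options
  screen_opts$max_outer_iters <- min(options$max_outer_iters, 6L)
  screen_opts$.skip_ring <- TRUE
  losses <- numeric(n_comb)
  for (k in seq_len(n_comb)) {
    losses[k] <- fit_fixed_subset(X, subsets[, k], weight, screen_opts)$loss
  }
  top <- order(losses)[seq_len(min(5L, n_comb))]
  best <- NULL
  for (k in sort(top)) {  # lexicographic order among the polished candidates
    idx <- subsets[, k]
    fit <- fit_fixed_subset(X, idx, weight, options)
    if (is.null(best) || fit$loss < best$loss - 1e-12 * max(1, abs(best$loss))) {
      best <- fit
      best$index_set <- idx
    }
  }
  list(index_set = best$index_set, center = best$center, radius = best$radius,
       loss = best$loss, trace = best$trace,
       n_subsets_evaluated = n_comb, converged = best$converged)
}

# Euclidean projection onto {v : 0 <= v <= 1, sum(v) <= s}.
.project_capped_simplex <- function(w, s) {
  v <- pmin(pmax(w, 0), 1)
  if (sum(v) <= s) return(v)
  lo <- min(w) - 1
  hi <- max(w)
  for (it in 1:100) {
    tau <- (lo + hi) / 2
    tot <- sum(pmin(pmax(w - tau, 0), 1))
    if (tot > s) lo <- tau else hi <- tau
  }
  pmin(pmax(w - hi, 0), 1)
}

# Loss of the relaxed problem with selection weights v in [0,1]^d.
.l1_loss <- function(X, cvec, r, v, W) {
  Xc <- sweep(X, 2L, cvec)
  B <- if (is.null(W)) Xc else Xc %*% W
  quad <- if (is.null(W)) rowSums(Xc^2) else rowSums(Xc * B)
  q <- sqrt(rowSums(sweep(B^2, 2L, v^2, `*`)))
  sum(quad + r^2 - 2 * r * q)
}

.l1_single_start <- function(X, s, W, v, cvec, opts) {
  n <- nrow(X)
  # closed-form radius for current (c, v)
  radius_of <- function(cvec, v) {
    Xc <- sweep(X, 2L, cvec)
    B <- if (is.null(W)) Xc else Xc %*% W
    mean(sqrt(rowSums(sweep(B^2, 2L, v^2, `*`))))
  }
  r <- max(radius_of(cvec, v), 1e-12)
  f <- .l1_loss(X, cvec, r, v, W)
  t_c <- 1 / n
  t_v <- 1 / n
  for (it in seq_len(opts$l1_max_iters)) {
    f_prev <- f
    # --- radius: exact minimizer
    r <- max(radius_of(cvec, v), 1e-12)
    f <- .l1_loss(X, cvec, r, v, W)
    # --- centre: one backtracking gradient step
    Xc <- sweep(X, 2L, cvec)
    B <- if (is.null(W)) Xc else Xc %*% W
    q <- sqrt(rowSums(sweep(B^2, 2L, v^2, `*`)))
    inv_q <- ifelse(q > 0, 1 / q, 0)
    Bv <- sweep(B, 2L, v^2, `*`) * inv_q
    g_c <- if (is.null(W)) -2 * colSums(Xc) + 2 * r * colSums(Bv)
           else -2 * colSums(B) + 2 * r * drop(crossprod(W, colSums(Bv)))
    gsq <- sum(g_c^2)
    if (gsq > 1e-30 * max(1, f)) {
      t_try <- t_c
      for (bt in 1:40) {
        cand <- cvec - t_try * g_c
        f_cand <- .l1_loss(X, cand, r, v, W)
        if (f_cand <= f - opts$armijo * t_try * gsq) break
        t_try <- t_try * opts$step_shrink
      }
      if (f_cand <= f) { cvec <- cand; f <- f_cand; t_c <- t_try * 2 }
    }
    # --- selection weights: projected gradient step
    Xc <- sweep(X, 2L, cvec)
    B <- if (is.null(W)) Xc else Xc %*% W
    q <- sqrt(rowSums(sweep(B^2, 2L, v^2, `*`)))
    inv_q <- ifelse(q > 0, 1 / q, 0)
    g_v <- -2 * r * v * colSums(B^2 * inv_q)
    t_try <- t_v
    improved <- FALSE
    for (bt in 1:40) {
      cand <- .project_capped_simplex(v - t_try * g_v, s)
      f_cand <- .l1_loss(X, cvec, r, cand, W)
      if (f_cand <= f) { improved <- TRUE; break }
      t_try <- t_try * opts$step_shrink
    }
    if (improved) { v <- cand; f <- f_cand; t_v <- t_try * 2 }
    if (!is.finite(f)) stop("l1 start diverged")
    if ((f_prev - f) <= 1e-8 * max(1, abs(f_prev))) break
  }
  list(v = v, center = cvec, radius = r, loss = f)
}

#' Subset search by l1 relaxation
#'
#' Relaxes the binary coordinate-selection vector to continuous
#' `v` in `[0,1]^d` with `sum(v) <= d'+1` and minimizes the relaxed geometric
#' loss over (v, c, r) by projected gradient (exact radius updates,
#' backtracking centre and selection steps) from seeded multi-starts, one of
#' which weights coordinates by their centred second moment. Each start is
#' rounded (the d'+1 largest entries of v, ties to lower indices) and
#' refitted with [fit_fixed_subset()]; the best refitted model is returned,
#' so the reported loss is always the loss of a valid discrete index set.
#'
#' @inheritParams exhaustive_search
#' @return Same shape as [exhaustive_search()].
#' @export
l1_search <- function(X, retained_dim, weight = NULL, options = fit_options()) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  s <- retained_dim + 1L
  if (s > d) stop("retained_dim must be at most d - 1")
  W <- .check_weight(weight, d)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  energy <- colMeans((if (is.null(W)) Xc else Xc %*% W)^2)
  starts <- list(list(v = .project_capped_simplex(s * energy / sum(energy) * d / s, s),
                      center = mu))
  extra <- .with_seed(options$seed, {
    lapply(seq_len(max(0L, options$n_starts - 1L)), function(k) {
      list(v = .project_capped_simplex(stats::runif(d), s),
           center = mu + stats::rnorm(d) * 0.1 * apply(X, 2L, stats::sd))
    })
  })
  starts <- c(starts, extra)
  candidates <- list()
  n_fail <- 0L
  for (st in starts) {
    sol <- tryCatch(.l1_single_start(X, s, W, st$v, st$center, options),
                    error = function(e) NULL)
    if (is.null(sol)) { n_fail <- n_fail + 1L; next }
    ord <- order(-sol$v, seq_len(d))
    idx <- sort(ord[seq_len(s)])
    key <- paste(idx, collapse = ",")
    if (is.null(candidates[[key]])) candidates[[key]] <- idx
  }
  if (length(candidates) == 0L) stop("all l1 starts failed")
  best <- NULL
  for (idx in candidates) {
    fit <- fit_fixed_subset(X, idx, W, options)
    take <- is.null(best) ||
      fit$loss < best$loss - 1e-12 * max(1, abs(best$loss)) ||
      (abs(fit$loss - best$loss) <= 1e-12 * max(1, abs(best$loss)) &&
         .lex_less(idx, best$index_set))
    if (take) { best <- fit; best$index_set <- idx }
  }
  list(index_set = best$index_set, center = best$center, radius = best$radius,
       loss = best$loss, trace = best$trace,
       n_subsets_evaluated = length(candidates), converged = best$converged)
}

.lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}
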