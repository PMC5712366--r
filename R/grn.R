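# Directed network inference: per-target ARX(p) regression with the group
# SCAD penalty.  A group is one candidate regulator's p lagged variables
# (including the target's own lags), so selection is per regulator, not
# per lag.  The solver is cyclic group coordinate descent on a
# within-group orthonormalized design, with warm starts along the lambda
# path (src/group_scad.cpp).

#' SCAD thresholding operator
#'
#' Closed-form minimizer over `b >= 0` of
#' `0.5 * (z - b)^2 + p_{lambda,a}(b)` with the SCAD penalty: 0 below the
#' threshold, soft-thresholding up to `2*lambda`, a linear interpolation
#' region up to `a*lambda`, and the identity (no shrinkage) beyond it —
#' the unbiasedness region that distinguishes SCAD from the lasso.
#'
#' @param z non-negative scalar or vector (e.g. a group correlation norm).
#' @param lambda penalty level (>= 0).
#' @param a SCAD shape parameter (> 2; canonical value 3.7).
#' @return thresholded value(s), same length as `z`.
#' @examples
#' scad_threshold(3, 1, 3.7)  # (2.7*3 - 3.7)/1.7
#' @export
scad_threshold <- function(z, lambda, a = 3.7) {
  if (a <= 2) stopf("SCAD shape a must exceed 2")
  if (any(z < 0) || lambda < 0) stopf("z and lambda must be non-negative")
  ifelse(z <= lambda, 0,
         ifelse(z <= 2 * lambda, z - lambda,
                ifelse(z <= a * lambda,
                       ((a - 1) * z - a * lambda) / (a - 2), z)))
}

# SCAD penalty value (scalar b >= 0); used for objectives in R-side checks.
scad_penalty <- function(b, lambda, a = 3.7) {
  ifelse(b <= lambda, lambda * b,
         ifelse(b <= a * lambda,
                (2 * a * lambda * b - b^2 - lambda^2) / (2 * (a - 1)),
                lambda^2 * (a + 1) / 2))
}

#' Lagged grouped regression design for one target gene
#'
#' Builds the ARX(p) design for `target`: response `y = x_target(t)` for
#' `t = p+1..T`, and for every candidate regulator g (all genes, the
#' target included) the p columns `x_g(t-1), ..., x_g(t-p)`, grouped per
#' regulator.
#'
#' @param series a [series_matrix()] (genes x time points).
#' @param target target gene id (or row index).
#' @param p ARX order (1, 2 or 3).
#' @return object of class `grouped_design`: `y` (length T-p), `X`
#'   ((T-p) x G*p), `groups` (integer vector mapping columns to
#'   regulators), `genes`, `target`, `p`.
#' @export
build_lagged_design <- function(series, target, p) {
  if (!p %in% 1:3) stopf("p must be 1, 2 or 3")
  m <- unclass(series)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ti <- if (is.character(target)) match(target, ids) else as.integer(target)
  if (is.na(ti) || ti < 1 || ti > nrow(m)) stopf("unknown target gene")
  Tn <- ncol(m)
  if (Tn <= p) stopf("series length T = %d must exceed the order p = %d", Tn, p)
  G <- nrow(m)
  rows <- (p + 1):Tn
  y <- m[ti, rows]
  X <- matrix(NA_real_, length(rows), G * p)
  cn <- character(G * p)
  for (g in seq_len(G)) {
    for (l in seq_len(p)) {
      X[, (g - 1) * p + l] <- m[g, rows - l]
      cn[(g - 1) * p + l] <- sprintf("%s.lag%d", ids[g], l)
    }
  }
  colnames(X) <- cn
  structure(list(y = y, X = X, groups = rep(seq_len(G), each = p),
                 genes = ids, target = ids[ti], p = p),
            class = "grouped_design")
}

#' @export
print.grouped_design <- function(x, ...) {
  cat(sprintf("<grouped_design> target %s: %d rows, %d regulators x p = %d lags\n",
              x$target, length(x$y), length(x$genes), x$p))
  invisible(x)
}

# Standardize (center, population-sd scale) and group-orthonormalize a
# design matrix so X_g' X_g = n I per group; records the transforms
# needed to map solver coefficients back to the original scale.  A
# standardized single-column group already has norm sqrt(n), so size-1
# groups need no QR (qr_list entry NULL).  Rank-deficient groups keep
# only their leading independent directions.  The result depends only on
# (X, groups), so network inference prepares one design shared by every
# target.
prepare_X <- function(X, groups) {
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd_pop)
  if (any(scl < 1e-12)) {
    stopf("constant design column (%s): exclude constant genes first",
          colnames(X)[which(scl < 1e-12)[1]])
  }
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  G <- max(groups)
  gsize <- tabulate(groups, G)
  if (all(gsize == 1L)) {
    return(list(Xt = Xs, ctr = ctr, scl = scl,
                qr_list = vector("list", G),
                sizes = rep(1L, G), n = n, G = G))
  }
  Xt_list <- vector("list", G)
  qr_list <- vector("list", G)
  sizes <- integer(G)
  for (g in seq_len(G)) {
    cols <- which(groups == g)
    if (length(cols) == 1L) {
      Xt_list[[g]] <- Xs[, cols, drop = FALSE]
      sizes[g] <- 1L
    } else {
      qg <- qr(Xs[, cols, drop = FALSE])
      r <- qg$rank
      Xt_list[[g]] <- qr.Q(qg)[, seq_len(r), drop = FALSE] * sqrt(n)
      qr_list[[g]] <- qg
      sizes[g] <- r
    }
  }
  list(Xt = do.call(cbind, Xt_list), ctr = ctr, scl = scl,
       qr_list = qr_list, sizes = sizes, n = n, G = G)
}

prepare_design <- function(design) {
  prep <- prepare_X(design$X, design$groups)
  prep$ybar <- mean(design$y)
  prep$yc <- design$y - prep$ybar
  prep
}

# Map solver coefficients (orthonormalized basis) back to the original
# column scale of the design.
backtransform_beta <- function(prep, design, beta_tilde) {
  d <- ncol(design$X)
  beta <- numeric(d)
  pos <- 0L
  for (g in seq_len(prep$G)) {
    cols <- which(design$groups == g)
    r <- prep$sizes[g]
    bt <- beta_tilde[pos + seq_len(r)]
    pos <- pos + r
    qg <- prep$qr_list[[g]]
    p <- length(cols)
    bstd <- numeric(p)
    if (any(bt != 0)) {
      if (is.null(qg)) {  # size-1 group: orthonormal basis is the column
        bstd <- bt
      } else {
        Rm <- qr.R(qg)[seq_len(r), , drop = FALSE]
        # R is r x p (pivoted); solve R[, 1:r] b = sqrt(n) bt in pivot order
        bp <- backsolve(Rm[, seq_len(r), drop = FALSE], sqrt(prep$n) * bt)
        bstd[qg$pivot[seq_len(r)]] <- bp
      }
    }
    beta[cols] <- bstd / prep$scl[cols]
  }
  names(beta) <- colnames(design$X)
  beta
}

#' Fit one penalized ARX(p) regression by group coordinate descent
#'
#' Minimizes `(1/2n) ||y - X beta||^2 + sum_g p_{lambda,a}(||beta_g||_2)`
#' over the grouped design, after centering/scaling the columns and
#' orthonormalizing each group (QR; the transform is inverted on output,
#' so reported coefficients are on the original series scale).  Each
#' group update is an exact SCAD threshold of the group's
#' partial-residual correlation; the objective is non-increasing across
#' updates.
#'
#' @param design a [build_lagged_design()] result (or any list with the
#'   same fields).
#' @param lambda penalty level (>= 0); `lambda = 0` with an
#'   overdetermined design recovers ordinary least squares.
#' @param a SCAD shape (> 2).
#' @param tol convergence threshold on the largest group-coefficient
#'   change per sweep.
#' @param max_iter sweep budget; non-convergence is flagged, not an error.
#' @param init optional warm-start coefficients (original scale).
#' @return object of class `arx_fit`: `coefficients` (original scale,
#'   named), `intercept`, `group_norms`, `selected` (logical per
#'   regulator, names = genes), `lambda`, `a`, `objective`, `iterations`,
#'   `converged`, `target`, `p`.
#' @export
fit_group_scad <- function(design, lambda, a = 3.7, tol = 1e-6,
                           max_iter = 10000, init = NULL) {
  if (a <= 2) stopf("SCAD shape a must exceed 2")
  if (lambda < 0) stopf("lambda must be non-negative")
  prep <- prepare_design(design)
  init_t <- NULL
  if (!is.null(init)) {
    # map original-scale warm start into the orthonormal basis
    bs <- init * prep$scl
    init_t <- unlist(lapply(seq_len(prep$G), function(g) {
      cols <- which(design$groups == g)
      qg <- prep$qr_list[[g]]
      if (is.null(qg)) return(bs[cols])
      r <- prep$sizes[g]
      (qr.R(qg)[seq_len(r), , drop = FALSE] %*%
         bs[cols][qg$pivot])[, 1] / sqrt(prep$n)
    }))
  }
  fit <- cpp_group_scad_path(prep$Xt, prep$yc, as.integer(prep$sizes),
                             lambda, a, tol, as.integer(max_iter),
                             dfmax = ncol(prep$Xt) + 1L, beta0 = init_t)
  bt <- fit$beta[, 1]
  beta <- backtransform_beta(prep, design, bt)
  sizes <- prep$sizes
  ends <- cumsum(sizes)
  gnorm <- vapply(seq_len(prep$G), function(g) {
    sqrt(sum(bt[(ends[g] - sizes[g] + 1):ends[g]]^2))
  }, numeric(1))
  names(gnorm) <- design$genes
  structure(list(
    coefficients = beta,
    intercept = prep$ybar - sum(prep$ctr * beta),
    group_norms = gnorm,
    selected = gnorm > 0,
    lambda = lambda, a = a,
    objective = fit$objective[1],
    iterations = fit$iterations[1],
    converged = fit$converged[1],
    target = design$target, p = design$p
  ), class = "arx_fit")
}

#' @export
print.arx_fit <- function(x, ...) {
  cat(sprintf("<arx_fit> target %s, p = %d, lambda = %.4g: %d/%d regulators selected%s\n",
              x$target, x$p, x$lambda, sum(x$selected), length(x$selected),
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Penalty path and information-criterion regulator selection
#'
#' Fits the group SCAD path from `lambda_max` (the largest group
#' correlation norm, at which every group is zero) down a log-spaced grid
#' with warm starts.  Each support (set of selected regulator groups)
#' encountered along the path is scored by the extended BIC on an
#' ordinary least-squares refit,
#' `EBIC = n log(RSS/n) + df log(n) + 2 gamma k log(G)`
#' with df = number of selected coefficients and k = number of selected
#' groups; the best support is then pruned by greedy backward elimination
#' while any single-group removal improves the criterion.  Scoring refits
#' rather than the penalized path estimates avoids two small-sample
#' artifacts: shrinkage inflating the RSS of good supports, and spurious
#' groups persisting as local minima of the nonconvex path once entered.
#' `gamma = 0` recovers the classical BIC; the default `gamma = 1` is the
#' usual conservative choice when candidate groups are as numerous as
#' observations.  The path stops before models can saturate (`dfmax`,
#' default `n - 2` coefficients), which keeps the criterion meaningful
#' when candidate regulators far outnumber time points.
#'
#' @param design a [build_lagged_design()] result.
#' @param nlambda grid size (>= 30).
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`.
#' @param a SCAD shape.
#' @param gamma extended-BIC weight (0 = classical BIC).
#' @param prune apply backward elimination to the winning support.
#' @param dfmax maximum selected coefficients before the path stops.
#' @param tol,max_iter solver controls.
#' @return list: `lambda` (grid value whose support won), `fit` (an
#'   `arx_fit` whose coefficients are the least-squares refit on the
#'   selected support), `path` (data.frame with `lambda`, `n_selected`,
#'   `rss`, `df`, `bic`, `converged`).
#' @export
select_lambda <- function(design, nlambda = 30, lambda_min_ratio = 0.01,
                          a = 3.7, gamma = 1, prune = TRUE, dfmax = NULL,
                          tol = 1e-6, max_iter = 10000) {
  prep <- prepare_design(design)
  core <- select_lambda_core(prep, nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio, a = a,
                             gamma = gamma, prune = prune, dfmax = dfmax,
                             tol = tol, max_iter = max_iter)
  beta <- backtransform_beta(prep, design, core$beta_tilde)
  gnorm <- core$group_norms
  names(gnorm) <- design$genes
  best_fit <- structure(list(
    coefficients = beta,
    intercept = prep$ybar - sum(prep$ctr * beta),
    group_norms = gnorm,
    selected = gnorm > 0,
    lambda = core$lambda, a = a,
    objective = core$rss / (2 * prep$n),
    iterations = core$iterations,
    converged = core$converged,
    target = design$target, p = design$p
  ), class = "arx_fit")
  list(lambda = core$lambda, fit = best_fit, path = core$path)
}

# Path + information-criterion selection on a prepared design (fields
# `Xt`, `yc`, `sizes`, `n`, `G`).  Shared by select_lambda() and
# infer_network_single(); the latter reuses one prepared X for every
# target, swapping in the target's centered response.
select_lambda_core <- function(prep, nlambda = 30, lambda_min_ratio = 0.01,
                               a = 3.7, gamma = 1, prune = TRUE,
                               dfmax = NULL, tol = 1e-6, max_iter = 10000) {
  if (nlambda < 30) stopf("the lambda grid must have at least 30 points")
  n <- prep$n
  if (is.null(dfmax)) dfmax <- max(1L, n - 2L)
  sizes <- prep$sizes
  ends <- cumsum(sizes)
  G <- prep$G
  corr <- crossprod(prep$Xt, prep$yc) / n
  lambda_max <- max(vapply(seq_len(G), function(g) {
    sqrt(sum(corr[(ends[g] - sizes[g] + 1):ends[g]]^2))
  }, numeric(1)))
  if (lambda_max <= 0) lambda_max <- 1e-3  # y orthogonal to every group
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))
  grid[1] <- grid[1] * (1 + 1e-8)  # roundoff guard: the path starts empty
  fit <- cpp_group_scad_path(prep$Xt, prep$yc, as.integer(sizes), grid, a,
                             tol, as.integer(max_iter),
                             dfmax = as.integer(dfmax))
  nc <- fit$n_computed
  group_cols <- lapply(seq_len(G), function(g) (ends[g] - sizes[g] + 1):ends[g])
  support_of <- function(b) {
    which(vapply(group_cols, function(cols) any(b[cols] != 0), logical(1)))
  }
  refit <- function(sel) {  # OLS on the support, orthonormal basis
    cols <- unlist(group_cols[sel])
    if (length(cols) == 0) {
      list(rss = sum(prep$yc^2), beta = numeric(ncol(prep$Xt)), cols = cols)
    } else {
      qf <- qr(prep$Xt[, cols, drop = FALSE])
      beta <- numeric(ncol(prep$Xt))
      beta[cols] <- qr.coef(qf, prep$yc)
      list(rss = sum(qr.resid(qf, prep$yc)^2), beta = beta, cols = cols)
    }
  }
  score_of <- function(sel) {
    df <- length(unlist(group_cols[sel]))
    n * log(max(refit(sel)$rss, 1e-12) / n) + df * log(n) +
      2 * gamma * length(sel) * log(G)
  }
  supports <- lapply(seq_len(nc), function(l) support_of(fit$beta[, l]))
  df_path <- fit$n_selected[seq_len(nc)]
  keys <- vapply(supports, paste, character(1), collapse = ",")
  uniq <- !duplicated(keys) & df_path <= dfmax
  if (!any(uniq)) uniq[1] <- TRUE
  scores <- rep(NA_real_, nc)
  scores[uniq] <- vapply(supports[uniq], score_of, numeric(1))
  best <- which.min(scores)
  sel <- supports[[best]]
  if (prune && length(sel) > 0) {
    cur <- scores[best]
    repeat {
      drops <- vapply(seq_along(sel), function(i) score_of(sel[-i]),
                      numeric(1))
      if (length(drops) == 0 || min(drops) >= cur) break
      cur <- min(drops)
      sel <- sel[-which.min(drops)]
    }
  }
  rf <- refit(sel)
  gnorm <- vapply(seq_len(G), function(g) {
    sqrt(sum(rf$beta[group_cols[[g]]]^2))
  }, numeric(1))
  rss_path <- vapply(seq_len(nc), function(l) {
    sum((prep$yc - prep$Xt %*% fit$beta[, l])^2)
  }, numeric(1))
  path <- data.frame(lambda = grid[seq_len(nc)], n_selected = df_path,
                     rss = rss_path, df = df_path, bic = scores,
                     converged = fit$converged[seq_len(nc)])
  list(selected = sel, lambda = grid[best], beta_tilde = rf$beta,
       group_norms = gnorm, rss = rf$rss, path = path,
       iterations = fit$iterations[best], converged = fit$converged[best])
}

#' Infer one directed network from a series matrix
#'
#' One penalized ARX(p) regression per target gene with BIC-selected
#' lambda; `B[i, j] = 1` when regulator i's lag group is selected for
#' target j (direction i -> j).  The diagonal records the target's own
#' autoregressive group but is excluded from reported edges.  Per-target
#' failures are caught: the column is left `NA` and the target listed in
#' the `failed_targets` attribute.
#'
#' @param series a [series_matrix()]; every gene must be non-constant.
#' @param p ARX order.
#' @param nlambda,lambda_min_ratio,a,gamma,prune,dfmax,tol,max_iter passed
#'   to [select_lambda()].
#' @return G x G binary matrix of class `binary_network` (dimnames =
#'   genes), attribute `lambda` (per-target selected lambda), attribute
#'   `failed_targets`.
#' @export
infer_network_single <- function(series, p, nlambda = 30,
                                 lambda_min_ratio = 0.01, a = 3.7,
                                 gamma = 1, prune = TRUE, dfmax = NULL,
                                 tol = 1e-6, max_iter = 10000) {
  m <- unclass(series)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  sds <- apply(m, 1, sd_pop)
  if (any(sds < 1e-12)) {
    stopf("constant gene in series: %s", ids[which(sds < 1e-12)[1]])
  }
  G <- nrow(m)
  Tn <- ncol(m)
  if (Tn <= p) stopf("series length T = %d must exceed the order p = %d", Tn, p)
  # the lagged X is identical for every target; prepare it once
  des1 <- build_lagged_design(series, ids[1], p)
  prep <- prepare_X(des1$X, des1$groups)
  rows <- (p + 1):Tn
  B <- matrix(NA_integer_, G, G, dimnames = list(ids, ids))
  lambdas <- stats::setNames(rep(NA_real_, G), ids)
  failed <- character(0)
  for (j in seq_len(G)) {
    res <- tryCatch({
      y <- m[j, rows]
      prep$ybar <- mean(y)
      prep$yc <- y - prep$ybar
      core <- select_lambda_core(prep, nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio,
                                 a = a, gamma = gamma, prune = prune,
                                 dfmax = dfmax, tol = tol,
                                 max_iter = max_iter)
      core
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, ids[j])
    } else {
      B[, j] <- 0L
      B[res$selected, j] <- 1L
      lambdas[j] <- res$lambda
    }
  }
  structure(B, class = c("binary_network", class(B)), p = p,
            lambda = lambdas, failed_targets = failed)
}

#' Directed edges of a binary network (diagonal excluded)
#' @param B a `binary_network` (or any square 0/1 matrix).
#' @return data.frame `source`, `target`.
#' @export
network_edges <- function(B) {
  ids <- rownames(B) %||% as.character(seq_len(nrow(B)))
  idx <- which(B == 1 & row(B) != col(B), arr.ind = TRUE)
  data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
             stringsAsFactors = FALSE)
}
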