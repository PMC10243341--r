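# Chambolle-Pock primal-dual solvers for the four regularized dynamic
# reconstruction problems:
#   TV    min_x   1/2||Ax - b||_F^2 + alpha ||grad3 x||_1
#   TGV   min_x   1/2||Ax - b||_F^2 + TGV^2_alpha(x)
#   LTV   min_L,S 1/2||A(L+S) - b||_F^2 + alpha ||grad3 S||_1 + beta ||L||_*
#   LTGV  min_L,S 1/2||A(L+S) - b||_F^2 + TGV^2_alpha(S)      + beta ||L||_*
# with TGV^2_alpha(x) = min_v alpha1 ||grad3 x - v||_1 + alpha0 ||E v||_1.
#
# Units convention. The scan geometry is specified in millimetres and
# the solver poses the objectives in millimetre attenuation units:
# images x in 1/mm, with the data term on the operator-normalized
# scale, min 1/2 ||A/||A|| x - b/||A|| ||_F^2 + regularizers(x). The
# normalization by the spectral norm ||A||_2 makes the fixed step
# sizes sigma = tau = 0.25 meaningful regardless of geometry, and the
# mm scale fixes what a regularization weight of order 1e-4..1e-2
# means for image gradients and singular values. Internally image
# arrays are carried in 1/cm (matching hu_to_mu()); the cm-to-mm slope
# is folded into the regularization weights, which leaves the
# minimizer unchanged. Steps are shrunk further only if
# sigma * tau * ||K||^2 > 1 would break convergence. The nuclear norm
# acts on the Casorati matrix of L (pixels x frames). In denoising
# mode (identity operator) the input is regularized on its own scale
# with no conversion.

#' Configure a regularized reconstruction
#'
#' @param method One of `"tv"`, `"tgv"`, `"ltv"`, `"ltgv"`.
#' @param alpha Regularization weight for the TV term (TV/LTV); typical
#'   range 1e-4 to 1e-2.
#' @param alpha1 First-order TGV weight (TGV/LTGV); defaults to `alpha`.
#' @param alpha0 Second-order TGV weight; default `2 * alpha1`.
#' @param beta Nuclear-norm weight for the low-rank component (default
#'   2).
#' @param sigma Dual step size (default 0.25).
#' @param tau Primal step size (default 0.25).
#' @param eps_tol Relative-change stopping tolerance (default 1e-6).
#' @param n_max Iteration cap (default 500).
#' @param temporal_weight Scale of the temporal gradient relative to the
#'   spatial ones (default 1).
#' @return Object of class `regularizer_config`.
#' @export
regularizer_config <- function(method = c("tv", "tgv", "ltv", "ltgv"),
                               alpha = 0.0025, alpha1 = alpha,
                               alpha0 = 2 * alpha1, beta = 2.0,
                               sigma = 0.25, tau = 0.25,
                               eps_tol = 1e-6, n_max = 500L,
                               temporal_weight = 1.0) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha1 > 0, alpha0 > 0, beta > 0, sigma > 0,
            tau > 0, eps_tol > 0, n_max >= 1L, temporal_weight > 0)
  structure(list(method = method, alpha = alpha, alpha1 = alpha1,
                 alpha0 = alpha0, beta = beta, sigma = sigma, tau = tau,
                 eps_tol = eps_tol, n_max = as.integer(n_max),
                 temporal_weight = temporal_weight),
            class = "regularizer_config")
}

#' @export
print.regularizer_config <- function(x, ...) {
  cat(sprintf("%s reconstruction config\n", toupper(x$method)))
  w <- if (x$method %in% c("tv", "ltv"))
    sprintf("alpha = %g", x$alpha)
  else sprintf("alpha1 = %g, alpha0 = %g", x$alpha1, x$alpha0)
  if (x$method %in% c("ltv", "ltgv")) w <- paste0(w, sprintf(", beta = %g", x$beta))
  cat(" ", w, "\n")
  cat(sprintf("  sigma = %g, tau = %g, eps_tol = %g, n_max = %d\n",
              x$sigma, x$tau, x$eps_tol, x$n_max))
  invisible(x)
}

# --- internal linear-operator plumbing --------------------------------

# forward/adjoint pair over all frames; geom = NULL gives the identity
# operator (denoising mode) with unit norm
make_frame_ops <- function(geom, nt) {
  if (is.null(geom)) {
    return(list(
      A = function(x) x, At = function(y) y, opnorm = 1,
      sino_dim = NULL))
  }
  Amat <- system_matrix(geom)
  n <- geom$grid_size
  nd <- geom$n_detectors; nv <- geom$n_views
  list(
    A = function(x) {
      y <- array(0, dim = c(nd, nv, nt))
      xm <- matrix(x, nrow = n * n)
      ym <- as.matrix(Amat %*% xm)
      array(ym, dim = c(nd, nv, nt))
    },
    At = function(y) {
      ym <- matrix(y, nrow = nd * nv)
      xm <- as.matrix(Matrix::crossprod(Amat, ym))
      array(xm, dim = c(n, n, nt))
    },
    opnorm = attr(Amat, "opnorm"),
    sino_dim = c(nd, nv))
}

lin_comb <- function(a, xs, b, ys) mapply(function(x, y) a * x + b * y,
                                          xs, ys, SIMPLIFY = FALSE)

# spectral norm of the composite operator K by power iteration,
# deterministic start; cached per problem signature
composite_opnorm <- function(K, Kt, primal_template, key) {
  if (!is.null(.perfct_cache[[key]])) return(.perfct_cache[[key]])
  v <- lapply(primal_template, function(z) {
    array(sin(seq_len(length(z))), dim = dim(z))
  })
  nrmsq <- function(xs) sum(vapply(xs, function(z) sum(z^2), 0))
  v <- lapply(v, function(z) z / sqrt(nrmsq(v)))
  lam <- 1
  for (it in seq_len(30L)) {
    w <- Kt(K(v))
    lam <- sum(mapply(function(a, b) sum(a * b), w, v))
    nw <- sqrt(nrmsq(w))
    if (nw == 0) break
    v <- lapply(w, function(z) z / nw)
  }
  out <- sqrt(abs(lam))
  .perfct_cache[[key]] <- out
  out
}

casorati <- function(x) matrix(x, nrow = prod(dim(x)[1:2]))

#' Reconstruct a dynamic series with spatiotemporal regularization
#'
#' Solves the selected objective with the Chambolle-Pock primal-dual
#' algorithm: the quadratic data term is dualized (prox
#' `q <- (q + sigma(Ax - b)) / (1 + sigma)`), each l1 term contributes a
#' dual variable projected onto its magnitude ball, and the nuclear
#' norm of the low-rank component enters through singular-value
#' thresholding of its Casorati (pixels x frames) matrix. Iterations
#' start from the Ram-Lak FBP series (low-rank start for LTV/LTGV, with
#' the sparse component at zero) and stop when the relative Frobenius
#' change of the image falls below `eps_tol` or after `n_max`
#' iterations.
#'
#' @param sino_series 3-D array (detector, view, frame) of line
#'   integrals; with `geom = NULL`, a 3-D image array (or
#'   [dynamic_series()]) to be denoised with the identity forward
#'   operator.
#' @param geom A [scan_geometry()], or `NULL` for denoising mode.
#' @param config A [regularizer_config()].
#' @param dt Frame spacing in s for the returned series.
#' @param init Optional initial image array (1/cm) overriding the FBP
#'   initializer.
#' @param objective_every Cadence (in iterations) of objective
#'   evaluation for the report history; the objective costs an extra
#'   operator application, so it is not tracked every iteration by
#'   default (default 10; the final iterate is always evaluated).
#' @return A list of class `recon_result`: `series` (a
#'   [dynamic_series()] in HU; in denoising mode, in the input units),
#'   `mu` (the solution array in solver units), `decomposition` (for
#'   LTV/LTGV, list with `L` and `S` arrays in solver units, else
#'   `NULL`), and `report` (class `solve_report` with `n_iters`,
#'   `converged`, `relative_change_history`, `objective_history`, and
#'   the step sizes actually used).
#' @export
reconstruct <- function(sino_series, geom, config, dt = 1.0,
                        init = NULL, objective_every = 10L) {
  stopifnot(inherits(config, "regularizer_config"))
  if (inherits(sino_series, "dynamic_series")) {
    if (!is.null(geom)) stop("dynamic_series input requires geom = NULL")
    dt <- sino_series$dt
    sino_series <- sino_series$data
  }
  stopifnot(length(dim(sino_series)) == 3L)
  nt <- dim(sino_series)[3]
  if (nt == 1L && config$temporal_weight > 0)
    warning("single-frame series: temporal gradient component is zero")
  ops <- make_frame_ops(geom, nt)
  if (!is.null(geom) &&
      !all(dim(sino_series)[1:2] == c(geom$n_detectors, geom$n_views)))
    stop("sinogram dimensions do not match geometry")

  cnorm <- ops$opnorm
  As <- function(x) ops$A(x) / cnorm
  Ast <- function(y) ops$At(y) / cnorm
  bs <- sino_series / cnorm
  tw <- config$temporal_weight
  g3 <- function(x) grad3(x, tw, warn_single_frame = FALSE)
  d3 <- function(p) div3(p, tw)
  Ev <- function(v) sym_grad(v, tw)
  Et <- function(r) sym_div(r, tw)

  # initializer in solver units; with a scan geometry the image is
  # supported on the reconstruction circle (outside pixels are not
  # covered by every fan and stay at zero attenuation)
  if (is.null(init)) {
    x0 <- if (is.null(geom)) sino_series
          else fbp_frames_mu(sino_series, geom)
  } else x0 <- init
  img_dim <- dim(x0)
  if (!is.null(geom)) {
    supp <- array(rep(fov_mask(geom), img_dim[3]), img_dim)
    x0 <- x0 * supp
  } else supp <- NULL
  mask_supp <- function(z) if (is.null(supp)) z else z * supp

  method <- config$method
  lowrank <- method %in% c("ltv", "ltgv")
  tgvlike <- method %in% c("tgv", "ltgv")
  # regularizers act on the image in 1/mm; internal arrays are 1/cm,
  # so fold the cm-to-mm slope 0.1 into the weights (identity mode:
  # the input's own scale)
  kappa <- if (is.null(geom)) 1 else 0.1
  a1 <- kappa * if (tgvlike) config$alpha1 else config$alpha
  a0 <- kappa * config$alpha0
  beta_s <- kappa * config$beta

  zero_img <- array(0, img_dim)
  zero_vec <- array(0, c(img_dim, 3L))
  zero_ten <- array(0, c(img_dim, 3L, 3L))

  # primal blocks, K, Kt per method; the "image" for the stopping rule
  # is x (TV/TGV) or L + S (LTV/LTGV)
  if (!lowrank) {
    primal <- list(x = x0)
    if (tgvlike) primal$v <- zero_vec
    K <- function(pr) {
      out <- list(q = As(pr$x))
      if (tgvlike) {
        out$p <- g3(pr$x) - pr$v
        out$r <- Ev(pr$v)
      } else out$p <- g3(pr$x)
      out
    }
    Kt <- function(du) {
      out <- list(x = Ast(du$q) - d3(du$p))
      if (tgvlike) out$v <- -du$p - Et(du$r)
      out
    }
  } else {
    primal <- list(L = x0, S = zero_img)
    if (tgvlike) primal$v <- zero_vec
    K <- function(pr) {
      out <- list(q = As(pr$L + pr$S))
      if (tgvlike) {
        out$p <- g3(pr$S) - pr$v
        out$r <- Ev(pr$v)
      } else out$p <- g3(pr$S)
      out
    }
    Kt <- function(du) {
      aq <- Ast(du$q)
      out <- list(L = aq, S = aq - d3(du$p))
      if (tgvlike) out$v <- -du$p - Et(du$r)
      out
    }
  }

  key <- paste("opnormK", if (is.null(geom)) "id" else geom_key(geom),
               method, tw, paste(img_dim, collapse = "x"), sep = "|")
  LK <- composite_opnorm(K, Kt, primal, key)
  sigma <- config$sigma; tau <- config$tau
  if (sigma * tau * LK^2 > 1) {
    f <- sqrt(0.99 / (sigma * tau * LK^2))
    sigma <- sigma * f; tau <- tau * f
  }

  dual <- lapply(K(primal), function(z) z * 0)
  bar <- primal
  image_of <- function(pr) if (lowrank) pr$L + pr$S else pr$x
  rel_hist <- numeric(0)
  obj_hist <- numeric(0)
  obj_iters <- integer(0)
  converged <- FALSE
  n_iters <- 0L

  for (it in seq_len(config$n_max)) {
    n_iters <- it
    Kb <- K(bar)
    dual$q <- (dual$q + sigma * (Kb$q - bs)) / (1 + sigma)
    dual$p <- project_ball_field(dual$p + sigma * Kb$p, a1)
    if (tgvlike)
      dual$r <- project_ball_field(dual$r + sigma * Kb$r, a0)
    step <- Kt(dual)
    newp <- primal
    for (nm in names(primal)) newp[[nm]] <- primal[[nm]] - tau * step[[nm]]
    # primal prox: support constraint on image blocks, singular-value
    # thresholding on the low-rank Casorati matrix
    if (lowrank) {
      newp$L <- mask_supp(array(svt(casorati(newp$L), tau * beta_s),
                                img_dim))
      newp$S <- mask_supp(newp$S)
    } else {
      newp$x <- mask_supp(newp$x)
    }
    # relative change of the composed image
    xi_old <- image_of(primal); xi_new <- image_of(newp)
    den <- sqrt(sum(xi_old^2))
    rel <- if (den > 0) sqrt(sum((xi_new - xi_old)^2)) / den
           else sqrt(sum(xi_new^2))
    rel_hist[it] <- rel
    last <- (rel < config$eps_tol) || it == config$n_max
    if (it %% objective_every == 0L || last) {
      obj_hist <- c(obj_hist, pd_objective(newp, bs, As, g3, Ev,
                                           config, a1 = a1, a0 = a0,
                                           beta_s = beta_s))
      obj_iters <- c(obj_iters, it)
    }
    if (!is.finite(rel) || rel > 1e6)
      stop("primal-dual iteration diverged; step sizes sigma/tau likely ",
           "violate sigma * tau * ||K||^2 <= 1")
    bar <- lin_comb(2, newp, -1, primal)
    primal <- newp
    if (rel < config$eps_tol) { converged <- TRUE; break }
  }

  xhat <- image_of(primal)
  report <- structure(list(
    n_iters = n_iters, converged = converged,
    relative_change_history = rel_hist,
    objective_history = obj_hist, objective_iters = obj_iters,
    sigma = sigma, tau = tau, opnorm_K = LK,
    opnorm_A = cnorm), class = "solve_report")
  series <- if (is.null(geom)) dynamic_series(xhat, dt = dt)
            else dynamic_series(mu_to_hu(xhat), dt = dt)
  structure(list(
    series = series, mu = xhat,
    decomposition = if (lowrank) list(L = primal$L, S = primal$S) else NULL,
    report = report, config = config), class = "recon_result")
}

# FBP initializer in attenuation units, per frame
fbp_frames_mu <- function(sino_series, geom) {
  nt <- dim(sino_series)[3]
  out <- array(0, dim = c(geom$grid_size, geom$grid_size, nt))
  for (f in seq_len(nt))
    out[, , f] <- fbp_reconstruct(sino_series[, , f], geom, "ram-lak")
  out
}

# objective of the current iterate on the preconditioned problem; for
# the TGV family this uses the solver's running v (an upper bound on
# the exact inner minimum)
pd_objective <- function(pr, bs, As, g3, Ev, config, a1, a0, beta_s) {
  lowrank <- !is.null(pr$L)
  x <- if (lowrank) pr$L + pr$S else pr$x
  res <- As(x) - bs
  obj <- 0.5 * sum(res^2)
  sparse_part <- if (lowrank) pr$S else pr$x
  if (is.null(pr$v)) {
    obj <- obj + a1 * sum_field_mag(g3(sparse_part))
  } else {
    obj <- obj + a1 * sum_field_mag(g3(sparse_part) - pr$v) +
      a0 * sum_field_mag(Ev(pr$v))
  }
  if (lowrank) obj <- obj + beta_s * sum(svd(casorati(pr$L))$d)
  obj
}

sum_field_mag <- function(z) {
  d <- dim(z)
  np <- prod(d[1:3])
  sum(sqrt(rowSums(matrix(z, nrow = np)^2)))
}

#' @export
print.recon_result <- function(x, ...) {
  d <- dim(x$mu)
  cat(sprintf("%s reconstruction: %d x %d px, %d frames\n",
              toupper(x$config$method), d[1], d[2], d[3]))
  print(x$report)
  invisible(x)
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("primal-dual solve: %d iterations, %s\n", x$n_iters,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  final relative change %.3g, steps sigma = %.3g tau = %.3g\n",
              utils::tail(x$relative_change_history, 1), x$sigma, x$tau))
  invisible(x)
}

#' Evaluate a reconstruction objective
#'
#' Evaluates the selected objective in the solver's units (data term on
#' the operator-normalized scale, image regularized in 1/mm) — the same
#' objective [reconstruct()] minimizes. For the TGV family the inner
#' minimization over the auxiliary field v is solved to a relative
#' tolerance of 1e-8.
#'
#' @param x Image array (x, y, frame) in solver units, or for LTV/LTGV
#'   a list with components `L` and `S`.
#' @param sino_series Data array matching `geom` (or image array in
#'   denoising mode).
#' @param geom A [scan_geometry()] or `NULL`.
#' @param config A [regularizer_config()].
#' @return Scalar objective value.
#' @export
objective_value <- function(x, sino_series, geom, config) {
  stopifnot(inherits(config, "regularizer_config"))
  lowrank <- config$method %in% c("ltv", "ltgv")
  tgvlike <- config$method %in% c("tgv", "ltgv")
  if (lowrank && !is.list(x)) stop("LTV/LTGV objective needs list(L, S)")
  img <- if (lowrank) x$L + x$S else x
  nt <- dim(img)[3]
  ops <- make_frame_ops(geom, nt)
  res <- (ops$A(img) - sino_series) / ops$opnorm
  obj <- 0.5 * sum(res^2)
  kappa <- if (is.null(geom)) 1 else 0.1
  tw <- config$temporal_weight
  sparse_part <- if (lowrank) x$S else x
  g <- grad3(sparse_part, tw, warn_single_frame = FALSE)
  if (!tgvlike) {
    obj <- obj + kappa * config$alpha * sum_field_mag(g)
  } else {
    obj <- obj + kappa * tgv_value(sparse_part, config$alpha1,
                                   config$alpha0, tw)
  }
  if (lowrank)
    obj <- obj + kappa * config$beta * sum(svd(casorati(x$L))$d)
  obj
}

#' Second-order total generalized variation of a dynamic image
#'
#' `TGV^2(x) = min_v alpha1 ||grad3 x - v||_1 + alpha0 ||E v||_1`,
#' evaluated by solving the inner convex problem over v with a
#' Chambolle-Pock iteration.
#'
#' @param x 3-D image array (x, y, frame).
#' @param alpha1,alpha0 First- and second-order weights.
#' @param temporal_weight Temporal gradient scale.
#' @param tol Relative-change tolerance for the inner solve (default
#'   1e-8).
#' @param n_max Inner iteration cap (default 3000).
#' @return Scalar TGV value.
#' @export
tgv_value <- function(x, alpha1, alpha0, temporal_weight = 1.0,
                      tol = 1e-8, n_max = 3000L) {
  g <- grad3(x, temporal_weight, warn_single_frame = FALSE)
  v <- g * 0
  r <- array(0, c(dim(x), 3L, 3L))
  LE <- sqrt(12) * max(1, temporal_weight)
  s <- 0.99 / LE
  vbar <- v
  for (it in seq_len(n_max)) {
    r <- project_ball_field(r + s * sym_grad(vbar, temporal_weight),
                            alpha0)
    w <- v + s * sym_div(r, temporal_weight)
    vnew <- g + soft_threshold_field(w - g, s * alpha1)
    rel <- sqrt(sum((vnew - v)^2)) / max(sqrt(sum(v^2)), 1e-30)
    vbar <- 2 * vnew - v
    v <- vnew
    if (rel < tol) break
  }
  alpha1 * sum_field_mag(g - v) + alpha0 *
    sum_field_mag(sym_grad(v, temporal_weight))
}
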