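# Gaussian-process regression of the relative CTV position on geometric
# features: three independent per-axis GPs with an anisotropic (ARD)
# squared-exponential kernel plus observation noise. Hyperparameters are
# found by marginal-likelihood maximization with restarts.

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

gp_kernel_cross <- function(A, B, ell, sf2) {
  # A: n x p, B: m x p (both standardized); returns n x m covariance
  n <- nrow(A); m <- nrow(B)
  W <- matrix(0, n, m)
  for (j in seq_len(ncol(A))) {
    W <- W + outer(A[, j], B[, j], "-")^2 / ell[j]^2
  }
  sf2 * exp(-0.5 * W)
}

# Negative log marginal likelihood and its gradient in
# theta = (log ell_1..p, log sf, log sn), with a one-step cache so optim's
# fn/gr pair does the heavy algebra once per point.
gp_objective <- function(D2, y) {
  p <- length(D2)
  n <- length(y)
  cache <- new.env(parent = emptyenv())
  compute <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) return(invisible())
    ell2 <- exp(2 * theta[seq_len(p)])
    sf2 <- exp(2 * theta[p + 1L])
    sn2 <- exp(2 * theta[p + 2L])
    W <- matrix(0, n, n)
    for (j in seq_len(p)) W <- W + D2[[j]] / ell2[j]
    Kse <- sf2 * exp(-0.5 * W)
    K <- Kse
    diag(K) <- diag(K) + sn2 + 1e-8
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) {
      cache$theta <- theta
      cache$bad <- TRUE
      return(invisible())
    }
    alpha <- backsolve(L, forwardsolve(t(L), y))
    nll <- as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
    Kinv <- chol2inv(L)
    A <- Kinv - tcrossprod(alpha)          # dNLL/dK = A/2
    g <- numeric(p + 2L)
    for (j in seq_len(p)) {                # dK/dlog ell_j = Kse * D2_j / ell_j^2
      g[j] <- 0.5 * sum(A * (Kse * (D2[[j]] / ell2[j])))
    }
    g[p + 1L] <- sum(A * Kse)              # dK/dlog sf = 2 Kse
    g[p + 2L] <- sn2 * sum(diag(A))        # dK/dlog sn = 2 sn2 I
    cache$theta <- theta
    cache$bad <- FALSE
    cache$nll <- nll
    cache$grad <- g
    invisible()
  }
  list(
    fn = function(theta) {
      compute(theta)
      if (isTRUE(cache$bad)) 1e10 else cache$nll
    },
    gr = function(theta) {
      compute(theta)
      if (isTRUE(cache$bad)) rep(0, p + 2L) else cache$grad
    })
}

gp_fit_axis <- function(Xs, y, n_restarts, seed) {
  n <- nrow(Xs); p <- ncol(Xs)
  ym <- mean(y)
  ys <- sd(y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  yc <- (y - ym) / ys
  D2 <- lapply(seq_len(p), function(j) outer(Xs[, j], Xs[, j], "-")^2)
  lower <- c(rep(log(0.05), p), log(1e-3), log(1e-4))
  upper <- c(rep(log(50), p), log(20), log(5))
  base <- c(rep(0, p), log(max(sd(yc), 1e-2)), log(0.3))
  inits <- with_preserved_seed(seed, {
    cbind(base, vapply(seq_len(max(0L, n_restarts - 1L)),
                       function(i) base + rnorm(p + 2L, sd = 0.8),
                       numeric(p + 2L)))
  })
  obj <- gp_objective(D2, yc)
  best <- NULL
  best_val <- Inf
  for (i in seq_len(ncol(inits))) {
    th0 <- pmin(pmax(inits[, i], lower), upper)
    fit <- tryCatch(
      optim(th0, obj$fn, obj$gr, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < best_val) {
      best_val <- fit$value
      best <- fit$par
    }
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  ell <- exp(best[seq_len(p)])
  sf2 <- exp(2 * best[p + 1L])
  sn2 <- exp(2 * best[p + 2L])
  W <- matrix(0, n, n)
  for (j in seq_len(p)) W <- W + D2[[j]] / ell[j]^2
  K <- sf2 * exp(-0.5 * W)
  diag(K) <- diag(K) + sn2 + 1e-8
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  list(ell = ell, sf2 = sf2, sn2 = sn2, alpha = alpha, L = L,
       y_mean = ym, y_sd = ys, nll = best_val)
}

#' Fit the per-axis Gaussian-process margin model
#'
#' Trains three independent GPs (one per patient-frame axis) mapping the seven
#' geometric features to the relative CTV position. Kernel: anisotropic
#' squared-exponential with per-feature length scales plus observation noise;
#' hyperparameters by marginal-likelihood maximization from `n_restarts`
#' deterministic restarts. Features are standardized to zero mean / unit
#' variance on the training data.
#'
#' @param X n x 7 matrix (or data frame) of features, n >= 10, no missing values.
#' @param Y n x 3 matrix of relative CTV positions (mm), columns dx, dy, dz.
#' @param n_restarts optimizer restarts per axis (default 5).
#' @param seed integer seed controlling the restart jitter.
#' @return A `gpr_model`.
#' @export
fit_gpr <- function(X, Y, n_restarts = 5L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 10L) stop("insufficient training data (need n >= 10)")
  if (nrow(X) != nrow(Y) || ncol(Y) != 3L) stop("X and Y dimensions disagree")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite training inputs")
  Xm <- colMeans(X)
  Xsd <- apply(X, 2, sd)
  Xsd[!is.finite(Xsd) | Xsd < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, Xm), 2, Xsd, "/")
  axes <- lapply(1:3, function(k) gp_fit_axis(Xs, Y[, k], n_restarts, seed + k))
  names(axes) <- c("dx", "dy", "dz")
  structure(list(X_mean = Xm, X_sd = Xsd, Xs = Xs, axes = axes,
                 n = nrow(X),
                 feature_names = colnames(X) %||% paste0("f", seq_len(ncol(X)))),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf("gpr_model: %d training points, %d features; per-axis noise sd (mm): %s\n",
              x$n, ncol(x$Xs),
              paste(sprintf("%.2f", vapply(x$axes, function(a) sqrt(a$sn2) * a$y_sd, 0)),
                    collapse = ", ")))
  invisible(x)
}

#' Predict the relative CTV position with uncertainty
#'
#' Per-axis predictive mean and standard deviation at one or more feature
#' vectors. The predictive variance includes the fitted observation noise, so
#' `mu +/- 2*sigma` is a prediction interval for a new treatment-day position.
#'
#' @param model a fitted [fit_gpr()] model.
#' @param x length-7 feature vector, or an m x 7 matrix.
#' @return list with `mu` and `sigma`: named mm triples (or m x 3 matrices).
#' @export
predict_with_uncertainty <- function(model, x) {
  if (!inherits(model, "gpr_model")) stop("untrained model")
  single <- is.null(dim(x))
  Xq <- if (single) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(Xq) != ncol(model$Xs)) stop("feature dimension mismatch")
  if (any(!is.finite(Xq))) stop("non-finite query features")
  Xqs <- sweep(sweep(Xq, 2, model$X_mean), 2, model$X_sd, "/")
  mu <- sig <- matrix(NA_real_, nrow(Xq), 3L,
                      dimnames = list(NULL, c("dx", "dy", "dz")))
  for (k in 1:3) {
    ax <- model$axes[[k]]
    Ks <- gp_kernel_cross(model$Xs, Xqs, ax$ell, ax$sf2)   # n x m
    mu_s <- drop(crossprod(Ks, ax$alpha))
    V <- forwardsolve(t(ax$L), Ks)
    var_s <- pmax(ax$sf2 + ax$sn2 - colSums(V^2), 1e-12)
    mu[, k] <- ax$y_mean + ax$y_sd * mu_s
    sig[, k] <- ax$y_sd * sqrt(var_s)
  }
  if (single) list(mu = mu[1, ], sigma = sig[1, ]) else list(mu = mu, sigma = sig)
}

#' Build the four digital-twin margin sets from a prediction
#'
#' The predicted treatment-day displacement is `d = mu - planning_rel_pos`
#' per axis; the base margin on each axis is `|d|`, applied symmetrically to
#' both directions of that axis. Four candidate margin sets are produced at
#' uncertainty offsets `{-0.5, 0, +0.5, +1.0} * sigma` (configurable), each
#' component then clamped to the physical bounds (default 1.5-5.0 mm).
#'
#' @param mu predicted relative CTV position (mm triple).
#' @param sigma predictive standard deviation (mm triple, > 0).
#' @param planning_rel_pos relative CTV position on the planning image
#'   ([relative_ctv_position()]).
#' @param cfg list with `offsets` (default `c(-0.5, 0, 0.5, 1)`), `lower`
#'   (default 1.5) and `upper` (default 5).
#' @return named list of [margin_set()]s, one per offset (`"DT-0.5sigma"`,
#'   `"DT"`, `"DT+0.5sigma"`, `"DT+1.0sigma"` for the defaults).
#' @export
build_margin_sets <- function(mu, sigma, planning_rel_pos,
                              cfg = list()) {
  offsets <- cfg$offsets %||% c(-0.5, 0, 0.5, 1)
  lower <- cfg$lower %||% 1.5
  upper <- cfg$upper %||% 5.0
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  rel <- as.numeric(planning_rel_pos)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  d <- abs(mu - rel)
  out <- lapply(offsets, function(off) {
    v <- clamp_margin(d + off * sigma, lower, upper)
    margin_set(left = v[1], right = v[1], anterior = v[2], posterior = v[2],
               superior = v[3], inferior = v[3])
  })
  names(out) <- vapply(offsets, function(off) {
    if (abs(off) < 1e-12) "DT" else sprintf("DT%+.1fsigma", off)
  }, character(1))
  out
}

#' Save a fitted margin model to JSON
#' @param model a `gpr_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_gpr_model <- function(model, path) {
  obj <- list(
    X_mean = model$X_mean, X_sd = model$X_sd,
    Xs = model$Xs, n = model$n, feature_names = model$feature_names,
    axes = lapply(model$axes, function(a) {
      list(ell = a$ell, sf2 = a$sf2, sn2 = a$sn2,
           y_mean = a$y_mean, y_sd = a$y_sd, alpha = a$alpha)
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a margin model saved by [save_gpr_model()]
#' @param path JSON file written by [save_gpr_model()].
#' @return A `gpr_model` (Cholesky factors are recomputed deterministically).
#' @export
load_gpr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Xs <- as.matrix(obj$Xs)
  axes <- lapply(obj$axes, function(a) {
    K <- gp_kernel_cross(Xs, Xs, a$ell, a$sf2)
    diag(K) <- diag(K) + a$sn2 + 1e-8
    list(ell = a$ell, sf2 = a$sf2, sn2 = a$sn2,
         alpha = as.numeric(a$alpha), L = chol(K),
         y_mean = a$y_mean, y_sd = a$y_sd)
  })
  structure(list(X_mean = as.numeric(obj$X_mean), X_sd = as.numeric(obj$X_sd),
                 Xs = Xs, axes = axes, n = obj$n,
                 feature_names = obj$feature_names),
            class = "gpr_model")
}
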