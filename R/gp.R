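#' Precompute pairwise kernel ingredients for a design space
#'
#' Computes, once, the full Tanimoto similarity matrix over the role-prefixed
#' binary blocks and the squared-distance matrix over scaled conditions for
#' all candidates. Kernel matrices for any hyperparameters are then cheap
#' elementwise assemblies; campaigns reuse one cache across iterations.
#'
#' @param space a [design_space()].
#' @return list of class `cibo_kernel_cache` with matrices `T` and `D2`.
#' @export
kernel_cache <- function(space) {
  feats <- encode_candidates(space)
  Tm <- .tanimoto_cross(feats$binary, feats$binary)
  D2 <- if (ncol(feats$numeric) > 0L) {
    .sq_dists(feats$numeric, feats$numeric)
  } else {
    matrix(0, nrow(Tm), ncol(Tm))
  }
  structure(list(T = Tm, D2 = D2, n = nrow(Tm)), class = "cibo_kernel_cache")
}

.assemble_kernel <- function(cache, rows, cols, hp) {
  hp$outputscale * cache$T[rows, cols, drop = FALSE] *
    exp(-0.5 * cache$D2[rows, cols, drop = FALSE] / hp$lengthscale^2)
}

.chol_jitter <- function(M, jitter = 1e-8, max_jitter = 1e-2) {
  j <- jitter
  repeat {
    L <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
    if (j >= max_jitter) {
      stop("matrix not positive definite even after jitter escalation to ",
           format(max_jitter))
    }
    j <- j * 10
  }
}

# negative log marginal likelihood for standardized targets
.gp_nlml <- function(theta, cache, train, y, has_cond, noise_floor) {
  hp <- .theta_to_hp(theta, has_cond, noise_floor)
  K <- .assemble_kernel(cache, train, train, hp)
  Ky <- K + diag(hp$noise, length(train))
  L <- tryCatch(chol(Ky), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  a <- backsolve(L, backsolve(L, y, transpose = TRUE))
  as.numeric(0.5 * sum(y * a) + sum(log(diag(L))) +
               0.5 * length(y) * log(2 * pi))
}

.theta_to_hp <- function(theta, has_cond, noise_floor) {
  if (has_cond) {
    list(outputscale = exp(theta[1]), lengthscale = exp(theta[2]),
         noise = max(exp(theta[3]), noise_floor))
  } else {
    list(outputscale = exp(theta[1]), lengthscale = 1,
         noise = max(exp(theta[2]), noise_floor))
  }
}

#' Fit the Gaussian-process surrogate
#'
#' Gaussian-process regression of observed yields on encoded candidates with
#' the Tanimoto-times-squared-exponential kernel. Yields are standardized
#' internally (prior mean = training mean); hyperparameters are set by
#' multi-restart maximization of the log marginal likelihood unless fixed
#' values are supplied.
#'
#' @param space a [design_space()].
#' @param train integer indices of the observed candidates.
#' @param yields observed yields in percent; defaults to the space's lookup
#'   yields at `train`.
#' @param settings list of fit options: `optimize` (default TRUE), `restarts`
#'   (default 5), `hyperparams` (fixed `outputscale`, `lengthscale`, `noise`
#'   when `optimize = FALSE`), `standardize` (default TRUE), `prior_mean`
#'   (default: training mean), `noise_floor` (jitter floor, default 1e-6),
#'   `seed` (restart reproducibility, default 1).
#' @param cache optional [kernel_cache()] for the space, reused if given.
#' @return An object of class `cibo_gp` with cached factorization state
#'   enabling O(n^2) posterior queries.
#' @export
fit_surrogate <- function(space, train, yields = NULL, settings = list(),
                          cache = NULL) {
  if (length(train) < 1L) {
    stop("empty training set: prior-only prediction is not a fit")
  }
  if (is.null(yields)) yields <- space$candidates$yield[train]
  if (length(yields) != length(train)) {
    stop("number of training candidates and yields differ")
  }
  if (anyNA(yields) || any(yields < 0 | yields > 100)) {
    stop("training yields must be in [0, 100]")
  }
  s <- modifyList(list(
    optimize = TRUE, restarts = 5L, hyperparams = NULL, standardize = TRUE,
    prior_mean = NULL, noise_floor = 1e-6, seed = 1L
  ), settings)
  if (is.null(cache)) cache <- kernel_cache(space)
  has_cond <- length(space$conditions) > 0L

  mu_y <- if (is.null(s$prior_mean)) mean(yields) else s$prior_mean
  sd_y <- if (s$standardize) stats::sd(yields) else 1
  if (is.na(sd_y) || sd_y < 1e-8) sd_y <- 1
  y <- (yields - mu_y) / sd_y

  if (s$optimize) {
    n_par <- if (has_cond) 3L else 2L
    starts <- matrix(0, nrow = s$restarts, ncol = n_par)
    if (s$restarts > 1L) {
      old <- .save_rng_state()
      set.seed(s$seed %% 2147483647L)
      starts[-1L, ] <- matrix(
        stats::runif((s$restarts - 1L) * n_par, -2, 2), ncol = n_par
      )
      .restore_rng_state(old)
    }
    starts[1L, ] <- if (has_cond) log(c(1, 0.5, 0.1)) else log(c(1, 0.1))
    best <- NULL
    for (r in seq_len(s$restarts)) {
      fit <- tryCatch(
        stats::optim(starts[r, ], .gp_nlml, cache = cache, train = train,
                     y = y, has_cond = has_cond, noise_floor = s$noise_floor,
                     method = "L-BFGS-B", lower = log(1e-6), upper = log(1e3)),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("hyperparameter optimization failed on all restarts")
    hp <- .theta_to_hp(best$par, has_cond, s$noise_floor)
  } else {
    if (is.null(s$hyperparams)) {
      stop("optimize = FALSE requires settings$hyperparams")
    }
    hp <- modifyList(list(outputscale = 1, lengthscale = 1, noise = 1e-6),
                     s$hyperparams)
    hp$noise <- max(hp$noise, s$noise_floor)
  }

  K <- .assemble_kernel(cache, train, train, hp)
  fac <- tryCatch(
    list(L = chol(K + diag(hp$noise, length(train))), jitter = 0),
    error = function(e) NULL
  )
  if (is.null(fac)) {
    fac <- tryCatch(.chol_jitter(K + diag(hp$noise, length(train))),
                    error = function(e) NULL)
    if (is.null(fac)) {
      dup <- which(duplicated(round(cache$T[train, train, drop = FALSE], 12),
                              MARGIN = 1))
      stop(sprintf(
        "singular kernel matrix after jitter escalation (duplicate rows: %s)",
        paste(train[dup], collapse = ", ")
      ))
    }
  }
  L <- fac$L
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  structure(
    list(space_name = space$name, train = train, yields = yields,
         hyperparams = hp, noise_variance = hp$noise * sd_y^2,
         mu_y = mu_y, sd_y = sd_y, L = L, alpha = alpha, cache = cache),
    class = "cibo_gp"
  )
}

#' @export
print.cibo_gp <- function(x, ...) {
  cat(sprintf(
    "<GP surrogate: %d training points; outputscale=%.3g, lengthscale=%.3g, noise=%.3g>\n",
    length(x$train), x$hyperparams$outputscale, x$hyperparams$lengthscale,
    x$hyperparams$noise
  ))
  invisible(x)
}

#' Posterior mean and standard deviation at candidates
#'
#' Standard GP posterior over the latent (noise-free) yield surface: as the
#' observation noise goes to zero, the mean interpolates the training yields
#' and the standard deviation vanishes at training inputs.
#'
#' @param model a fitted [fit_surrogate()] model.
#' @param indices candidate indices to predict at.
#' @return list of class `cibo_posterior` with numeric vectors `mu` and
#'   `sigma` (percent-yield scale).
#' @export
posterior_predict <- function(model, indices) {
  Kxt <- .assemble_kernel(model$cache, indices, model$train, model$hyperparams)
  mu <- model$mu_y + model$sd_y * as.numeric(Kxt %*% model$alpha)
  V <- backsolve(model$L, t(Kxt), transpose = TRUE)
  var <- pmax(model$hyperparams$outputscale - colSums(V^2), 0)
  structure(list(mu = mu, sigma = model$sd_y * sqrt(var)),
            class = "cibo_posterior")
}

# joint posterior mean vector and covariance matrix (percent scale)
.posterior_joint <- function(model, indices) {
  hp <- model$hyperparams
  Kxt <- .assemble_kernel(model$cache, indices, model$train, hp)
  Kxx <- .assemble_kernel(model$cache, indices, indices, hp)
  mu <- model$mu_y + model$sd_y * as.numeric(Kxt %*% model$alpha)
  V <- backsolve(model$L, t(Kxt), transpose = TRUE)
  Sigma <- (Kxx - crossprod(V)) * model$sd_y^2
  list(mu = mu, Sigma = (Sigma + t(Sigma)) / 2)
}

#' Draw joint samples from the GP posterior
#'
#' Samples from the full joint posterior (with cross-candidate covariance,
#' not independent marginals) over the given candidates; reproducible given a
#' seed and insulated from the caller's RNG state.
#'
#' @param model a fitted [fit_surrogate()] model.
#' @param indices candidate indices to sample at.
#' @param n_samples number of joint draws (>= 1).
#' @param seed integer seed.
#' @return matrix of draws, `length(indices) x n_samples`.
#' @export
posterior_sample <- function(model, indices, n_samples, seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  joint <- .posterior_joint(model, indices)
  fac <- .chol_jitter(joint$Sigma)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed %% 2147483647L)
  Z <- matrix(stats::rnorm(length(indices) * n_samples), nrow = length(indices))
  joint$mu + t(fac$L) %*% Z
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
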