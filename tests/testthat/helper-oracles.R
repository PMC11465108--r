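# Independent oracles and fixture builders. Everything here is deliberately
# naive (dense solves, exhaustive enumeration) and separate from the code
# paths it checks.

# textbook GP posterior via direct dense solve of (K + noise I) a = y
gp_oracle <- function(K_tr, K_x_tr, k_xx_diag, y, noise, prior_mean) {
  n <- nrow(K_tr)
  A <- K_tr + diag(noise, n)
  a <- solve(A, y - prior_mean)
  mu <- prior_mean + as.numeric(K_x_tr %*% a)
  W <- solve(A, t(K_x_tr))
  var <- k_xx_diag - colSums(t(K_x_tr) * W)
  list(mu = mu, sigma = sqrt(pmax(var, 0)))
}

# closed-form expected improvement for a Gaussian posterior
ei_closed_form <- function(mu, sigma, incumbent) {
  z <- (mu - incumbent) / sigma
  sigma * (z * pnorm(z) + dnorm(z))
}

# exhaustive enumeration of the adjusted-norm argmax over all batches
brute_force_batch <- function(space, pool, alpha_by_idx, ledger, S, n_e) {
  combos <- utils::combn(sort(pool), n_e)
  norms <- apply(combos, 2, function(idx) {
    ids <- unique(unlist(lapply(idx, function(i) {
      candidate_compounds(space, i)
    })))
    ids <- setdiff(ids, ledger$owned)
    sum(alpha_by_idx[as.character(idx)]) -
      S * sum(compound_prices(space)[ids])
  })
  best <- which.max(norms)
  list(indices = combos[, best], norm = norms[best])
}

# second, independent implementation of the minimal-spend scan
minimal_spend_oracle <- function(space, target) {
  best <- Inf
  for (i in seq_len(nrow(space$candidates))) {
    if (space$candidates$yield[i] >= target) {
      ids <- unique(candidate_compounds(space, i))
      best <- min(best, sum(compound_prices(space)[ids]))
    }
  }
  if (is.finite(best)) best else NA_real_
}

# hand-built deterministic space: 2 ligands x 2 bases x temperature levels
tiny_space <- function(temps = c(25, 50, 75), yields = NULL,
                       lig_prices = c(10, 50), base_prices = c(0, 0)) {
  comps <- list(
    compound("LA", "ligand", lig_prices[1], fp = fingerprint(c(0, 1, 2), 64)),
    compound("LB", "ligand", lig_prices[2], fp = fingerprint(c(2, 3, 4), 64)),
    compound("BA", "base", base_prices[1], fp = fingerprint(c(10, 11), 64)),
    compound("BB", "base", base_prices[2], fp = fingerprint(c(11, 12), 64))
  )
  grid <- expand.grid(ligand = c("LA", "LB"), base = c("BA", "BB"),
                      temperature = temps, stringsAsFactors = FALSE)
  if (is.null(yields)) {
    yields <- 10 + 80 * (grid$ligand == "LB") / 2 +
      30 * (grid$base == "BB") / 2 + grid$temperature / 10
  }
  grid$yield <- pmin(pmax(yields, 0), 100)
  design_space(grid, comps, conditions = "temperature", name = "tiny")
}

# random 12-candidate instance for batch-search tests: random prices,
# random ownership, random alpha
random_batch_instance <- function(seed) {
  set.seed(seed)
  space <- generate_synthetic_space(synthetic_spec(
    n_ligands = 6L, n_bases = 2L, n_solvents = 1L,
    conditions = list(temperature = 25),
    priced_roles = c("ligand", "base"), n_bits = 32L,
    seed = seed + 1000L
  ))
  pool <- seq_len(nrow(space$candidates))
  owned <- names(space$compounds)[runif(length(space$compounds)) < 0.3]
  ledger <- initialize_ledger(owned, compound_prices(space),
                              charge_initial = FALSE)
  alpha <- setNames(runif(length(pool), 0, 3), pool)
  S <- runif(1, 0.005, 0.05)
  list(space = space, pool = pool, ledger = ledger, alpha = alpha, S = S)
}

# small CC-like space for campaign tests
small_cc_space <- function(seed, n_ligands = 6L, price_quality_cor = 0,
                           quality_sd = 1.5, lig_sdlog = 1.2) {
  generate_synthetic_space(synthetic_spec(
    n_ligands = n_ligands, n_bases = 2L, n_solvents = 1L,
    conditions = list(temperature = c(60, 80, 100),
                      concentration = c(0.05, 0.1, 0.2)),
    price_model = list(ligand = c(meanlog = log(150), sdlog = lig_sdlog),
                       base = c(meanlog = log(15), sdlog = 0.5),
                       solvent = c(meanlog = log(5), sdlog = 0.5)),
    priced_roles = c("ligand", "base"),
    quality_sd = quality_sd, price_quality_cor = price_quality_cor,
    n_bits = 64L, seed = seed
  ))
}

fast_cfg <- function(policy, lam = 0, seed = 1L, n_iterations = 5L, ...) {
  campaign_config(policy = policy, lam = lam, n_iterations = n_iterations,
                  seed = seed, mc_samples = 128L,
                  fit = list(restarts = 2L), ...)
}
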