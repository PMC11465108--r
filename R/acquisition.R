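#' Cost policy for acquisition adjustment
#'
#' @param lam cost weight \eqn{\lambda \ge 0}. `lam = 0` makes the
#'   cost-informed path identical to standard batch BO.
#' @return list of class `cibo_cost_policy`.
#' @export
cost_policy <- function(lam = 1) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    stop("lam must be a non-negative number")
  }
  structure(list(lam = lam), class = "cibo_cost_policy")
}

#' Monte-Carlo noisy expected improvement per candidate
#'
#' For every untested candidate, draws joint posterior samples over the
#' observed inputs and the pool (common random numbers: one joint draw matrix
#' is shared by all candidates within a call) and averages
#' `max(0, draw_at_candidate - max draw over observed inputs)`. This is the
#' per-experiment noisy expected improvement over the noisy incumbent; values
#' are non-negative by construction.
#'
#' @param model a fitted [fit_surrogate()] model.
#' @param pool indices of untested candidates (non-empty).
#' @param observed indices of observed candidates (default: the model's
#'   training set); the incumbent is the per-draw maximum over these.
#' @param mc_samples number of posterior draws (default 512).
#' @param seed integer seed.
#' @return list of class `cibo_alpha` with `alpha` (named by pool index),
#'   `mc_samples`, `seed`.
#' @export
compute_alpha <- function(model, pool, observed = model$train,
                          mc_samples = 512L, seed = 1L) {
  if (length(pool) < 1L) stop("pool must be non-empty")
  if (mc_samples < 1L) stop("mc_samples must be >= 1")
  all_idx <- c(observed, pool)
  draws <- posterior_sample(model, all_idx, mc_samples, seed = seed)
  obs_rows <- seq_along(observed)
  incumbent <- apply(draws[obs_rows, , drop = FALSE], 2, max)
  imp <- sweep(draws[-obs_rows, , drop = FALSE], 2, incumbent, "-")
  alpha <- rowMeans(pmax(imp, 0))
  structure(
    list(alpha = stats::setNames(alpha, pool), mc_samples = mc_samples,
         seed = seed),
    class = "cibo_alpha"
  )
}

#' Inventory-conditional cost of one candidate experiment
#'
#' Sums the prices of the candidate's compounds, skipping any compound that
#' is already owned in the ledger or appears in an earlier member of the same
#' batch: a compound is paid for at most once, and owning it makes every
#' further experiment with it free.
#'
#' @param space a [design_space()].
#' @param index candidate index.
#' @param ledger a `cibo_ledger`.
#' @param earlier_in_batch candidate indices placed earlier in the batch.
#' @return non-negative cost.
#' @export
experiment_cost <- function(space, index, ledger,
                            earlier_in_batch = integer(0)) {
  ids <- candidate_compounds(space, index)
  free <- ledger$owned
  if (length(earlier_in_batch)) {
    free <- c(free, unlist(lapply(earlier_in_batch, function(i) {
      candidate_compounds(space, i)
    })))
  }
  ids <- setdiff(ids, free)
  if (!length(ids)) return(0)
  p <- compound_prices(space)[ids]
  if (anyNA(p)) {
    stop(sprintf("no price known for compound(s): %s",
                 paste(ids[is.na(p)], collapse = ", ")))
  }
  sum(p)
}

#' Scaling function S turning prices into acquisition units
#'
#' `S = lam * max(alpha) / mean(prices)`: the largest possible subtracted
#' term is commensurate with the largest acquisition value, and the cost
#' units cancel. Recomputed every iteration from the current acquisition
#' values and catalog prices.
#'
#' @param alpha a `cibo_alpha` or numeric vector of acquisition values.
#' @param prices numeric vector of all compound prices in the design space.
#' @param lam cost weight \eqn{\lambda}.
#' @return scalar `S >= 0`; exactly 0 when `lam = 0`.
#' @export
scaling_factor <- function(alpha, prices, lam) {
  if (inherits(alpha, "cibo_alpha")) alpha <- alpha$alpha
  if (!length(alpha)) stop("alpha must be non-empty")
  if (lam == 0) return(0)
  if (mean(prices) <= 0) {
    stop("all compound prices are zero: cost adjustment is meaningless ",
         "(set lam = 0 for plain BO)")
  }
  lam * max(alpha) / mean(prices)
}

#' Cost-subtracted acquisition value
#'
#' @param alpha_j raw acquisition value(s).
#' @param cost_j inventory-conditional cost(s).
#' @param S scaling factor from [scaling_factor()].
#' @return `alpha_j - S * cost_j`; may be negative (no clipping).
#' @export
adjusted_alpha <- function(alpha_j, cost_j, S) {
  if (S < 0) stop("S must be >= 0")
  if (any(cost_j < 0)) stop("costs must be >= 0")
  alpha_j - S * cost_j
}

# adjusted norm of a batch: sum of alphas minus S times the total price of
# distinct unowned compounds referenced by the batch (within-batch
# deduplication; order-independent through the compound-set union)
.batch_adjusted_norm <- function(space, indices, alpha_by_idx, ledger, S) {
  raw <- sum(alpha_by_idx[as.character(indices)])
  if (S == 0) return(raw)
  ids <- unique(unlist(lapply(indices, function(i) {
    candidate_compounds(space, i)
  })))
  ids <- setdiff(ids, ledger$owned)
  raw - S * sum(compound_prices(space)[ids])
}

#' Raw or adjusted norm of a batch proposal
#'
#' The raw norm is the sum of the members' acquisition values; the adjusted
#' norm subtracts the scaled cost of every distinct not-yet-owned compound in
#' the batch, charged once regardless of how many members share it.
#'
#' @param proposal a `cibo_batch` from [propose_batch()].
#' @param adjusted if TRUE return the cost-adjusted norm.
#' @return scalar; `batch_norm(p, TRUE) <= batch_norm(p, FALSE)` always.
#' @export
batch_norm <- function(proposal, adjusted = FALSE) {
  if (adjusted) proposal$adjusted_norm else proposal$raw_norm
}

.make_proposal <- function(space, indices, alpha_by_idx, ledger, S) {
  ids <- unique(unlist(lapply(indices, function(i) {
    candidate_compounds(space, i)
  })))
  new_ids <- setdiff(ids, ledger$owned)
  prices <- compound_prices(space)
  purchases <- data.frame(id = new_ids,
                          price = as.numeric(prices[new_ids]),
                          stringsAsFactors = FALSE)
  raw <- sum(alpha_by_idx[as.character(indices)])
  structure(
    list(indices = indices,
         alpha = alpha_by_idx[as.character(indices)],
         raw_norm = raw,
         adjusted_norm = raw - S * sum(purchases$price),
         incremental_cost = sum(purchases$price),
         purchases = purchases, S = S),
    class = "cibo_batch"
  )
}

#' @export
print.cibo_batch <- function(x, ...) {
  cat(sprintf(
    "<batch: candidates [%s]; raw norm %.4g, adjusted %.4g, new cost %.2f>\n",
    paste(x$indices, collapse = ", "), x$raw_norm, x$adjusted_norm,
    x$incremental_cost
  ))
  invisible(x)
}

#' Select the batch maximizing the cost-adjusted norm
#'
#' A shortlist of the top `M` candidates by singly-costed adjusted
#' acquisition is searched with multi-start greedy construction (within-batch
#' cost zeroing recomputed after each pick) followed by pairwise swap
#' refinement until no improvement; on small instances this matches
#' exhaustive enumeration of the adjusted-norm argmax. Ties break
#' lexicographically by candidate index. With `lam = 0` the scaling factor is
#' 0, every adjusted value equals its raw value, and the selected batch is
#' provably the top `n_e` candidates by raw acquisition — identical to the
#' pure-BO path of [propose_batch_bo()].
#'
#' @param model a fitted [fit_surrogate()] model.
#' @param space the [design_space()].
#' @param pool indices of untested candidates.
#' @param ledger current `cibo_ledger`.
#' @param policy a [cost_policy()].
#' @param n_e batch size.
#' @param search list of search options: `shortlist` (top-M size, default 50),
#'   `mc_samples` (default 512).
#' @param seed integer seed for the Monte-Carlo acquisition.
#' @param alpha optional precomputed `cibo_alpha` over `pool` (skips the MC
#'   step).
#' @return A `cibo_batch`, or `NULL` when the pool is smaller than `n_e`
#'   (campaign-termination signal, not an error).
#' @export
propose_batch <- function(model, space, pool, ledger, policy = cost_policy(0),
                          n_e = 5L, search = list(), seed = 1L, alpha = NULL) {
  if (length(pool) < n_e) return(NULL)
  s <- modifyList(list(shortlist = 50L, mc_samples = 512L), search)
  if (is.null(alpha)) {
    alpha <- compute_alpha(model, pool, mc_samples = s$mc_samples, seed = seed)
  }
  a <- alpha$alpha
  names(a) <- pool

  S <- scaling_factor(a, compound_prices(space), policy$lam)
  cost0 <- vapply(pool, function(i) experiment_cost(space, i, ledger),
                  numeric(1))
  ahat0 <- a - S * cost0
  ord <- order(-ahat0, pool)
  short <- pool[ord[seq_len(min(max(s$shortlist, n_e), length(pool)))]]

  greedy_from <- function(first) {
    chosen <- first
    owned_plus <- unique(c(ledger$owned, unlist(lapply(chosen, function(i) {
      candidate_compounds(space, i)
    }))))
    while (length(chosen) < n_e) {
      rest <- setdiff(short, chosen)
      marg <- vapply(rest, function(i) {
        ids <- setdiff(candidate_compounds(space, i), owned_plus)
        a[as.character(i)] - S * sum(compound_prices(space)[ids])
      }, numeric(1))
      pick <- rest[order(-marg, rest)[1L]]
      chosen <- c(chosen, pick)
      owned_plus <- unique(c(owned_plus, candidate_compounds(space, pick)))
    }
    sort(chosen)
  }

  norm_of <- function(idx) .batch_adjusted_norm(space, idx, a, ledger, S)

  starts <- short[seq_len(min(n_e, length(short)))]
  best <- NULL
  best_norm <- -Inf
  for (st in starts) {
    cand <- greedy_from(st)
    nv <- norm_of(cand)
    if (nv > best_norm + 1e-12 ||
        (abs(nv - best_norm) <= 1e-12 && !is.null(best) &&
         paste(cand, collapse = ",") < paste(best, collapse = ","))) {
      best <- cand; best_norm <- nv
    }
  }

  # pairwise swap refinement: replace one member by one shortlist outsider
  repeat {
    improved <- FALSE
    outside <- setdiff(short, best)
    for (pos in seq_along(best)) {
      for (cand in outside) {
        trial <- sort(c(best[-pos], cand))
        nv <- norm_of(trial)
        if (nv > best_norm + 1e-12) {
          best <- trial; best_norm <- nv; improved <- TRUE
          outside <- setdiff(short, best)
        }
      }
    }
    if (!improved) break
  }
  .make_proposal(space, best, a, ledger, S)
}

#' Pure standard-BO batch selection
#'
#' The batch of the `n_e` untested candidates with the largest raw
#' acquisition values, with ties broken by candidate index. No cost or
#' inventory code is executed; this is the baseline path that
#' [propose_batch()] must reproduce at `lam = 0`.
#'
#' @inheritParams propose_batch
#' @return A `cibo_batch` (with `S = 0`), or `NULL` when the pool is smaller
#'   than `n_e`.
#' @export
propose_batch_bo <- function(model, space, pool, ledger, n_e = 5L,
                             search = list(), seed = 1L, alpha = NULL) {
  if (length(pool) < n_e) return(NULL)
  s <- modifyList(list(mc_samples = 512L), search)
  if (is.null(alpha)) {
    alpha <- compute_alpha(model, pool, mc_samples = s$mc_samples, seed = seed)
  }
  a <- alpha$alpha
  names(a) <- pool
  ord <- order(-a, pool)
  chosen <- sort(pool[ord[seq_len(n_e)]])
  .make_proposal(space, chosen, a, ledger, S = 0)
}
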