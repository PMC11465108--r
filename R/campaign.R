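#' Campaign configuration
#'
#' @param policy `"cibo"` (cost-informed), `"bo"` (standard batch BO), or
#'   `"random"` (uniform batches without replacement).
#' @param lam cost weight \eqn{\lambda}; ignored by `"bo"`/`"random"`.
#' @param batch_size experiments per iteration (default 5).
#' @param n_iterations iteration budget.
#' @param seed master seed; every stochastic sub-step derives its own
#'   counter-based sub-seed from it.
#' @param stop_yield optional threshold in percent (e.g. 70): the first
#'   iteration reaching it is recorded as `terminal_iteration`.
#' @param hard_stop if TRUE the loop halts once `stop_yield` is met;
#'   by default it runs its full budget and only records the crossing.
#' @param charge_initial charge the initialization compounds at iteration 0.
#' @param mc_samples Monte-Carlo draws per acquisition evaluation.
#' @param shortlist top-M shortlist size for the batch search.
#' @param fit list of [fit_surrogate()] settings overrides (e.g. `restarts`).
#' @return list of class `cibo_config`.
#' @export
campaign_config <- function(policy = c("cibo", "bo", "random"), lam = 1,
                            batch_size = 5L, n_iterations = 20L, seed = 1L,
                            stop_yield = NULL, hard_stop = FALSE,
                            charge_initial = TRUE, mc_samples = 512L,
                            shortlist = 50L, fit = list()) {
  policy <- match.arg(policy)
  stopifnot(batch_size >= 1L, n_iterations >= 1L)
  if (!is.null(stop_yield) && (stop_yield < 0 || stop_yield > 100)) {
    stop("stop_yield must be in [0, 100]")
  }
  structure(
    list(policy = policy, lam = lam, batch_size = as.integer(batch_size),
         n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         stop_yield = stop_yield, hard_stop = hard_stop,
         charge_initial = charge_initial, mc_samples = as.integer(mc_samples),
         shortlist = as.integer(shortlist), fit = fit),
    class = "cibo_config"
  )
}

# counter-based sub-seed derivation; keeps every seed below 2^31
.derive_seed <- function(master, iteration, stream) {
  (abs(master) * 48271 + iteration * 1009 + stream * 7919) %% 2147483647
}

#' Run one optimization campaign over a lookup design space
#'
#' Iterates fit -> acquire -> cost-adjust -> select -> commit -> observe,
#' looking yields up from the design-space table (retrospective benchmark
#' mode). Each iteration consumes exactly `batch_size` untested candidates;
#' no candidate is ever observed twice. The loop halts at the iteration
#' budget or when the untested pool is smaller than the batch size.
#'
#' @param space a [design_space()].
#' @param init integer indices of the initialization subset (observed before
#'   iteration 1; their compounds seed the inventory).
#' @param config a [campaign_config()].
#' @param cache optional [kernel_cache()] reused across iterations/runs.
#' @return list of class `cibo_trace`: data.frame `iterations` (columns
#'   `iteration`, `best_yield`, `cumulative_spend`, `n_observed`, plus
#'   list-columns `batch` and `purchased`), `terminal_iteration` (first
#'   iteration meeting `stop_yield`, NA if never), `config`, `space_name`.
#' @export
run_campaign <- function(space, init, config, cache = NULL) {
  n <- nrow(space$candidates)
  init <- as.integer(init)
  if (!length(init)) stop("init subset must be non-empty")
  if (any(init < 1L | init > n)) {
    stop("init subset references unknown candidate indices")
  }
  if (anyDuplicated(init)) stop("init subset contains duplicates")
  if (is.null(cache) && config$policy != "random") cache <- kernel_cache(space)

  ledger <- ledger_from_space(space, init, config$charge_initial)
  observed <- init
  pool <- setdiff(seq_len(n), init)
  yields <- space$candidates$yield

  rows <- list()
  record <- function(it, batch, purchased, raw, adj) {
    rows[[length(rows) + 1L]] <<- data.frame(
      iteration = it, best_yield = max(yields[observed]),
      cumulative_spend = cumulative_spend(ledger),
      n_observed = length(observed),
      batch = I(list(batch)), purchased = I(list(purchased)),
      raw_norm = raw, adjusted_norm = adj
    )
  }
  record(0L, integer(0), ledger$purchases$id, NA_real_, NA_real_)

  terminal <- NA_integer_
  check_stop <- function(it) {
    if (!is.null(config$stop_yield) && is.na(terminal) &&
        max(yields[observed]) >= config$stop_yield) {
      terminal <<- it
    }
  }
  check_stop(0L)

  for (it in seq_len(config$n_iterations)) {
    if (length(pool) < config$batch_size) break
    if (config$hard_stop && !is.na(terminal)) break
    if (config$policy == "random") {
      old <- .save_rng_state()
      set.seed(.derive_seed(config$seed, it, 1L))
      batch <- sort(sample(pool, config$batch_size))
      .restore_rng_state(old)
      a0 <- stats::setNames(rep(0, length(batch)), batch)
      proposal <- .make_proposal(space, batch, a0, ledger, S = 0)
    } else {
      fit_settings <- modifyList(
        list(seed = .derive_seed(config$seed, it, 2L)), config$fit
      )
      model <- fit_surrogate(space, observed, yields[observed],
                             settings = fit_settings, cache = cache)
      acq_seed <- .derive_seed(config$seed, it, 3L)
      search <- list(shortlist = config$shortlist,
                     mc_samples = config$mc_samples)
      proposal <- if (config$policy == "bo") {
        propose_batch_bo(model, space, pool, ledger,
                         n_e = config$batch_size, search = search,
                         seed = acq_seed)
      } else {
        propose_batch(model, space, pool, ledger,
                      policy = cost_policy(config$lam),
                      n_e = config$batch_size, search = search,
                      seed = acq_seed)
      }
      if (is.null(proposal)) break
    }
    res <- commit_batch(ledger, space, proposal$indices, it)
    ledger <- res$ledger
    observed <- c(observed, proposal$indices)
    pool <- setdiff(pool, proposal$indices)
    record(it, proposal$indices, proposal$purchases$id,
           proposal$raw_norm, proposal$adjusted_norm)
    check_stop(it)
    if (config$hard_stop && !is.na(terminal)) break
  }

  structure(
    list(iterations = do.call(rbind, rows), terminal_iteration = terminal,
         ledger = ledger, config = config, space_name = space$name),
    class = "cibo_trace"
  )
}

#' @export
print.cibo_trace <- function(x, ...) {
  last <- x$iterations[nrow(x$iterations), ]
  cat(sprintf(
    "<campaign trace (%s): %d iterations, best yield %.1f%%, spend %.2f>\n",
    x$config$policy, last$iteration, last$best_yield, last$cumulative_spend
  ))
  invisible(x)
}

#' Money spent when a yield threshold is first met
#'
#' @param trace a `cibo_trace`.
#' @param threshold yield threshold in percent.
#' @return cumulative spend at the first iteration whose best observed yield
#'   reaches the threshold, or `NA_real_` as the explicit "not reached"
#'   marker.
#' @export
spend_at_threshold <- function(trace, threshold) {
  hit <- which(trace$iterations$best_yield >= threshold)
  if (!length(hit)) return(NA_real_)
  trace$iterations$cumulative_spend[hit[1L]]
}

#' Run an ensemble of campaigns with one initialization
#'
#' Runs `n_runs` campaigns with seeds `config$seed + 0 ... + (n_runs - 1)`
#' and the same initialization subset, and summarizes best yield and spend
#' per iteration across runs.
#'
#' @inheritParams run_campaign
#' @param n_runs number of repeated runs R (>= 1).
#' @param keep_traces keep the individual traces in the result.
#' @return list of class `cibo_ensemble`: data.frame `summary` (per-iteration
#'   mean/sd of best yield and spend), numeric `spend_at_stop` (per-run spend
#'   at `config$stop_yield`, all NA when no threshold is set), `traces`.
#' @export
run_ensemble <- function(space, init, config, n_runs, cache = NULL,
                         keep_traces = TRUE) {
  stopifnot(n_runs >= 1L)
  if (is.null(cache) && config$policy != "random") cache <- kernel_cache(space)
  traces <- lapply(seq_len(n_runs) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    run_campaign(space, init, cfg, cache = cache)
  })
  iters <- lapply(traces, function(tr) tr$iterations)
  n_it <- min(vapply(iters, nrow, integer(1)))
  best <- vapply(iters, function(d) d$best_yield[seq_len(n_it)],
                 numeric(n_it))
  spend <- vapply(iters, function(d) d$cumulative_spend[seq_len(n_it)],
                  numeric(n_it))
  best <- matrix(best, nrow = n_it)
  spend <- matrix(spend, nrow = n_it)
  sd0 <- function(m) apply(m, 1, function(v) {
    if (length(v) > 1L) stats::sd(v) else 0
  })
  summary <- data.frame(
    iteration = iters[[1]]$iteration[seq_len(n_it)],
    mean_best_yield = rowMeans(best), sd_best_yield = sd0(best),
    mean_spend = rowMeans(spend), sd_spend = sd0(spend)
  )
  sas <- if (!is.null(config$stop_yield)) {
    vapply(traces, spend_at_threshold, numeric(1),
           threshold = config$stop_yield)
  } else rep(NA_real_, n_runs)
  structure(
    list(summary = summary, spend_at_stop = sas,
         traces = if (keep_traces) traces else NULL,
         n_runs = n_runs, config = config),
    class = "cibo_ensemble"
  )
}

#' @export
print.cibo_ensemble <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "<ensemble (%s, R=%d): final mean best yield %.1f%%, mean spend %.2f>\n",
    x$config$policy, x$n_runs, last$mean_best_yield, last$mean_spend
  ))
  invisible(x)
}

#' Write a campaign trace to CSV (plus a JSON sidecar)
#'
#' The CSV holds one row per iteration with `;`-joined batch and purchase
#' columns; the JSON sidecar records config, terminal iteration and final
#' totals. [read_trace()] round-trips the CSV.
#'
#' @param trace a `cibo_trace`.
#' @param path CSV output path; the JSON sidecar gets extension `.json`.
#' @export
write_trace <- function(trace, path) {
  d <- trace$iterations
  out <- data.frame(
    iteration = d$iteration, best_yield = d$best_yield,
    cumulative_spend = d$cumulative_spend, n_observed = d$n_observed,
    batch_indices = vapply(d$batch, paste, character(1), collapse = ";"),
    purchases = vapply(d$purchased, paste, character(1), collapse = ";"),
    raw_norm = d$raw_norm, adjusted_norm = d$adjusted_norm
  )
  utils::write.csv(out, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(
    policy = trace$config$policy, lam = trace$config$lam,
    batch_size = trace$config$batch_size, seed = trace$config$seed,
    space = trace$space_name,
    terminal_iteration = trace$terminal_iteration,
    final_best_yield = d$best_yield[nrow(d)],
    final_spend = d$cumulative_spend[nrow(d)]
  ), side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a campaign trace written by [write_trace()]
#' @param path CSV path.
#' @return A `cibo_trace` (iterations table and terminal iteration only).
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_int <- function(s) {
    if (is.na(s) || !nzchar(s)) integer(0) else as.integer(strsplit(s, ";")[[1]])
  }
  split_chr <- function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";")[[1]]
  }
  iters <- data.frame(
    iteration = d$iteration, best_yield = d$best_yield,
    cumulative_spend = d$cumulative_spend, n_observed = d$n_observed,
    batch = I(lapply(as.character(d$batch_indices), split_int)),
    purchased = I(lapply(as.character(d$purchases), split_chr)),
    raw_norm = d$raw_norm, adjusted_norm = d$adjusted_norm
  )
  side <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else list()
  term <- meta$terminal_iteration
  structure(
    list(iterations = iters,
         terminal_iteration = if (is.null(term)) NA_integer_ else term,
         ledger = NULL, config = meta, space_name = meta$space),
    class = "cibo_trace"
  )
}

#' Plot best yield and spend against iteration
#'
#' Base-graphics convenience plot of a single campaign trace; never
#' load-bearing for any numeric output.
#'
#' @param x a `cibo_trace`.
#' @param ... passed to [plot()].
#' @export
plot.cibo_trace <- function(x, ...) {
  d <- x$iterations
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(d$iteration, d$best_yield, type = "s", xlab = "iteration",
       ylab = "best yield [%]", ylim = c(0, 100), ...)
  plot(d$iteration, d$cumulative_spend, type = "s", xlab = "iteration",
       ylab = "cumulative spend", ...)
  invisible(x)
}
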