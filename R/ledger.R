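#' Initialize an inventory ledger
#'
#' The ledger is the dynamic state behind experiment costing: it tracks which
#' compounds are owned and records each purchase exactly once. Compounds
#' never leave the inventory (stocks are assumed inexhaustible), so ownership
#' and cumulative spend are monotone over a campaign.
#'
#' @param initial_ids character vector of compound ids granted at campaign
#'   start.
#' @param prices named numeric vector of compound prices (required when
#'   `charge_initial`).
#' @param charge_initial if TRUE (default), each initial compound is recorded
#'   as a purchase at iteration 0, so initialization cost enters the total.
#' @return An object of class `cibo_ledger`.
#' @export
initialize_ledger <- function(initial_ids = character(0), prices = NULL,
                              charge_initial = TRUE) {
  initial_ids <- as.character(initial_ids)
  if (anyDuplicated(initial_ids)) {
    stop("duplicate compound ids in initial inventory")
  }
  purchases <- data.frame(id = character(0), price = numeric(0),
                          iteration = integer(0), stringsAsFactors = FALSE)
  if (charge_initial && length(initial_ids)) {
    p <- prices[initial_ids]
    if (anyNA(p)) {
      stop(sprintf("no price known for initial compound(s): %s",
                   paste(initial_ids[is.na(p)], collapse = ", ")))
    }
    purchases <- data.frame(id = initial_ids, price = as.numeric(p),
                            iteration = 0L, stringsAsFactors = FALSE)
  }
  structure(
    list(owned = initial_ids, purchases = purchases,
         initial_owned = initial_ids,
         quantities = stats::setNames(rep(Inf, length(initial_ids)),
                                      initial_ids)),
    class = "cibo_ledger"
  )
}

#' @export
print.cibo_ledger <- function(x, ...) {
  cat(sprintf("<inventory ledger: %d owned, %d purchases, spend %.2f>\n",
              length(x$owned), nrow(x$purchases), cumulative_spend(x)))
  invisible(x)
}

#' Ledger seeded from a design space initialization subset
#'
#' @param space a [design_space()].
#' @param init_indices candidate indices of the initialization subset; every
#'   compound they reference becomes owned.
#' @param charge_initial see [initialize_ledger()].
#' @return A `cibo_ledger`.
#' @export
ledger_from_space <- function(space, init_indices, charge_initial = TRUE) {
  ids <- unique(unlist(lapply(init_indices, function(i) {
    candidate_compounds(space, i)
  })))
  initialize_ledger(ids, compound_prices(space), charge_initial)
}

#' Commit a selected batch to the inventory
#'
#' Every compound referenced by the batch that is not yet owned becomes owned
#' with exactly one purchase record; already-owned compounds charge nothing.
#' Re-committing the same batch is idempotent (charges 0).
#'
#' @param ledger a `cibo_ledger`.
#' @param space the [design_space()] the batch indices refer to.
#' @param indices candidate indices of the batch.
#' @param iteration iteration number recorded on the purchases.
#' @return list with the updated `ledger` and the amount `charged`.
#' @export
commit_batch <- function(ledger, space, indices, iteration) {
  ids <- unique(unlist(lapply(indices, function(i) {
    candidate_compounds(space, i)
  })))
  new_ids <- setdiff(ids, ledger$owned)
  prices <- compound_prices(space)
  charged <- 0
  if (length(new_ids)) {
    p <- prices[new_ids]
    if (anyNA(p)) {
      stop(sprintf("no price known for compound(s): %s",
                   paste(new_ids[is.na(p)], collapse = ", ")))
    }
    ledger$purchases <- rbind(ledger$purchases, data.frame(
      id = new_ids, price = as.numeric(p), iteration = as.integer(iteration),
      stringsAsFactors = FALSE
    ))
    ledger$owned <- c(ledger$owned, new_ids)
    ledger$quantities[new_ids] <- Inf
    charged <- sum(p)
  }
  list(ledger = ledger, charged = charged)
}

#' Cumulative money spent up to an iteration
#'
#' @param ledger a `cibo_ledger`.
#' @param up_to_iteration include purchases at iterations `<=` this value
#'   (default: all).
#' @return total spend; non-decreasing in `up_to_iteration`.
#' @export
cumulative_spend <- function(ledger, up_to_iteration = Inf) {
  sum(ledger$purchases$price[ledger$purchases$iteration <= up_to_iteration])
}

#' Serialize a ledger's purchase stream to line-oriented JSON
#'
#' One purchase record per line, for audit or resume.
#'
#' @param ledger a `cibo_ledger`.
#' @param path output file path.
#' @export
write_ledger <- function(ledger, path) {
  lines <- vapply(seq_len(nrow(ledger$purchases)), function(k) {
    jsonlite::toJSON(as.list(ledger$purchases[k, ]), auto_unbox = TRUE)
  }, character(1))
  header <- jsonlite::toJSON(
    list(initial_owned = as.list(ledger$initial_owned)), auto_unbox = TRUE
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a ledger back from its line-oriented JSON stream
#' @param path file written by [write_ledger()].
#' @return A `cibo_ledger`.
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  initial <- as.character(unlist(header$initial_owned))
  led <- initialize_ledger(initial, charge_initial = FALSE)
  if (length(lines) > 1L) {
    recs <- lapply(lines[-1], jsonlite::fromJSON)
    led$purchases <- data.frame(
      id = vapply(recs, function(r) r$id, character(1)),
      price = vapply(recs, function(r) as.numeric(r$price), numeric(1)),
      iteration = vapply(recs, function(r) as.integer(r$iteration), integer(1)),
      stringsAsFactors = FALSE
    )
    led$owned <- unique(c(led$owned, led$purchases$id))
    led$quantities <- stats::setNames(rep(Inf, length(led$owned)), led$owned)
  }
  led
}
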