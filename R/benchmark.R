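#' Specification of a synthetic benchmark design space
#'
#' Describes a full-factorial reagent/condition grid with a latent additive
#' yield model, emulating the shape of retrospective HTE yield tables: the
#' default is a DA-like grid of 12 ligands x 4 bases x 3 solvents x 3
#' concentrations x 4 temperatures (1728 candidates) with heterogeneous
#' per-gram ligand prices and cost-free bases/solvents. CC-like ~90-row
#' subsets are obtained by shrinking the counts and pricing all roles.
#'
#' @param n_ligands,n_bases,n_solvents reagent counts per role (>= 1).
#' @param conditions named list of numeric level vectors, one per free
#'   condition variable (cost-free by definition).
#' @param price_model per-role lognormal price parameters: named list of
#'   `c(meanlog, sdlog)`.
#' @param priced_roles roles whose compounds carry a nonzero price; the
#'   others are costed at 0 (negligible-cost reagents).
#' @param quality_sd spread of per-ligand latent quality (logit units).
#' @param role_effect_sd spread of per-base/per-solvent latent effects.
#' @param cond_effect_sd spread of per-condition-level latent effects.
#' @param interaction strength of the ligand x base interaction term.
#' @param noise_sd observation noise on the latent scale.
#' @param price_quality_cor Gaussian-copula correlation in `[-1, 1]` between
#'   ligand quality and ligand price; `+1` is the adversarial regime where
#'   the best ligand is also the most expensive.
#' @param n_bits synthetic fingerprint length.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class `cibo_synthetic_spec`.
#' @export
synthetic_spec <- function(n_ligands = 12L, n_bases = 4L, n_solvents = 3L,
                           conditions = list(
                             concentration = c(0.057, 0.1, 0.153),
                             temperature = c(90, 105, 120, 135)
                           ),
                           price_model = list(
                             ligand = c(meanlog = log(100), sdlog = 1),
                             base = c(meanlog = log(20), sdlog = 0.7),
                             solvent = c(meanlog = log(10), sdlog = 0.7)
                           ),
                           priced_roles = "ligand",
                           quality_sd = 1.5, role_effect_sd = 0.4,
                           cond_effect_sd = 0.35, interaction = 0.3,
                           noise_sd = 0.05, price_quality_cor = 0,
                           n_bits = 256L, seed = 1L) {
  stopifnot(n_ligands >= 1L, n_bases >= 1L, n_solvents >= 1L)
  if (abs(price_quality_cor) > 1) {
    stop("price_quality_cor must lie in [-1, 1]")
  }
  structure(
    list(n_ligands = as.integer(n_ligands), n_bases = as.integer(n_bases),
         n_solvents = as.integer(n_solvents), conditions = conditions,
         price_model = price_model, priced_roles = priced_roles,
         quality_sd = quality_sd, role_effect_sd = role_effect_sd,
         cond_effect_sd = cond_effect_sd, interaction = interaction,
         noise_sd = noise_sd, price_quality_cor = price_quality_cor,
         n_bits = as.integer(n_bits), seed = as.integer(seed)),
    class = "cibo_synthetic_spec"
  )
}

# quality-ordered block fingerprints: ligands close in quality share a
# sliding window of bits, so Tanimoto similarity tracks quality similarity
# and the GP has learnable structure without real chemistry
.synthetic_fingerprints <- function(qualities, n_bits) {
  L <- length(qualities)
  w <- max(4L, n_bits %/% 8L)
  half <- n_bits %/% 2L
  rank <- rank(qualities, ties.method = "first")
  lapply(seq_len(L), function(l) {
    frac <- if (L > 1L) (rank[l] - 1) / (L - 1) else 0
    start <- floor(frac * max(half - w, 0L))
    window <- seq.int(start, start + w - 1L)
    extra <- sample.int(n_bits - half, size = max(4L, w %/% 2L)) + half - 1L
    fingerprint(c(window, extra), n_bits)
  })
}

#' Generate a synthetic design space
#'
#' Builds the full factorial candidate grid of a [synthetic_spec()]. The
#' yield of a candidate is a clipped logistic of
#' `ligand quality + base effect + solvent effect + condition-level effects +
#' interaction + noise`, scaled to percent. Ligand prices are drawn
#' lognormally with the requested Gaussian-copula correlation to quality;
#' at correlation +1 the price ranking equals the quality ranking exactly.
#' Synthetic fingerprints are assigned so that Tanimoto similarity between
#' ligands correlates with their quality similarity. Fully seeded: the same
#' spec yields byte-identical tables.
#'
#' @param spec a [synthetic_spec()].
#' @return A [design_space()] whose `$truth` attribute records the latent
#'   model (qualities, effects, prices) for oracle checks.
#' @export
generate_synthetic_space <- function(spec) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(spec$seed %% 2147483647L)

  lig_ids <- sprintf("L%02d", seq_len(spec$n_ligands))
  base_ids <- sprintf("B%02d", seq_len(spec$n_bases))
  solv_ids <- sprintf("S%02d", seq_len(spec$n_solvents))

  z_q <- stats::rnorm(spec$n_ligands)
  quality <- spec$quality_sd * z_q
  base_eff <- stats::rnorm(spec$n_bases, sd = spec$role_effect_sd)
  solv_eff <- stats::rnorm(spec$n_solvents, sd = spec$role_effect_sd)
  cond_eff <- lapply(spec$conditions, function(lv) {
    stats::setNames(stats::rnorm(length(lv), sd = spec$cond_effect_sd),
                    as.character(lv))
  })
  inter <- matrix(stats::rnorm(spec$n_ligands * spec$n_bases),
                  nrow = spec$n_ligands) * spec$interaction

  rho <- spec$price_quality_cor
  z_ind <- stats::rnorm(spec$n_ligands)
  z_price <- rho * z_q + sqrt(max(1 - rho^2, 0)) * z_ind
  pm <- spec$price_model
  draw_price <- function(role, z) {
    if (!role %in% spec$priced_roles) return(rep(0, length(z)))
    stats::qlnorm(stats::pnorm(z), meanlog = pm[[role]]["meanlog"],
                  sdlog = pm[[role]]["sdlog"])
  }
  lig_price <- draw_price("ligand", z_price)
  base_price <- draw_price("base", stats::rnorm(spec$n_bases))
  solv_price <- draw_price("solvent", stats::rnorm(spec$n_solvents))

  fps_l <- .synthetic_fingerprints(quality, spec$n_bits)
  rand_fp <- function() {
    fingerprint(sample.int(spec$n_bits, size = max(8L, spec$n_bits %/% 8L)) - 1L,
                spec$n_bits)
  }
  fps_b <- replicate(spec$n_bases, rand_fp(), simplify = FALSE)
  fps_s <- replicate(spec$n_solvents, rand_fp(), simplify = FALSE)

  compounds <- c(
    lapply(seq_len(spec$n_ligands), function(l) {
      compound(lig_ids[l], "ligand", lig_price[l], fp = fps_l[[l]])
    }),
    lapply(seq_len(spec$n_bases), function(b) {
      compound(base_ids[b], "base", base_price[b], fp = fps_b[[b]])
    }),
    lapply(seq_len(spec$n_solvents), function(s) {
      compound(solv_ids[s], "solvent", solv_price[s], fp = fps_s[[s]])
    })
  )

  grid <- expand.grid(c(
    list(ligand = lig_ids, base = base_ids, solvent = solv_ids),
    spec$conditions
  ), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  li <- match(grid$ligand, lig_ids)
  bi <- match(grid$base, base_ids)
  si <- match(grid$solvent, solv_ids)
  latent <- quality[li] + base_eff[bi] + solv_eff[si] + inter[cbind(li, bi)]
  for (cn in names(spec$conditions)) {
    latent <- latent + cond_eff[[cn]][as.character(grid[[cn]])]
  }
  latent <- latent + stats::rnorm(nrow(grid), sd = spec$noise_sd)
  grid$yield <- pmin(pmax(100 * stats::plogis(latent), 0), 100)

  space <- design_space(grid, compounds,
                        conditions = names(spec$conditions),
                        name = sprintf("synthetic-%d", spec$seed))
  space$truth <- list(quality = stats::setNames(quality, lig_ids),
                      base_eff = stats::setNames(base_eff, base_ids),
                      solv_eff = stats::setNames(solv_eff, solv_ids),
                      cond_eff = cond_eff, interaction = inter,
                      spec = spec)
  space
}

#' Pick the initialization subset of a design space
#'
#' Mirrors the cheap/worst initialization protocol of retrospective
#' campaigns: by default, every candidate using the single cheapest compound
#' of a role (ties broken by id, documented), so the surrogate starts from an
#' inexpensive corner of the space.
#'
#' @param space a [design_space()].
#' @param strategy `"cheapest"`, `"named:<id>"` (every candidate using that
#'   compound), or an integer vector of explicit candidate indices.
#' @param role role searched by the `"cheapest"` strategy (default
#'   `"ligand"`).
#' @return sorted integer vector of candidate indices.
#' @export
select_initialization <- function(space, strategy = "cheapest",
                                  role = "ligand") {
  if (is.numeric(strategy)) {
    idx <- as.integer(strategy)
    if (any(idx < 1L | idx > nrow(space$candidates))) {
      stop("explicit initialization indices out of range")
    }
    return(sort(idx))
  }
  if (identical(strategy, "cheapest")) {
    roles <- vapply(space$compounds, function(x) x$role, character(1))
    cand <- names(roles)[roles == role]
    if (!length(cand)) stop(sprintf("no compounds with role '%s'", role))
    p <- compound_prices(space)[cand]
    target <- cand[order(p, cand)][1L]
  } else if (startsWith(strategy, "named:")) {
    target <- sub("^named:", "", strategy)
    if (!target %in% names(space$compounds)) {
      stop(sprintf("no compound '%s' in the design space", target))
    }
    role <- space$compounds[[target]]$role
  } else {
    stop(sprintf("unknown initialization strategy '%s'", strategy))
  }
  sort(space$candidates$index[space$candidates[[role]] == target])
}

#' Least compound cost of any single candidate reaching a target yield
#'
#' Exhaustive scan: among candidates with yield at or above the target, the
#' minimum over candidates of the summed prices of their distinct compounds.
#' This is the oracle lower bound on what a perfectly informed buyer would
#' spend.
#'
#' @param space a [design_space()].
#' @param target yield threshold in percent.
#' @return minimum cost, or `NA_real_` as the explicit "unreachable" marker.
#' @export
minimal_spend <- function(space, target) {
  ok <- which(space$candidates$yield >= target)
  if (!length(ok)) return(NA_real_)
  prices <- compound_prices(space)
  costs <- vapply(ok, function(i) {
    sum(prices[unique(candidate_compounds(space, i))])
  }, numeric(1))
  min(costs)
}

#' Write a design space to the package's CSV dialect
#'
#' One row per candidate; for each reagent role `r` the columns `r`,
#' `r_price`, `r_smiles` (empty when synthetic) and `r_fp` (`|`-joined
#' active bit indices) are emitted, followed by the condition columns and
#' `yield`. Comma-separated, header required, UTF-8, `.` decimal separator.
#'
#' @param space a [design_space()].
#' @param path output CSV path.
#' @export
write_design_space <- function(space, path) {
  d <- data.frame(row.names = seq_len(nrow(space$candidates)))
  for (rc in space$roles) {
    ids <- as.character(space$candidates[[rc]])
    d[[rc]] <- ids
    d[[paste0(rc, "_price")]] <- compound_prices(space)[ids]
    d[[paste0(rc, "_smiles")]] <- vapply(ids, function(id) {
      s <- space$compounds[[id]]$structure
      if (is.na(s)) "" else s
    }, character(1))
    d[[paste0(rc, "_fp")]] <- vapply(ids, function(id) {
      paste(as.integer(space$compounds[[id]]$fingerprint), collapse = "|")
    }, character(1))
  }
  for (cn in space$conditions) d[[cn]] <- space$candidates[[cn]]
  d$yield <- space$candidates$yield
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a cost-annotated design-space table
#'
#' Parses the CSV dialect of [write_design_space()] under an explicit column
#' mapping and validates it into a [design_space()]: yield and price columns
#' must exist, prices must be non-negative and consistent per compound, and
#' duplicate (compounds, conditions) rows are rejected.
#'
#' @param path CSV file path.
#' @param schema list with `role_columns` (character vector of reagent-role
#'   column names, each of which must be one of ligand/base/solvent/other),
#'   `condition_columns`, `yield_column` (default `"yield"`), and `n_bits`
#'   (fingerprint length used when only SMILES are given, default 2048).
#' @param name,currency metadata labels for the resulting space.
#' @return A [design_space()].
#' @export
read_design_space <- function(path, schema, name = basename(path),
                              currency = "$") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  schema <- modifyList(list(yield_column = "yield", n_bits = 2048L,
                            condition_columns = character(0)), schema)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(schema$role_columns, paste0(schema$role_columns, "_price"),
            schema$yield_column, schema$condition_columns)
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop(sprintf("design-space table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  compounds <- list()
  for (rc in schema$role_columns) {
    prices <- d[[paste0(rc, "_price")]]
    if (any(prices < 0)) {
      stop(sprintf("negative price(s) in column %s_price", rc))
    }
    for (id in unique(d[[rc]])) {
      rows <- d[[rc]] == id
      p <- unique(prices[rows])
      if (length(p) != 1L) {
        stop(sprintf("conflicting prices for compound '%s'", id))
      }
      smiles_col <- paste0(rc, "_smiles")
      fp_col <- paste0(rc, "_fp")
      fp <- NULL
      if (fp_col %in% names(d)) {
        bits_str <- unique(d[[fp_col]][rows])
        if (length(bits_str) != 1L) {
          stop(sprintf("conflicting fingerprints for compound '%s'", id))
        }
        if (nzchar(bits_str)) {
          fp <- fingerprint(as.integer(strsplit(bits_str, "|",
                                                fixed = TRUE)[[1]]),
                            schema$n_bits)
        }
      }
      smiles <- NA_character_
      if (smiles_col %in% names(d)) {
        s <- unique(as.character(d[[smiles_col]][rows]))
        if (length(s) == 1L && !is.na(s) && nzchar(s)) smiles <- s
      }
      compounds[[length(compounds) + 1L]] <-
        compound(id, rc, p, structure = smiles, fp = fp,
                 n_bits = schema$n_bits)
    }
  }
  cand <- d[c(schema$role_columns, schema$condition_columns)]
  cand$yield <- d[[schema$yield_column]]
  design_space(cand, compounds, conditions = schema$condition_columns,
               name = name, currency = currency)
}
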