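#' Construct a purchasable compound
#'
#' @param id short unique label (e.g. a ligand abbreviation).
#' @param role one of `"ligand"`, `"base"`, `"solvent"`, `"other"`.
#' @param price non-negative cost per gram, in user units.
#' @param structure optional SMILES string; when absent a fingerprint must be
#'   supplied directly (synthetic benchmarks do this).
#' @param fp optional [fingerprint()]; computed from `structure` when missing.
#' @param n_bits,radius fingerprint parameters used when featurizing
#'   `structure`.
#' @return A list of class `cibo_compound`.
#' @export
compound <- function(id, role, price, structure = NA_character_, fp = NULL,
                     n_bits = 2048L, radius = 2L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  role <- match.arg(role, c("ligand", "base", "solvent", "other"))
  if (!is.numeric(price) || length(price) != 1L || is.na(price) || price < 0) {
    stop(sprintf("compound '%s': price must be a non-negative number", id))
  }
  if (is.null(fp)) {
    if (is.na(structure)) {
      stop(sprintf(
        "compound '%s': needs either a structure string or a fingerprint", id
      ))
    }
    fp <- featurize_compound(structure, n_bits = n_bits, radius = radius)
  }
  structure(
    list(id = id, role = role, price = as.numeric(price),
         structure = structure, fingerprint = fp),
    class = "cibo_compound"
  )
}

#' Assemble a discrete reaction design space
#'
#' A design space is the finite set of candidate experiments over which a
#' campaign optimizes: one row per candidate, each referencing one compound
#' per reagent role plus numeric condition settings, and carrying a measured
#' yield used as a lookup oracle in benchmark mode.
#'
#' @param candidates data.frame with one column per reagent role (holding
#'   compound ids), the condition columns named in `conditions`, and a
#'   `yield` column in `[0, 100]`.
#' @param compounds list of [compound()] objects cataloguing every reagent.
#' @param conditions character vector naming the condition columns.
#' @param name,currency free-text metadata labels.
#' @return An object of class `cibo_design_space`.
#' @export
design_space <- function(candidates, compounds, conditions = character(0),
                         name = "design-space", currency = "$") {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  ids <- vapply(compounds, function(x) x$id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate compound ids in catalog: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(compounds) <- ids
  roles <- vapply(compounds, function(x) x$role, character(1))
  role_cols <- sort(unique(roles))
  role_cols <- role_cols[role_cols %in% names(candidates)]
  if (!length(role_cols)) {
    stop("candidates must have at least one reagent-role column")
  }
  if (!"yield" %in% names(candidates)) {
    stop("candidates must carry a 'yield' column (lookup-oracle completeness)")
  }
  y <- candidates$yield
  if (anyNA(y) || any(y < 0 | y > 100)) {
    stop("all yields must be present and in [0, 100]")
  }
  missing_cond <- setdiff(conditions, names(candidates))
  if (length(missing_cond)) {
    stop(sprintf("condition columns missing from candidates: %s",
                 paste(missing_cond, collapse = ", ")))
  }
  for (rc in role_cols) {
    unknown <- setdiff(unique(candidates[[rc]]), ids)
    if (length(unknown)) {
      stop(sprintf("candidates reference uncataloged %s compound(s): %s",
                   rc, paste(unknown, collapse = ", ")))
    }
    mismatch <- roles[candidates[[rc]]] != rc
    if (any(mismatch)) {
      stop(sprintf("compound(s) used in role '%s' have a different catalog role",
                   rc))
    }
  }
  key <- do.call(paste, c(candidates[c(role_cols, conditions)], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (compounds, conditions) candidate rows")
  }
  nb <- unique(vapply(compounds, function(x) attr(x$fingerprint, "n_bits"),
                      integer(1)))
  if (length(nb) != 1L) stop("all compound fingerprints must share n_bits")
  candidates$index <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  comp_mat <- do.call(cbind, lapply(role_cols, function(rc) {
    as.character(candidates[[rc]])
  }))
  colnames(comp_mat) <- role_cols
  structure(
    list(candidates = candidates, compounds = compounds,
         roles = role_cols, conditions = conditions, n_bits = nb,
         comp_mat = comp_mat,
         prices = vapply(compounds, function(x) x$price, numeric(1)),
         name = name, currency = currency),
    class = "cibo_design_space"
  )
}

#' @export
print.cibo_design_space <- function(x, ...) {
  cat(sprintf(
    "<design space '%s': %d candidates, %d compounds (%s), %d condition(s)>\n",
    x$name, nrow(x$candidates), length(x$compounds),
    paste(x$roles, collapse = "/"), length(x$conditions)
  ))
  invisible(x)
}

#' Compound ids referenced by one candidate
#' @param space a [design_space()].
#' @param index candidate row index.
#' @return character vector of compound ids (one per reagent role).
#' @export
candidate_compounds <- function(space, index) {
  as.character(space$comp_mat[index, ])
}

#' Per-compound prices of a design space
#' @param space a [design_space()].
#' @return named numeric vector of catalog prices.
#' @export
compound_prices <- function(space) {
  space$prices
}

#' Min/max scaling table for the conditions of a design space
#' @param space a [design_space()].
#' @return data.frame with columns `name`, `min`, `max`.
#' @export
condition_scaling <- function(space) {
  data.frame(
    name = space$conditions,
    min = vapply(space$conditions, function(cn) min(space$candidates[[cn]]),
                 numeric(1)),
    max = vapply(space$conditions, function(cn) max(space$candidates[[cn]]),
                 numeric(1)),
    row.names = NULL
  )
}

#' Encode one candidate as a joint numeric feature vector
#'
#' Concatenates (i) the role-prefixed union of the candidate's compound
#' fingerprints (each reagent role occupies its own block of `n_bits`
#' positions, so identical bits in different roles stay distinct) and
#' (ii) min-max-scaled condition values in `[0, 1]`.
#'
#' @param space a [design_space()].
#' @param index candidate row index.
#' @param scaling a condition scaling table as from [condition_scaling()];
#'   must cover every condition of the space.
#' @return numeric vector of length `n_roles * n_bits + n_conditions`.
#' @export
encode_candidate <- function(space, index, scaling = condition_scaling(space)) {
  enc <- encode_candidates(space, index, scaling)
  c(as.numeric(enc$binary[1L, ]), as.numeric(enc$numeric[1L, ]))
}

#' Encode many candidates into binary and numeric feature blocks
#'
#' Vectorized companion of [encode_candidate()], returning the two blocks
#' separately so the product kernel can treat them with Tanimoto and
#' squared-exponential parts respectively.
#'
#' @inheritParams encode_candidate
#' @param indices candidate row indices (default: all).
#' @return list of class `cibo_features` with a 0/1 matrix `binary`
#'   (`n x n_roles*n_bits`) and a matrix `numeric` (`n x n_conditions`).
#' @export
encode_candidates <- function(space, indices = space$candidates$index,
                              scaling = condition_scaling(space)) {
  unknown <- setdiff(space$conditions, scaling$name)
  if (length(unknown)) {
    stop(sprintf("condition scaling missing for: %s",
                 paste(unknown, collapse = ", ")))
  }
  n <- length(indices)
  nb <- space$n_bits
  B <- matrix(0, nrow = n, ncol = length(space$roles) * nb)
  for (s in seq_along(space$roles)) {
    rc <- space$roles[s]
    ids <- as.character(space$candidates[[rc]][indices])
    for (u in unique(ids)) {
      bits <- as.integer(space$compounds[[u]]$fingerprint)
      B[ids == u, (s - 1L) * nb + bits + 1L] <- 1
    }
  }
  N <- matrix(0, nrow = n, ncol = length(space$conditions),
              dimnames = list(NULL, space$conditions))
  for (cn in space$conditions) {
    row <- scaling[scaling$name == cn, ]
    span <- row$max - row$min
    v <- space$candidates[[cn]][indices]
    N[, cn] <- if (span > 0) (v - row$min) / span else 0
  }
  structure(list(binary = B, numeric = N), class = "cibo_features")
}

# pairwise Tanimoto similarities between the rows of two 0/1 matrices;
# empty-vs-empty pairs get similarity 1 by convention
.tanimoto_cross <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("binary feature dimensions differ")
  inter <- A %*% t(B)
  na <- rowSums(A)
  nb <- rowSums(B)
  un <- outer(na, nb, "+") - inter
  out <- ifelse(un > 0, inter / un, 1)
  out
}

#' Pairwise kernel matrix between two candidate sets
#'
#' The kernel is a Jaccard-Tanimoto kernel on the role-prefixed binary
#' fingerprint blocks, multiplied by a squared-exponential kernel on the
#' min-max-scaled numeric conditions, and scaled by `outputscale`:
#' \deqn{k(x, x') = s^2 \, T(b, b') \, \exp(-\|u - u'\|^2 / (2\ell^2)).}
#'
#' @param feats_a,feats_b `cibo_features` objects from [encode_candidates()].
#' @param hyperparams list with `outputscale` (\eqn{s^2}) and `lengthscale`
#'   (\eqn{\ell}, applied to the scaled conditions).
#' @return matrix of kernel values, `nrow(feats_a) x nrow(feats_b)`.
#' @export
kernel_matrix <- function(feats_a, feats_b = feats_a,
                          hyperparams = list(outputscale = 1, lengthscale = 1)) {
  if (ncol(feats_a$numeric) != ncol(feats_b$numeric)) {
    stop("numeric feature dimensions differ")
  }
  K <- .tanimoto_cross(feats_a$binary, feats_b$binary)
  if (ncol(feats_a$numeric) > 0L) {
    d2 <- .sq_dists(feats_a$numeric, feats_b$numeric)
    K <- K * exp(-0.5 * d2 / hyperparams$lengthscale^2)
  }
  hyperparams$outputscale * K
}

.sq_dists <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}
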