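#' Binary substructure fingerprints
#'
#' A fingerprint is stored as a sorted integer vector of active bit positions
#' (0-based) with an `n_bits` attribute giving the total feature count.
#' Fingerprints are the binary objects compared by the Jaccard-Tanimoto
#' kernel of the surrogate model.
#'
#' @param bits integer vector of active bit indices, each in `[0, n_bits)`.
#' @param n_bits total number of bits.
#' @return An object of class `cibo_fingerprint`.
#' @export
fingerprint <- function(bits, n_bits) {
  bits <- sort(unique(as.integer(bits)))
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L) stop("n_bits must be >= 1")
  if (length(bits) && (min(bits) < 0L || max(bits) >= n_bits)) {
    stop("fingerprint bits must lie in [0, n_bits)")
  }
  structure(bits, n_bits = n_bits, class = "cibo_fingerprint")
}

#' @export
print.cibo_fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d/%d bits set>\n", length(x), attr(x, "n_bits")))
  invisible(x)
}

# --- minimal SMILES tokenizer/parser ---------------------------------------
# Supports the organic subset (B C N O P S F Cl Br I, aromatic b c n o p s),
# bracket atoms with charge and explicit H counts, branches, ring-bond
# closures (digits and %nn), and bond symbols - = # $ : / \. This is not a
# full SMILES implementation; it exists to give reagent structures a
# deterministic circular-substructure fingerprint without an external
# cheminformatics toolkit.

.smiles_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Ti", "Cr", "Mn", "Fe", "Co", "Ni",
  "Cu", "Zn", "As", "Se", "Br", "Kr", "Rh", "Pd", "Ag", "Sn", "Sb", "Te",
  "I", "Xe", "Pt", "Au", "Hg", "Pb", "Bi"
)

.parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("structure must be a single non-empty SMILES string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()    # each: list(element, aromatic, charge)
  bonds <- list()    # each: c(i, j, order); order 1,2,3,4; 1.5 for aromatic
  stack <- integer(0)
  prev <- 0L
  pending_bond <- NA_real_
  ring_open <- list() # ring digit -> c(atom, bond order or NA)
  fail <- function(at) {
    stop(sprintf("cannot parse SMILES '%s' (near position %d)", smiles, at))
  }
  add_atom <- function(element, aromatic, charge) {
    if (!(element %in% .smiles_elements)) fail(i)
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge
    )
    idx <- length(atoms)
    if (prev > 0L) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    pending_bond <<- NA_real_
    prev <<- idx
  }
  close_ring <- function(key) {
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- c(prev, pending_bond)
    } else {
      opener <- ring_open[[key]]
      ord <- pending_bond
      if (is.na(ord)) ord <- opener[2]
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && atoms[[opener[1]]]$aromatic)
          1.5 else 1
      }
      bonds[[length(bonds) + 1L]] <<- c(opener[1], prev, ord)
      ring_open[[key]] <<- NULL
    }
    pending_bond <<- NA_real_
  }
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Br", "Cl")) {
        add_atom(two, FALSE, 0L); i <- i + 2L
      } else {
        add_atom(ch, FALSE, 0L); i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail(i)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(
        body,
        regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*)?$",
                body)
      )[[1]]
      if (length(m) == 0L) fail(i)
      elem <- m[3]
      aromatic <- elem == tolower(elem) && nchar(elem) == 1L
      if (aromatic) elem <- toupper(elem)
      charge <- 0L
      if (nzchar(m[6])) {
        sgn <- if (substr(m[6], 1, 1) == "+") 1L else -1L
        mag <- substring(m[6], 2)
        charge <- sgn * if (nzchar(mag)) as.integer(mag) else 1L
      }
      add_atom(elem, aromatic, charge)
      i <- j + 1L
    } else if (ch == "(") {
      if (prev == 0L) fail(i)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail(i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- 3; i <- i + 1L
    } else if (ch == "$") {
      pending_bond <- 4; i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- 1.5; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) fail(i)
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || prev == 0L) fail(i)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == ".") {
      prev <- 0L; pending_bond <- NA_real_; i <- i + 1L
    } else {
      fail(i)
    }
  }
  if (length(stack)) fail(n)
  open_keys <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_keys)) {
    stop(sprintf("cannot parse SMILES '%s' (unclosed ring bond %s)",
                 smiles, open_keys[1]))
  }
  if (!length(atoms)) fail(1L)
  list(atoms = atoms, bonds = do.call(rbind, c(bonds, list(matrix(
    numeric(0), ncol = 3
  )))))
}

# deterministic 31-bit mixing hash over integer sequences; exact in doubles
.hash_fold <- function(values) {
  h <- 16777619
  for (v in values) {
    h <- (h * 131 + (v %% 2147483647)) %% 2147483647
  }
  h
}

#' Circular substructure fingerprint of a molecule
#'
#' Parses a SMILES string and hashes iteratively grown atom neighbourhoods
#' (Morgan-style, up to `radius` bonds) into a fixed-length binary
#' fingerprint. Deterministic: the same structure string always yields the
#' same fingerprint.
#'
#' @param structure a SMILES string.
#' @param n_bits fingerprint length (default 2048).
#' @param radius neighbourhood radius in bonds (default 2).
#' @return A [fingerprint()] with at least one active bit.
#' @examples
#' featurize_compound("CCO")
#' @export
featurize_compound <- function(structure, n_bits = 2048L, radius = 2L) {
  mol <- .parse_smiles(structure)
  n_atoms <- length(mol$atoms)
  nb <- vector("list", n_atoms)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      nb[[b[1]]] <- rbind(nb[[b[1]]], c(b[2], b[3]))
      nb[[b[2]]] <- rbind(nb[[b[2]]], c(b[1], b[3]))
    }
  }
  degree <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  inv <- vapply(seq_len(n_atoms), function(a) {
    at <- mol$atoms[[a]]
    .hash_fold(c(match(at$element, .smiles_elements),
                 as.integer(at$aromatic), at$charge + 10L, degree[a]))
  }, numeric(1))
  hashes <- inv
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(n_atoms), function(a) {
      env <- if (degree[a] > 0L) {
        codes <- nb[[a]][, 2] * 3000000 + inv[nb[[a]][, 1]]
        sort(codes)
      } else numeric(0)
      .hash_fold(c(r, inv[a], env))
    }, numeric(1))
    inv <- inv_new
    hashes <- c(hashes, inv)
  }
  fingerprint(unique(floor(hashes)) %% n_bits, n_bits)
}

#' Jaccard-Tanimoto similarity between two fingerprints
#'
#' Computes `|a intersect b| / |a union b|`. Two empty fingerprints are
#' defined to have similarity 1 (two featureless objects are maximally
#' similar), avoiding a 0/0.
#'
#' @param a,b [fingerprint()] objects sharing the same `n_bits`.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  if (!identical(attr(a, "n_bits"), attr(b, "n_bits"))) {
    stop("fingerprints have mismatched n_bits")
  }
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  if (nu == 0L) return(1)
  ni / nu
}
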