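test_that("factorial counts and determinism of the generator", {
  sp <- generate_synthetic_space(synthetic_spec(seed = 3))
  expect_equal(nrow(sp$candidates), 1728L)   # 12 x 4 x 3 x 3 x 4
  expect_length(sp$compounds, 12 + 4 + 3)
  expect_true(all(sp$candidates$yield >= 0 & sp$candidates$yield <= 100))
  sp2 <- generate_synthetic_space(synthetic_spec(seed = 3))
  expect_equal(sp$candidates, sp2$candidates)
  expect_equal(compound_prices(sp), compound_prices(sp2))
  sp3 <- generate_synthetic_space(synthetic_spec(seed = 4))
  expect_false(isTRUE(all.equal(sp$candidates$yield, sp3$candidates$yield)))
})

test_that("noise- and interaction-free optimum is the componentwise argmax", {
  spec <- synthetic_spec(n_ligands = 5, n_bases = 3, n_solvents = 2,
                         noise_sd = 0, interaction = 0, seed = 11)
  sp <- generate_synthetic_space(spec)
  tr <- sp$truth
  best <- sp$candidates[which.max(sp$candidates$yield), ]
  expect_equal(as.character(best$ligand), names(which.max(tr$quality)))
  expect_equal(as.character(best$base), names(which.max(tr$base_eff)))
  expect_equal(as.character(best$solvent), names(which.max(tr$solv_eff)))
  for (cn in names(tr$cond_eff)) {
    expect_equal(as.character(best[[cn]]),
                 names(which.max(tr$cond_eff[[cn]])))
  }
})

test_that("price-quality correlation knob behaves as labelled", {
  sp_adv <- generate_synthetic_space(synthetic_spec(price_quality_cor = 1,
                                                    seed = 9))
  q <- sp_adv$truth$quality
  p <- compound_prices(sp_adv)[names(q)]
  expect_equal(rank(q), rank(p))   # +1: best ligand is the most expensive
  sp_neg <- generate_synthetic_space(synthetic_spec(price_quality_cor = -1,
                                                    seed = 9))
  q2 <- sp_neg$truth$quality
  p2 <- compound_prices(sp_neg)[names(q2)]
  expect_equal(rank(q2), rank(-p2))
})

test_that("synthetic fingerprints give quality-correlated kernel structure", {
  sp <- generate_synthetic_space(synthetic_spec(seed = 5))
  q <- sp$truth$quality
  lig <- names(q)
  sims <- numeric(0); dq <- numeric(0)
  for (i in seq_along(lig)) for (j in seq_along(lig)) {
    if (i < j) {
      sims <- c(sims, tanimoto_similarity(
        sp$compounds[[lig[i]]]$fingerprint,
        sp$compounds[[lig[j]]]$fingerprint
      ))
      dq <- c(dq, abs(q[i] - q[j]))
    }
  }
  expect_lt(cor(sims, dq), -0.3)   # similar quality => similar fingerprint
})

test_that("select_initialization strategies", {
  sp <- generate_synthetic_space(synthetic_spec(seed = 2))
  init <- select_initialization(sp, "cheapest")
  expect_length(init, 144L)   # all conditions of the single cheapest ligand
  roles <- vapply(sp$compounds, function(x) x$role, character(1))
  lig_prices <- compound_prices(sp)[roles == "ligand"]
  cheapest <- names(lig_prices)[which.min(lig_prices)]
  expect_true(all(sp$candidates$ligand[init] == cheapest))
  expect_equal(select_initialization(sp, c(3, 1, 2)), 1:3)
  named <- select_initialization(sp, paste0("named:", cheapest))
  expect_equal(named, init)
  expect_error(select_initialization(sp, "named:NOPE"), "NOPE")
  expect_error(select_initialization(sp, c(0, 5)), "out of range")
  # price tie between two ligands breaks deterministically by id
  comps <- list(compound("LZ", "ligand", 5, fp = fingerprint(1, 16)),
                compound("LA", "ligand", 5, fp = fingerprint(2, 16)))
  grid <- data.frame(ligand = c("LZ", "LA"), yield = c(10, 20))
  tie <- design_space(grid, comps)
  expect_equal(select_initialization(tie, "cheapest"), 2L)  # LA wins
})

test_that("minimal_spend: forced minimum, boundary, oracle agreement", {
  sp <- tiny_space(lig_prices = c(10, 99), base_prices = c(0, 0),
                   yields = c(10, 100, 10, 100, 10, 100, 10, 100, 10, 100,
                              10, 100))
  expect_equal(minimal_spend(sp, 100), 99)   # only the 99-ligand reaches 100
  expect_equal(minimal_spend(sp, 0), 10)     # cheapest candidate compound set
  expect_true(is.na(minimal_spend(sp, 101)))
  for (seed in 1:5) {
    rsp <- small_cc_space(seed)
    tgt <- stats::quantile(rsp$candidates$yield, 0.9)
    expect_equal(minimal_spend(rsp, tgt), minimal_spend_oracle(rsp, tgt))
  }
})

test_that("design-space CSV round-trips bit-exactly enough", {
  sp <- generate_synthetic_space(synthetic_spec(
    n_ligands = 3, n_bases = 2, n_solvents = 2,
    priced_roles = c("ligand", "base"), n_bits = 64, seed = 6
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_space(sp, path)
  sp2 <- read_design_space(path, schema = list(
    role_columns = c("ligand", "base", "solvent"),
    condition_columns = sp$conditions, n_bits = 64
  ))
  expect_equal(sp2$candidates$yield, sp$candidates$yield, tolerance = 1e-12)
  expect_equal(sp2$candidates$ligand, sp$candidates$ligand)
  expect_equal(compound_prices(sp2)[names(compound_prices(sp))],
               compound_prices(sp), tolerance = 1e-12)
  for (id in names(sp$compounds)) {
    expect_identical(as.integer(sp2$compounds[[id]]$fingerprint),
                     as.integer(sp$compounds[[id]]$fingerprint))
  }
  # and a second write produces an identical file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_design_space(sp2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_design_space validates schema and prices", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(ligand = c("L1", "L2"), ligand_price = c(5, 8),
                  temperature = c(20, 30), yield = c(10, 90))
  utils::write.csv(d, path, row.names = FALSE)
  # fingerprint-free, SMILES-free compounds are rejected by the compound
  # contract (no structure and no fingerprint)
  expect_error(read_design_space(path, schema = list(
    role_columns = "ligand", condition_columns = "temperature"
  )), "structure")
  d$ligand_smiles <- c("CCO", "CCN")
  utils::write.csv(d, path, row.names = FALSE)
  sp <- read_design_space(path, schema = list(
    role_columns = "ligand", condition_columns = "temperature"
  ))
  expect_equal(nrow(sp$candidates), 2L)
  # missing price column
  expect_error(read_design_space(path, schema = list(
    role_columns = c("ligand", "base"), condition_columns = "temperature"
  )), "base")
  # negative price
  d$ligand_price <- c(-1, 8)
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_design_space(path, schema = list(
    role_columns = "ligand", condition_columns = "temperature"
  )), "negative")
  expect_error(read_design_space("/nonexistent.csv", schema = list(
    role_columns = "ligand"
  )), "no such file")
})

test_that("toy 2x3 table reads into a complete lookup oracle", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(
    ligand = rep(c("PPh3", "PCy3"), each = 3),
    ligand_price = rep(c(2, 30), each = 3),
    ligand_smiles = rep(c("P(c1ccccc1)(c1ccccc1)c1ccccc1",
                          "P(C1CCCCC1)(C1CCCCC1)C1CCCCC1"), each = 3),
    temperature = rep(c(40, 60, 80), 2),
    yield = c(10, 20, 30, 60, 80, 95)
  )
  utils::write.csv(d, path, row.names = FALSE)
  sp <- read_design_space(path, schema = list(
    role_columns = "ligand", condition_columns = "temperature"
  ))
  expect_equal(nrow(sp$candidates), 6L)
  expect_length(sp$compounds, 2L)
  expect_false(anyNA(sp$candidates$yield))
  # referential integrity enforced at construction
  comps <- list(compound("A", "ligand", 1, fp = fingerprint(1, 8)))
  bad <- data.frame(ligand = c("A", "GHOST"), yield = c(1, 2))
  expect_error(design_space(bad, comps), "uncataloged")
})
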