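# Structure/label I/O, conformer generation, feature perception.

write_tmp_smiles <- function(lines) {
  f <- withr::local_tempfile(fileext = ".smi",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

write_tmp_labels <- function(df) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  readr::write_csv(df, f)
  f
}

test_that("SMILES + label CSV round-trips ids and labels", {
  smi <- write_tmp_smiles(c("c1ccccc1 b1", "CCO e1", "CCCCCC h1"))
  lab <- write_tmp_labels(tibble::tibble(
    mol_id = c("b1", "e1", "h1"),
    label = c("active", "inactive", "active")
  ))
  lib <- read_labeled_library(smi, lab)
  expect_equal(nrow(lib), 3)
  expect_equal(lib$label[match(c("b1", "e1", "h1"), lib$mol_id)],
               c("active", "inactive", "active"))
  expect_true(all(lib$mol_weight > 0))
})

test_that("unparsable SMILES lines are dropped with a warning, not fatal", {
  smi <- write_tmp_smiles(c("c1ccccc1 a", "C1CC b", "CCO c",
                            "CCC d", "CC(=O)O e"))
  expect_warning(lib <- read_labeled_library(smi), "failed to parse")
  expect_equal(nrow(lib), 4)
  expect_equal(attr(lib, "failures"), "b")
})

test_that("unlabeled molecules get label unknown; duplicate ids error", {
  smi <- write_tmp_smiles(c("CCO e1", "CCC p1"))
  lab <- write_tmp_labels(tibble::tibble(mol_id = "e1", label = "active"))
  lib <- read_labeled_library(smi, lab)
  expect_equal(lib$label[lib$mol_id == "p1"], "unknown")

  smi2 <- write_tmp_smiles(c("CCO x", "CCC x"))
  expect_error(read_labeled_library(smi2), "duplicate mol_id")
})

test_that("feature-cloud library round-trips through CSV", {
  fix <- make_planted_library(n_active = 5, n_inactive = 10, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_library(fix$library, f)
  back <- read_feature_library(f)
  expect_equal(back$mol_id, fix$library$mol_id)
  expect_equal(back$label, fix$library$label)
  expect_equal(sum(back$label == "active"), 5)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$features[[i]]$ftype, fix$library$features[[i]]$ftype)
    expect_equal(back$features[[i]]$x, fix$library$features[[i]]$x)
  }
})

test_that("SDF + CSV library round-trips ids, labels and feature multisets", {
  lib <- make_smiles_fixture()
  lib <- generate_conformers(lib, max_confs = 3, seed = 1)
  lib <- perceive_features(lib)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, sdf, csv)
  back <- read_labeled_library(sdf, csv)
  expect_setequal(back$mol_id, lib$mol_id)
  expect_equal(back$label[match(lib$mol_id, back$mol_id)], lib$label)
  back <- generate_conformers(back, max_confs = 3, seed = 1)
  back <- perceive_features(back)
  for (id in c("benzene", "phenol", "benzamidine", "acetic_acid")) {
    f1 <- sort(lib$features[[which(lib$mol_id == id)]]$ftype)
    f2 <- sort(back$features[[which(back$mol_id == id)]]$ftype)
    expect_equal(f2, f1, label = paste("feature multiset of", id))
  }
})

test_that("rigid molecules give one conformer; ensembles are deterministic", {
  smi <- write_tmp_smiles(c("c1ccccc1 benzene", "CCCCCC hexane"))
  lib <- read_labeled_library(smi)
  a <- generate_conformers(lib, max_confs = 10, seed = 1)
  b <- generate_conformers(lib, max_confs = 10, seed = 1)
  # benzene: a single conformer (no rotatable bonds)
  expect_equal(length(unique(a$conformers[[1]]$conf_id)), 1)
  # hexane: several, capped, and bit-identical across runs
  nhex <- length(unique(a$conformers[[2]]$conf_id))
  expect_gte(nhex, 2)
  expect_lte(nhex, 10)
  expect_identical(a$conformers, b$conformers)
})

test_that("conformer ensembles respect max_confs and separate geometries", {
  smi <- write_tmp_smiles("CCCCCC hexane")
  lib <- read_labeled_library(smi)
  lib <- generate_conformers(lib, max_confs = 4, seed = 2, prune_rmsd = 0.3)
  confs <- lib$conformers[[1]]
  ids <- unique(confs$conf_id)
  expect_lte(length(ids), 4)
  # any two kept conformers differ in their sorted distance signature
  sig <- lapply(ids, function(cid) {
    cc <- confs[confs$conf_id == cid, ]
    sort(as.vector(dist(as.matrix(cc[, c("x", "y", "z")]))))
  })
  for (i in seq_along(sig)) for (j in seq_len(i - 1)) {
    expect_gt(sqrt(mean((sig[[i]] - sig[[j]])^2)), 0.3)
  }
})

test_that("perception applies the shipped rule table", {
  smi <- write_tmp_smiles(c("c1ccccc1 benzene", "CC(=O)[O-] acetate",
                            "CC(=O)O acetic_acid", "CC[NH3+] ethylammonium"))
  lib <- read_labeled_library(smi)
  lib <- generate_conformers(lib, max_confs = 1, seed = 1)
  lib <- perceive_features(lib)
  feats <- function(id) lib$features[[which(lib$mol_id == id)]]

  # benzene: exactly one R at the ring centroid, nothing else
  fb <- feats("benzene")
  expect_equal(fb$ftype, "R")
  cc <- lib$conformers[[which(lib$mol_id == "benzene")]]
  expect_equal(unname(c(fb$x, fb$y, fb$z)),
               c(mean(cc$x), mean(cc$y), mean(cc$z)),
               tolerance = 1e-8)

  # acetate and neutral acetic acid: exactly one N on the carboxylate
  # (pH-7.4 convention), no other features
  expect_equal(feats("acetate")$ftype, "N")
  expect_equal(feats("acetic_acid")$ftype, "N")

  # protonated amine: P only (never D), plus the terminal methyl hydrophobe
  fe <- feats("ethylammonium")
  expect_equal(sort(fe$ftype), c("H", "P"))
})

test_that("a structure with zero atoms yields no features", {
  graph <- list(
    atoms = tibble::tibble(idx = integer(), element = character(),
                           charge = integer(), arom = logical(),
                           nH = integer()),
    bonds = tibble::tibble(a1 = integer(), a2 = integer(), order = integer()),
    arom_rings = list()
  )
  out <- perceive_conformer_features(graph, matrix(numeric(0), 0, 3))
  expect_equal(nrow(out), 0)
})

test_that("perception is invariant under rigid motion of the conformer", {
  lib <- make_smiles_fixture()
  lib <- generate_conformers(lib, max_confs = 1, seed = 1)
  lib <- perceive_features(lib)
  i <- which(lib$mol_id == "p_toluic_acid")
  graph <- lib$structure[[i]]
  cc <- lib$conformers[[i]]
  xyz <- as.matrix(cc[order(cc$atom), c("x", "y", "z")])
  f0 <- perceive_conformer_features(graph, xyz)

  set.seed(42)
  for (rep in 1:5) {
    rot <- rigid_rotation()
    shift <- runif(3, -10, 10)
    f1 <- perceive_conformer_features(
      graph, sweep(xyz %*% t(rot), 2, shift, FUN = "+"))
    expect_equal(f1$ftype, f0$ftype)
    moved <- sweep(as.matrix(f0[, c("x", "y", "z")]) %*% t(rot), 2, shift,
                   FUN = "+")
    expect_equal(as.matrix(f1[, c("x", "y", "z")]), moved,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("the shipped fixture library covers all six feature types", {
  lib <- make_smiles_fixture()
  expect_equal(length(attr(lib, "failures")), 0)
  lib <- generate_conformers(lib, max_confs = 1, seed = 1)
  lib <- perceive_features(lib)
  seen <- sort(unique(unlist(lapply(lib$features, function(f) f$ftype))))
  expect_equal(seen, c("A", "D", "H", "N", "P", "R"))
})
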