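# Union-rule classification, confusion metrics, combinatorial enumeration
# and highest-BACC selection.

random_match_tibble <- function(n_mol, hyp_ids, p = 0.2) {
  m <- matrix(runif(n_mol * length(hyp_ids)) < p, n_mol, length(hyp_ids))
  colnames(m) <- hyp_ids
  dplyr::bind_cols(tibble::tibble(mol_id = sprintf("m%03d", seq_len(n_mol))),
                   tibble::as_tibble(m))
}

test_that("the union rule predicts active on any member match", {
  expect_equal(classify_union(c(TRUE, FALSE, FALSE, FALSE)), "active")
  expect_equal(classify_union(c(FALSE, FALSE, FALSE)), "inactive")
  expect_equal(classify_union(rep(TRUE, 4)), "active")
  expect_error(classify_union(logical()), "non-empty")
})

test_that("confusion metrics satisfy their defining identities", {
  m <- confusion_metrics(rep(c("active", "inactive"), c(10, 10)),
                         rep(c("active", "inactive", "active", "inactive"),
                             each = 5))
  expect_equal(m$tp, 5); expect_equal(m$fp, 5)
  expect_equal(m$se, 0.5); expect_equal(m$sp, 0.5)
  expect_equal(m$acc, 0.5); expect_equal(m$bacc, 0.5)

  perfect <- confusion_metrics(rep(c("active", "inactive"), c(5, 5)),
                               rep(c("active", "inactive"), c(5, 5)))
  expect_equal(unlist(perfect[c("se", "sp", "acc", "bacc")]),
               c(se = 1, sp = 1, acc = 1, bacc = 1))

  expect_error(confusion_metrics(rep("active", 3), rep("active", 3)),
               "no 'inactive'")
})

test_that("the back-solved calibration row reproduces the published rates", {
  # counts recovered from a 42-inhibitor / 399-noninhibitor calibration set
  truth <- rep(c("active", "inactive"), c(42, 399))
  pred <- c(rep("active", 31), rep("inactive", 11),
            rep("active", 96), rep("inactive", 303))
  m <- confusion_metrics(pred, truth)
  expect_equal(m$tp, 31); expect_equal(m$fn, 11)
  expect_equal(m$tn, 303); expect_equal(m$fp, 96)
  expect_equal(round(m$se, 2), 0.74)
  expect_equal(round(m$sp, 2), 0.76)
  expect_equal(round(m$acc, 2), 0.76)
  expect_equal(round(m$bacc, 2), 0.75)
})

test_that("model enumeration is complete, unique and ordered", {
  expect_equal(nrow(enumerate_cp_models(sprintf("h%02d", 1:27))), 20475)
  expect_equal(nrow(enumerate_cp_models(paste0("h", 1:4))), 5)   # C(4,3)+C(4,4)
  expect_equal(nrow(enumerate_cp_models(paste0("h", 1:3))), 1)
  cand <- enumerate_cp_models(c("b", "a", "c", "d"), sizes = 3)
  expect_equal(cand$model_id[1], "a+b+c")           # lexicographic
  expect_equal(anyDuplicated(cand$model_id), 0)
  expect_warning(out <- enumerate_cp_models(c("a", "b"), sizes = c(3, 4)),
                 "smaller")
  expect_equal(nrow(out), 0)
})

test_that("enumeration count matches the closed form for n = 3..30", {
  for (n in c(3:12, 20, 27, 30)) {
    pool <- sprintf("h%02d", seq_len(n))
    expect_equal(nrow(enumerate_cp_models(pool, sizes = c(3, 4))),
                 choose(n, 3) + choose(n, 4))
  }
})

test_that("select_best maximizes calibration BACC deterministically", {
  set.seed(5)
  hyp_ids <- sprintf("h%02d", 1:10)
  mm <- random_match_tibble(120, hyp_ids, p = 0.25)
  truth <- tibble::tibble(mol_id = mm$mol_id,
                          label = rep(c("active", "inactive"), c(30, 90)))
  cand <- enumerate_cp_models(hyp_ids, sizes = c(3, 4))
  best <- select_best(cand, mm, truth)

  # independent exhaustive re-scan
  M <- as.matrix(as.data.frame(mm)[, hyp_ids])
  y <- truth$label
  bacc_of <- function(members) {
    pred <- ifelse(rowSums(M[, members, drop = FALSE]) > 0,
                   "active", "inactive")
    unname(bf_metrics(pred, y)["bacc"])
  }
  all_bacc <- vapply(cand$members, bacc_of, numeric(1))
  expect_equal(best$metrics_calibration$bacc, max(all_bacc))

  # single candidate returns itself; ranking respects bacc
  one <- select_best(cand[17, ], mm, truth)
  expect_equal(one$members, cand$members[[17]])
  expect_equal(best$ranked$bacc, sort(all_bacc, decreasing = TRUE),
               tolerance = 1e-12)
})

test_that("select_best is invariant under candidate permutation", {
  set.seed(6)
  hyp_ids <- sprintf("h%02d", 1:8)
  mm <- random_match_tibble(80, hyp_ids, p = 0.3)
  truth <- tibble::tibble(mol_id = mm$mol_id,
                          label = rep(c("active", "inactive"), c(20, 60)))
  cand <- enumerate_cp_models(hyp_ids, sizes = c(3, 4))
  a <- select_best(cand, mm, truth)
  b <- select_best(cand[sample(nrow(cand)), ], mm, truth)
  expect_equal(a$members, b$members)
  expect_equal(a$metrics_calibration, b$metrics_calibration)
})

test_that("degenerate models hit the expected metric extremes", {
  fix <- make_planted_library(n_active = 5, n_inactive = 15, seed = 8)
  truth <- tibble::tibble(mol_id = fix$library$mol_id,
                          label = fix$library$label)
  mm <- build_match_matrix(fix$library, fix$manifest$planted_hyps)
  # add a never-matching and an always-matching pseudo-hypothesis column
  mm$never <- FALSE
  mm$always <- TRUE
  m_never <- evaluate_on_set("never", mm, truth)
  expect_equal(m_never$se, 0); expect_equal(m_never$sp, 1)
  m_always <- evaluate_on_set("always", mm, truth)
  expect_equal(m_always$se, 1); expect_equal(m_always$sp, 0)
  # manifest oracle: both plants together classify the library perfectly
  m_plants <- evaluate_on_set(fix$manifest$planted_hyps$hyp_id, mm, truth)
  expect_equal(m_plants$se, 1)
  expect_equal(m_plants$sp, 1)
})

test_that("adding a member never decreases SE nor increases SP", {
  set.seed(9)
  for (rep in 1:30) {
    hyp_ids <- sprintf("h%02d", 1:6)
    mm <- random_match_tibble(60, hyp_ids, p = runif(1, 0.05, 0.5))
    truth <- tibble::tibble(mol_id = mm$mol_id,
                            label = rep(c("active", "inactive"), c(15, 45)))
    base <- sample(hyp_ids, 3)
    extra <- sample(setdiff(hyp_ids, base), 1)
    m0 <- evaluate_on_set(base, mm, truth)
    m1 <- evaluate_on_set(c(base, extra), mm, truth)
    expect_gte(m1$se, m0$se)
    expect_lte(m1$sp, m0$sp)
    # bacc lies between se and sp
    expect_gte(m1$bacc, min(m1$se, m1$sp))
    expect_lte(m1$bacc, max(m1$se, m1$sp))
  }
})

test_that("evaluate_on_set reports molecules missing from the matrix", {
  fix <- make_planted_library(n_active = 3, n_inactive = 3, seed = 10)
  mm <- build_match_matrix(fix$library, fix$manifest$planted_hyps)
  truth <- tibble::tibble(mol_id = c(fix$library$mol_id[-1]),
                          label = fix$library$label[-1])
  expect_error(evaluate_on_set("HHR", mm, truth), fix$library$mol_id[1])
})

test_that("the stratified split preserves class balance and is seeded", {
  fix <- make_planted_library(n_active = 10, n_inactive = 40, seed = 12)
  sp1 <- split_calibration_test(fix$library, seed = 3)
  sp2 <- split_calibration_test(fix$library, seed = 3)
  expect_equal(sp1$calibration$mol_id, sp2$calibration$mol_id)
  expect_equal(sum(sp1$calibration$label == "active"), 5)
  expect_equal(sum(sp1$test$label == "inactive"), 20)
  expect_equal(sort(c(sp1$calibration$mol_id, sp1$test$mol_id)),
               sort(fix$library$mol_id))
})

test_that("cp_model accessors: print, tidy, glance, autoplot, JSON", {
  set.seed(14)
  hyp_ids <- sprintf("h%02d", 1:5)
  mm <- random_match_tibble(50, hyp_ids, p = 0.3)
  truth <- tibble::tibble(mol_id = mm$mol_id,
                          label = rep(c("active", "inactive"), c(15, 35)))
  best <- select_best(enumerate_cp_models(hyp_ids), mm, truth)
  expect_output(print(best), "Combinatorial pharmacophore model")
  td <- tidy(best)
  expect_equal(nrow(td), best$size)
  gl <- glance(best)
  expect_equal(gl$bacc, best$metrics_calibration$bacc)
  expect_s3_class(autoplot(best), "ggplot")

  f <- withr::local_tempfile(fileext = ".json")
  write_cp_model(best, f)
  back <- read_cp_model(f)
  expect_equal(back$members, best$members)
  expect_equal(back$metrics$bacc, best$metrics_calibration$bacc)
})
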