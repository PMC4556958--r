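# Hypothesis generation, scoring and filtering.

# one-molecule library wrapper around a feature table
cloud_library <- function(feats, ids = NULL, labels = "active") {
  if (is.data.frame(feats)) feats <- list(feats)
  n <- length(feats)
  tibble::tibble(
    mol_id = ids %||% sprintf("m%02d", seq_len(n)),
    label = rep_len(labels, n),
    features = lapply(feats, function(f) {
      if (!"conf_id" %in% names(f)) f <- dplyr::mutate(f, conf_id = 1L)
      f
    })
  )
}

tri_feats <- function(types = c("H", "H", "R")) {
  tibble::tibble(ftype = types, x = c(0, 3, 0), y = c(0, 0, 4), z = 0)
}

test_that("a single exact tuple yields exactly one hypothesis", {
  lib <- cloud_library(tri_feats())
  hyps <- enumerate_candidate_hypotheses(lib, k_values = 3, min_actives = 1)
  expect_equal(nrow(hyps), 1)
  expect_equal(hyps$hyp_id, "HHR")
  expect_equal(sort(hyps$dist[[1]][upper.tri(hyps$dist[[1]])]), c(3, 4, 5))
})

test_that("a common planted triangle is found among decoys (brute-force check)", {
  set.seed(7)
  feats <- lapply(1:5, function(i) {
    rot <- rigid_rotation()
    pts <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), 3, 3, byrow = TRUE) %*% t(rot)
    pts <- sweep(pts, 2, runif(3, 0, 5), FUN = "+")
    dplyr::bind_rows(
      tibble::tibble(ftype = c("H", "H", "R"),
                     x = pts[, 1], y = pts[, 2], z = pts[, 3]),
      random_cloud(4)
    )
  })
  lib <- cloud_library(feats)
  hyps <- enumerate_candidate_hypotheses(lib, k_values = 3, min_actives = 5,
                                         bin_width = 1.0)
  hhr <- hyps[vapply(hyps$sites, function(s) identical(s, c("H", "H", "R")),
                     logical(1)), ]
  expect_gte(nrow(hhr), 1)
  devs <- vapply(seq_len(nrow(hhr)), function(i) {
    max(abs(sort(hhr$dist[[i]][upper.tri(hhr$dist[[i]])]) - c(3, 4, 5)))
  }, numeric(1))
  expect_lte(min(devs), 1.0)

  # brute force: the (3,4,5) HHR triple really is present in all five actives
  for (f in feats) {
    hyp <- list(hyp_id = "HHR", sites = c("H", "H", "R"),
                dist = matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), tol = 0.01)
    expect_true(bf_match(f, hyp)$matched)
  }
})

test_that("actives with disjoint feature vocabularies share no hypothesis", {
  f1 <- tibble::tibble(ftype = c("A", "A", "A"), x = c(0, 3, 0),
                       y = c(0, 0, 4), z = 0)
  f2 <- tibble::tibble(ftype = c("H", "H", "H"), x = c(0, 3, 0),
                       y = c(0, 0, 4), z = 0)
  lib <- cloud_library(list(f1, f2))
  hyps <- enumerate_candidate_hypotheses(lib, k_values = 3, min_actives = 2)
  expect_equal(nrow(hyps), 0)
})

test_that("every emitted hypothesis is matched by >= min_actives of its actives", {
  fix <- make_planted_library(n_active = 8, n_inactive = 0, seed = 13)
  lib <- fix$library[fix$library$label == "active", ]
  hyps <- enumerate_candidate_hypotheses(lib, k_values = c(3, 4),
                                         min_actives = 3, tol = 1.0)
  expect_gt(nrow(hyps), 0)
  for (i in seq_len(nrow(hyps))) {
    n_matched <- sum(vapply(lib$features, function(ft) {
      match_molecule(ft, hyps[i, ])$matched
    }, logical(1)))
    expect_gte(n_matched, 3)
  }
})

test_that("generation is invariant to the order of the actives", {
  fix <- make_planted_library(n_active = 6, n_inactive = 0, seed = 17)
  lib <- fix$library
  h1 <- enumerate_candidate_hypotheses(lib, min_actives = 3)
  set.seed(1)
  h2 <- enumerate_candidate_hypotheses(lib[sample(nrow(lib)), ],
                                       min_actives = 3)
  expect_equal(h1$hyp_id, h2$hyp_id)
  expect_equal(h1$dist, h2$dist)
  expect_equal(h1$support_ids, h2$support_ids)
})

test_that("an active without features is excluded with a warning", {
  lib <- cloud_library(list(
    tri_feats(),
    tibble::tibble(conf_id = integer(), ftype = character(),
                   x = numeric(), y = numeric(), z = numeric())
  ))
  expect_warning(
    hyps <- enumerate_candidate_hypotheses(lib, k_values = 3, min_actives = 1),
    "without features"
  )
  expect_equal(hyps$hyp_id, "HHR")
})

test_that("survival score is the matched-active fraction", {
  # 5 molecules carry the HHR triangle, 5 carry nothing useful
  feats <- c(replicate(5, tri_feats(), simplify = FALSE),
             replicate(5, tibble::tibble(ftype = "A", x = 0, y = 0, z = 0),
                       simplify = FALSE))
  lib <- cloud_library(feats)
  hyp <- list(hyp_id = "HHR", sites = c("H", "H", "R"),
              dist = matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), tol = 0.5)
  expect_equal(survival_score(hyp, lib), 0.5)
  expect_equal(survival_score(hyp, lib[1:5, ]), 1.0)
  expect_equal(survival_score(hyp, lib[6:10, ]), 0.0)
  expect_error(survival_score(hyp, lib[0, ]), "non-empty")
})

test_that("survival-inactive is the lambda-penalized difference", {
  lib_a <- cloud_library(replicate(10, tri_feats(), simplify = FALSE))
  hyp <- list(hyp_id = "HHR", sites = c("H", "H", "R"),
              dist = matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), tol = 0.5)
  lib_i5 <- cloud_library(
    c(replicate(2, tri_feats(), simplify = FALSE),
      replicate(8, tibble::tibble(ftype = "A", x = 0, y = 0, z = 0),
                simplify = FALSE)),
    ids = sprintf("i%02d", 1:10), labels = "inactive")
  # f_active = 1.0, f_inactive = 0.2, lambda = 1 -> 0.8
  expect_equal(
    survival_inactive_score(hyp, lib_a, lib_i5, penalty_lambda = 1), 0.8)
  # lambda = 0 reduces to survival
  expect_equal(
    survival_inactive_score(hyp, lib_a, lib_i5, penalty_lambda = 0),
    survival_score(hyp, lib_a))
  # monotone non-increasing in lambda
  vals <- vapply(c(0, 0.5, 1, 2), function(l) {
    survival_inactive_score(hyp, lib_a, lib_i5, penalty_lambda = l)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  # empty inactives: warning, equals survival
  expect_warning(
    v <- survival_inactive_score(hyp, lib_a, lib_i5[0, ]), "no inactives")
  expect_equal(v, 1.0)
})

test_that("selectivity is the add-one log rarity", {
  hyp <- list(hyp_id = "HHR", sites = c("H", "H", "R"),
              dist = matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), tol = 0.5)
  # all N match -> 0
  lib_all <- cloud_library(replicate(10, tri_feats(), simplify = FALSE))
  expect_equal(selectivity_score(hyp, lib_all), 0)
  # N = 99, none match -> -log10(1/100) = 2
  lib_none <- cloud_library(
    replicate(99, tibble::tibble(ftype = "A", x = 0, y = 0, z = 0),
              simplify = FALSE),
    ids = sprintf("n%03d", 1:99))
  expect_equal(selectivity_score(hyp, lib_none), 2)
  # N = 999, 9 match -> -log10(10/1000) = 2 (stub matcher: pure arithmetic)
  lib_big <- cloud_library(
    replicate(999, tibble::tibble(ftype = "A", x = 0, y = 0, z = 0),
              simplify = FALSE),
    ids = sprintf("n%03d", 1:999))
  calls <- 0
  stub_fn <- function(ft, h) {
    calls <<- calls + 1
    list(matched = calls <= 9)
  }
  expect_equal(selectivity_score(hyp, lib_big, match_fn = stub_fn), 2)
  # strictly decreasing in n_matched for fixed N
  sel <- vapply(c(0, 3, 9, 99), function(nm) {
    calls <<- 0
    f <- function(ft, h) {
      calls <<- calls + 1
      list(matched = calls <= nm)
    }
    selectivity_score(hyp, lib_none, match_fn = f)
  }, numeric(1))
  expect_true(all(diff(sel) < 0))
})

test_that("score_hypotheses summarises survival, penalty and rarity per hypothesis", {
  fix <- make_planted_library(n_active = 6, n_inactive = 20, seed = 19)
  hyps <- fix$manifest$planted_hyps
  sc <- score_hypotheses(hyps, fix$library)
  expect_equal(sc$hyp_id, hyps$hyp_id)
  # each plant is carried by half the actives, inactives never match
  expect_equal(sc$n_active_matched >= 3, c(TRUE, TRUE))
  expect_equal(sc$n_inactive_matched, c(0, 0))
  expect_equal(sc$survival_inactive, sc$survival)
  expect_equal(sc$selectivity,
               -log10((sc$n_active_matched + 1) / (nrow(fix$library) + 1)))
})

test_that("filtering keeps threshold passers, then the fewest-inactive top k", {
  hyps <- new_test_hypotheses(5)
  scores <- tibble::tibble(
    hyp_id = hyps$hyp_id,
    survival = c(0.9, 0.8, 0.7, 0.6, 0.5),
    survival_inactive = c(0.5, 0.4, 0.3, 0.2, 0.1),
    selectivity = c(2, 2, 2, 2, 2),
    n_active_matched = 5:1,
    n_inactive_matched = c(0, 1, 2, 3, 4)
  )
  # pass-through
  all_kept <- filter_hypotheses(scores, hyps, survival_inactive_min = -Inf,
                                selectivity_min = -Inf,
                                inactive_match_top_k = 10)
  expect_equal(all_kept$hyp_id, sort(hyps$hyp_id))
  # top 2 by fewest inactive matches
  top2 <- filter_hypotheses(scores, hyps, survival_inactive_min = -Inf,
                            selectivity_min = -Inf, inactive_match_top_k = 2)
  expect_equal(sort(top2$hyp_id), sort(hyps$hyp_id[1:2]))
})

test_that("filter ties resolve by survival-inactive then hyp_id, deterministically", {
  hyps <- new_test_hypotheses(4)
  scores <- tibble::tibble(
    hyp_id = hyps$hyp_id,
    survival = 0.5,
    survival_inactive = c(0.3, 0.5, 0.5, 0.2),
    selectivity = 1,
    n_active_matched = 3,
    n_inactive_matched = c(1, 1, 1, 0)
  )
  got <- filter_hypotheses(scores, hyps, survival_inactive_min = -Inf,
                           selectivity_min = -Inf, inactive_match_top_k = 2)
  # exhaustive stable sort oracle
  ord <- order(scores$n_inactive_matched, -scores$survival_inactive,
               scores$hyp_id)
  expect_equal(sort(got$hyp_id), sort(scores$hyp_id[ord[1:2]]))
  # stable across permuted input
  set.seed(2)
  p <- sample(4)
  got2 <- filter_hypotheses(scores[p, ], hyps[p, ],
                            survival_inactive_min = -Inf,
                            selectivity_min = -Inf, inactive_match_top_k = 2)
  expect_equal(got2$hyp_id, got$hyp_id)
})

test_that("hypotheses round-trip exactly through JSON", {
  fix <- make_planted_library(n_active = 6, n_inactive = 0, seed = 23)
  hyps <- enumerate_candidate_hypotheses(fix$library, min_actives = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_hypotheses(hyps, f)
  back <- read_hypotheses(f)
  expect_equal(back$hyp_id, hyps$hyp_id)
  expect_equal(back$sites, hyps$sites)
  expect_equal(back$dist, hyps$dist)
  expect_equal(back$tol, hyps$tol)
})
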