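test_that("kissing-loop and eRMSD filter retains exactly the valid models", {
  coll <- toy_collection(n = 3, seed = 7)
  ref <- toy_reference(coll)

  # model 1: break a required pair -> altered KL
  m1 <- coll$models[[1]]
  sel <- m1$atoms$resno == 7 & m1$atoms$atom != "C1'"
  m1$atoms$x[sel] <- m1$atoms$x[sel] + 2.0

  # model 2: shift a whole stem pair -> preserved but eRMSD > 0.8
  m2 <- coll$models[[2]]
  sel <- m2$atoms$resno %in% c(2, 7)
  m2$atoms$z[sel] <- m2$atoms$z[sel] + 2.0

  m3 <- coll$models[[3]]
  test_coll <- structure_collection(list(m1, m2, m3))
  ann <- annotate_collection(test_coll, ref)
  expect_equal(ann$kl_status, c("altered", "preserved", "preserved"))
  expect_gt(ann$ermsd[2], 0.8)
  expect_lte(ann$ermsd[3], 0.8)

  kept <- filter_collection(test_coll, ref, annotations = ann)
  expect_equal(length(kept), 1L)
  expect_equal(model_ids(kept), m3$model_id)
  audit <- attr(kept, "audit")
  expect_equal(audit$retained, c(FALSE, FALSE, TRUE))
})

test_that("the eRMSD threshold is inclusive and the filter is order-independent", {
  coll <- toy_collection(n = 3, seed = 7)
  ref <- toy_reference(coll)
  ann <- data.frame(model_id = model_ids(coll),
                    kl_status = "preserved",
                    ermsd = c(0.8, 0.800000001, 0.5),
                    n_canonical = 8L)
  kept <- filter_collection(coll, ref, annotations = ann)
  expect_setequal(model_ids(kept), model_ids(coll)[c(1, 3)])

  perm <- structure_collection(coll$models[c(3, 1, 2)])
  kept_perm <- filter_collection(perm, ref, annotations = ann)
  expect_setequal(model_ids(kept_perm), model_ids(kept))
})

test_that("unweighted selection reproduces |B_i|/N with multiplicity one", {
  e <- c(rep(0.02, 2), rep(0.32, 3), rep(0.61, 5))
  rec <- data.frame(model_id = sprintf("m%02d", 1:10), E_DA = e)
  h <- histogram_efficiencies(rec, 0.05)
  w <- unweighted_selection(h)
  expect_equal(w$n_total, 10L)
  expect_true(all(w$table$multiplicity == 1L))
  sh <- fretsel:::selection_histogram(w, rec, 0.05)
  expect_equal(sh$probabilities[c(1, 7, 13)], c(0.2, 0.3, 0.5))

  single <- histogram_efficiencies(data.frame(model_id = "only", E_DA = 0.4), 0.05)
  ws <- unweighted_selection(single)
  expect_equal(ws$table$model_id, "only")
  expect_equal(ws$n_total, 1L)

  empty <- histogram_efficiencies(data.frame(model_id = character(0),
                                             E_DA = numeric(0)), 0.05)
  expect_error(unweighted_selection(empty), "empty")
})

test_that("weighted selection matches the hand-apportionment oracle", {
  # populated bins 1 and 3 of four bins: |B| = (10, 0, 5, 0)
  rec <- data.frame(model_id = sprintf("m%02d", 1:15),
                    E_DA = c(rep(0.1, 10), rep(0.6, 5)))
  h <- histogram_efficiencies(rec, 0.25)
  target <- target_distribution(c(0.5, 0.3, 0.2, 0), 0.25)
  w <- weighted_selection(h, target, n_total = 10, seed = 1)
  quota <- attr(w, "quota")
  # renormalized over populated bins: (5/7, 2/7) -> largest remainder (7, 3)
  expect_equal(quota$quota, c(7L, 0L, 3L, 0L))
  expect_equal(attr(w, "discarded_mass"), 0.3)
  expect_equal(w$n_total, 10L)
  bin1 <- w$table$model_id[attr(w, "bin_of") == 1]
  expect_equal(length(bin1), 7L)             # scenario 1: distinct members
  expect_true(all(w$table$multiplicity[attr(w, "bin_of") == 1] == 1L))
  bin3 <- w$table$multiplicity[attr(w, "bin_of") == 3]
  expect_equal(sort(bin3), c(1L, 1L, 1L))    # 3 of the 5 members, once each
})

test_that("scenario 2 fills insufficient bins by repetition plus remainder", {
  rec <- data.frame(model_id = c("a", "b"), E_DA = c(0.1, 0.12))
  h <- histogram_efficiencies(rec, 0.25)
  target <- target_distribution(c(1, 0, 0, 0), 0.25)
  w <- weighted_selection(h, target, n_total = 5, seed = 3)
  expect_equal(sort(w$table$multiplicity), c(2L, 3L))  # |B| = 2, quota 5
  expect_equal(w$n_total, 5L)
})

test_that("weighted selection fails when no populated bin carries target mass", {
  rec <- data.frame(model_id = c("a", "b"), E_DA = c(0.9, 0.95))
  h <- histogram_efficiencies(rec, 0.25)
  target <- target_distribution(c(1, 0, 0, 0), 0.25)
  expect_error(weighted_selection(h, target, n_total = 5), "no overlap")
})

test_that("weighted per-bin frequencies track the renormalized target", {
  rec <- bimodal_records(400, seed = 9)
  h <- histogram_efficiencies(rec, 0.05)
  target <- generate_synthetic_smfret(0.5, 0.2, 5e4, 0.05, seed = 10)
  populated <- h$counts > 0
  p_renorm <- ifelse(populated, target$probabilities, 0)
  p_renorm <- p_renorm / sum(p_renorm)
  for (seed in 1:20) {
    w <- weighted_selection(h, target, n_total = 400, seed = seed)
    expect_equal(w$n_total, 400L)                      # exact conservation
    sh <- fretsel:::selection_histogram(w, rec, 0.05)
    expect_true(all(abs(sh$probabilities - p_renorm) <= 1 / 400 + 1e-12))
  }
})

test_that("contribution report gives percentages and unique counts", {
  w <- fretsel:::new_selection_weights(
    data.frame(model_id = c("a", "b"), multiplicity = c(3L, 1L)), "weighted"
  )
  tab <- report_contributions(w)
  expect_equal(tab$percent[tab$model_id == "a"], 75)
  expect_equal(tab$percent[tab$model_id == "b"], 25)
  expect_equal(attr(tab, "unique_count"), 2L)

  # unweighted: every contribution 1/N
  h <- histogram_efficiencies(bimodal_records(50, seed = 1), 0.05)
  tu <- report_contributions(unweighted_selection(h))
  expect_true(all(tu$percent == 2))
  expect_equal(attr(tu, "unique_count"), 50L)
})
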