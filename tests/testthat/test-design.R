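test_that("the main design enumerates 25 mutually exclusive cells", {
  cells <- enumerate_cells("main")
  expect_equal(nrow(cells), 25)
  one_way <- cells[xor(cells$drift_size != "none",
                       cells$threshold_size != "none"), ]
  two_way <- cells[cells$drift_size != "none" &
                     cells$threshold_size != "none", ]
  expect_equal(nrow(one_way), 6)
  expect_equal(nrow(two_way), 18)
  expect_equal(sum(cells$drift_size == "none" &
                     cells$threshold_size == "none"), 1)
  expect_equal(anyDuplicated(cells$cell_id), 0)
  # arrangement applies exactly when both effects are present
  expect_true(all((cells$arrangement != "n/a") ==
                    (cells$drift_size != "none" &
                       cells$threshold_size != "none")))
  expect_true(all(cells$trials_per_condition == 300))
  expect_true(all(cells$replicates == 100))
  expect_error(enumerate_cells("bogus"))
})

test_that("follow-up designs cover the diagnostic cells", {
  ss <- enumerate_cells("sample_size_followup")
  expect_equal(nrow(ss), 20)
  expect_equal(sort(unique(ss$trials_per_condition)), c(30, 100, 300, 900))
  pf <- enumerate_cells("prior_followup")
  expect_equal(nrow(pf), 5)
  expect_setequal(pf$true_variant,
                  c("null", "drift", "threshold", "complex"))
  expect_true(all(pf$drift_size %in% c("none", "small")))
})

test_that("cell parameters implement the effect table", {
  cells <- enumerate_cells("main")
  null_cell <- cells[cells$drift_size == "none" &
                       cells$threshold_size == "none", ]
  p <- cell_params(null_cell)
  expect_equal(p$cond1, p$cond2)
  expect_equal(unclass(p$cond1),
               list(v_c = 3, v_e = 2, sv_c = 1, sv_e = 1, A = 1, b = 2,
                    t0 = 0.3), ignore_attr = TRUE)

  sd <- cells[cells$drift_size == "small" & cells$threshold_size == "none", ]
  p2 <- cell_params(sd)
  expect_equal(p2$cond2$v_c, 3.3)
  expect_equal(p2$cond1$v_c, 3)
  expect_equal(p2$cond2$b, 2)

  lt <- cells[cells$threshold_size == "large" & cells$drift_size == "none", ]
  p3 <- cell_params(lt)
  expect_equal(p3$cond2$b, 1.595)

  # extreme: both manipulations in condition 2; balanced: threshold in 1
  ex <- cells[cells$drift_size == "moderate" &
                cells$threshold_size == "moderate" &
                cells$arrangement == "extreme", ]
  pex <- cell_params(ex)
  expect_equal(c(pex$cond2$v_c, pex$cond2$b), c(3.75, 1.74))
  expect_equal(c(pex$cond1$v_c, pex$cond1$b), c(3, 2))
  ba <- ex; ba$arrangement <- "balanced"
  pba <- cell_params(ba)
  expect_equal(c(pba$cond2$v_c, pba$cond2$b), c(3.75, 2))
  expect_equal(c(pba$cond1$v_c, pba$cond1$b), c(3, 1.74))
})

test_that("dataset generation is deterministic and respects the design", {
  cells <- enumerate_cells("main")
  cell <- cells[cells$drift_size == "small" &
                  cells$threshold_size == "none", ]
  d1 <- generate_dataset(cell, replicate = 3, master_seed = 7)
  d2 <- generate_dataset(cell, replicate = 3, master_seed = 7)
  expect_identical(d1, d2)
  d3 <- generate_dataset(cell, replicate = 4, master_seed = 7)
  expect_false(identical(d1, d3))
  expect_equal(sum(d1$condition == 1), 300)
  expect_equal(sum(d1$condition == 2), 300)
  expect_gt(min(d1$rt), 0.3)
})

test_that("every manipulation speeds responses up in the manipulated condition", {
  cells <- enumerate_cells("main")
  for (i in which(cells$true_variant != "null")) {
    cell <- cells[i, ]
    pars <- cell_params(cell)
    n <- 1e5
    r1 <- simulate_lba_trials(pars$cond1, n_per_condition = n, seed = 100 + i)
    r2 <- simulate_lba_trials(pars$cond2, n_per_condition = n, seed = 200 + i)
    if (cell$arrangement == "balanced") {
      # offsetting effects: just require both conditions near each other
      expect_lt(abs(mean(r1$rt) - mean(r2$rt)), 0.15)
    } else {
      expect_gt(mean(r1$rt), mean(r2$rt))
    }
  }
})

test_that("calibrated effect sizes are ordered and near zero at baseline", {
  e0 <- calibrate_effect_size("v_c", 3, n_mc = 5e4, seed = 1)
  expect_lt(abs(e0), 0.02)
  ev <- effect_values()
  dv <- vapply(ev$v_c, function(v)
    calibrate_effect_size("v_c", v, n_mc = 5e4, seed = 2), numeric(1))
  db <- vapply(ev$b, function(b)
    calibrate_effect_size("b", b, n_mc = 5e4, seed = 3), numeric(1))
  expect_true(all(diff(dv) > 0))
  expect_true(all(diff(db) > 0))
  expect_true(all(c(dv, db) > 0))
  expect_error(calibrate_effect_size("v_c", 3.3, n_mc = 100))
})

test_that("the design manifest lists every dataset with its seed", {
  cells <- enumerate_cells("main", replicates = 2)
  man <- design_manifest(cells, master_seed = 5)
  expect_equal(nrow(man), 50)
  expect_equal(anyDuplicated(man$dataset_id), 0)
  # manifest seeds reproduce the generated datasets
  row <- man[17, ]
  cell <- cells[cells$cell_id == row$cell_id, ]
  d <- generate_dataset(cell, row$replicate, master_seed = 5)
  d2 <- simulate_lba_trials(cell_params(cell)$cond1, cell_params(cell)$cond2,
                            cell$trials_per_condition, seed = row$seed)
  expect_identical(d, d2)
})
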