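test_that("indirect effects multiply along carry-over paths", {
  dag <- dag_model(list(arr_b = "dep_nb", dep_b = "arr_b"))
  fits <- list(arr_b = manual_fit("arr_b", c(dep_nb = 0.35)),
               dep_b = manual_fit("dep_b", c(arr_b = 0.10)))
  et <- decompose_effects(dag, fits)
  row <- et[et$predictor == "dep_nb" & et$outcome == "dep_b", ]
  expect_equal(row$indirect, 0.035)
  expect_true(is.na(row$direct))
  expect_equal(row$total, 0.035)
  expect_equal(round_half_away(row$indirect, 2), 0.04)

  # two parallel routes sum: 0.24*0.17 + 0.24*0.10*0.38 = 0.0499
  dag2 <- dag_model(list(arr_b = "mig_dist", dep_b = "arr_b",
                         arr_nb = c("arr_b", "dep_b", "mig_dist")))
  fits2 <- list(
    arr_b = manual_fit("arr_b", c(mig_dist = 0.24)),
    dep_b = manual_fit("dep_b", c(arr_b = 0.10)),
    arr_nb = manual_fit("arr_nb", c(arr_b = 0.17, dep_b = 0.38,
                                    mig_dist = 0.14)))
  et2 <- decompose_effects(dag2, fits2)
  row2 <- et2[et2$predictor == "mig_dist" & et2$outcome == "arr_nb", ]
  expect_equal(row2$indirect, 0.24 * 0.17 + 0.24 * 0.10 * 0.38)
  expect_equal(row2$direct, 0.14)
  expect_equal(round_half_away(row2$indirect, 2), 0.05)

  # pair with no multi-edge path: indirect 0, total = direct
  row3 <- et2[et2$predictor == "dep_b" & et2$outcome == "arr_nb", ]
  expect_equal(row3$indirect, 0)
  expect_equal(row3$total, row3$direct)
})

test_that("non-significant edges are gated out of every path", {
  dag <- dag_model(list(arr_b = "dep_nb", dep_b = "arr_b"))
  fits <- list(
    # interval [-0.17, 0.26] includes zero: not significant
    arr_b = manual_fit("arr_b", c(dep_nb = 0.05), lower = -0.17,
                       upper = 0.26),
    dep_b = manual_fit("dep_b", c(arr_b = 0.10)))
  et <- decompose_effects(dag, fits)
  expect_true(is.na(et$direct[et$predictor == "dep_nb" &
                                et$outcome == "arr_b"]))
  expect_equal(et$indirect[et$predictor == "dep_nb" &
                             et$outcome == "dep_b"], 0)
  # ungated, the same decomposition keeps the weak edge
  et_raw <- decompose_effects(dag, fits, gate = FALSE)
  expect_equal(et_raw$indirect[et_raw$predictor == "dep_nb" &
                                 et_raw$outcome == "dep_b"], 0.005)
})

test_that("path enumeration equals brute force and the matrix identity", {
  for (seed in 1:20) {
    W <- random_weighted_dag(sample(4:8, 1), seed)
    dag <- dag_from_weights(W)
    fits <- fits_from_weights(W)
    et <- decompose_effects(dag, fits)
    Tm <- total_effects_matrix(dag, fits)
    for (r in seq_len(nrow(et))) {
      from <- et$predictor[r]
      to <- et$outcome[r]
      expect_equal(et$indirect[r], bf_indirect(W, from, to),
                   tolerance = 1e-12)
      expect_equal(et$total[r], Tm[from, to], tolerance = 1e-12)
    }
  }
})

test_that("rendering follows the table conventions", {
  expect_equal(round_half_away(0.035, 2), 0.04)
  expect_equal(round_half_away(-0.025, 2), -0.03)
  expect_equal(migsem:::format_signed(0.0499), "0.05")
  expect_equal(migsem:::format_signed(-0.003), "-0.00")

  dag <- dag_model(list(arr_b = c("dep_nb", "mig_dist"),
                        dep_b = "arr_b",
                        arr_nb = c("dep_b", "mig_dist")))
  fits <- list(
    arr_b = manual_fit("arr_b", c(dep_nb = 0.35, mig_dist = 0.24),
                       lower = c(0.3, -0.1), upper = c(0.4, 0.5)),
    dep_b = manual_fit("dep_b", c(arr_b = 0.10)),
    arr_nb = manual_fit("arr_nb", c(dep_b = 0.38, mig_dist = -0.003)))
  tab <- render_effect_table(decompose_effects(dag, fits))
  expect_equal(tab["arr_b direct", "mig_dist"], "-")     # gated out
  expect_equal(tab["arr_b direct", "dep_nb"], "0.35")
  expect_equal(tab["arr_nb direct", "mig_dist"], "-0.00")
  expect_equal(tab["dep_b indirect", "dep_nb"], "0.04")  # 0.035 rounded
})

test_that("Fisher's C and its closed forms", {
  expect_equal(fishers_c(c(1, 1, 1))$C, 0)
  expect_equal(fishers_c(c(1, 1, 1))$p_value, 1)
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * 2 * log(0.5), tolerance = 1e-10)
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4L)
  # k = 1, p = 0.05: C equals the chi-square(2) 95% quantile
  fc1 <- fishers_c(0.05)
  expect_equal(fc1$C, qchisq(0.95, 2), tolerance = 1e-10)
  expect_equal(fc1$C, 5.991, tolerance = 1e-3)
  expect_equal(fc1$p_value, 0.05, tolerance = 1e-10)
  expect_error(fishers_c(c(0.5, 0)), "decisive")
  expect_error(fishers_c(numeric(0)), "at least one")
  expect_error(fishers_c(1.2), "in \\(0, 1\\]")
})

test_that("basis sets follow the d-separation construction", {
  # chain A -> B -> C: single claim A _||_ C | B
  chain <- dag_model(list(B = "A", C = "B"))
  bs <- basis_set(chain)
  expect_length(bs, 1L)
  expect_equal(bs[[1]]$x, "A")
  expect_equal(bs[[1]]$y, "C")
  expect_equal(bs[[1]]$cond, "B")

  # saturated DAG: empty basis set
  sat <- dag_model(list(B = "A", C = c("A", "B")))
  expect_length(basis_set(sat), 0L)

  # default DAG: every claim pair is non-adjacent, and no
  # exogenous-exogenous pairs appear
  dag <- build_default_dag()
  bs2 <- basis_set(dag)
  expect_gt(length(bs2), 0L)
  for (cl in bs2) {
    expect_false(cl$x %in% dag$parents[[cl$y]])
    expect_false(cl$y %in% dag$parents[[cl$x]])
    expect_false(cl$x %in% c("body_mass", "flight_mode") &&
                   cl$y %in% c("body_mass", "flight_mode"))
  }
})

test_that("dsep_test combines claim p-values on data", {
  s <- small_derived()
  res <- dsep_test(s$derived, build_default_dag(), s$phylo)
  expect_equal(res$df, 2L * nrow(res$claims))
  expect_true(all(res$claims$p_value > 0 & res$claims$p_value <= 1))
  expect_equal(res$C, -2 * sum(log(res$claims$p_value)), tolerance = 1e-10)
})

test_that("non-converged fits block decomposition unless forced", {
  dag <- dag_model(list(arr_b = "dep_nb"))
  bad <- manual_fit("arr_b", c(dep_nb = 0.3))
  bad$diagnostics$converged <- FALSE
  expect_error(decompose_effects(dag, list(arr_b = bad)), "converge")
  expect_s3_class(decompose_effects(dag, list(arr_b = bad), force = TRUE),
                  "effect_table")
})
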