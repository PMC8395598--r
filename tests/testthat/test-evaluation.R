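test_that("D_pre matches closed forms", {
  a <- landmark_set(c("p1", "p2", "p3"), c(0, 1, 2), c(0, 1, 2), c(0, 1, 2))
  expect_equal(landmark_distance_pre(a, a)$d_pre, c(0, 0, 0))
  b <- landmark_set(a$id, a$x + 3, a$y + 4, a$z)
  expect_equal(landmark_distance_pre(a, b)$d_pre, c(5, 5, 5))
})

test_that("phantom D_pre lies in the expected range for a 15 mm truth", {
  case <- acc_clean_case()
  d <- landmark_distance_pre(case$landmarks_b, case$landmarks_f)$d_pre
  expect_gte(mean(d), 5)
  expect_lte(mean(d), 15)
})

identity_result <- function(case) {
  dims <- dim(case$baseline$voxels)
  list(velocity = NULL,
       forward = lungreg:::zero_field(dims, case$baseline$affine),
       backward = lungreg:::zero_field(dims, case$baseline$affine))
}

test_that("D_reg of the identity equals D_pre per landmark", {
  case <- small_case()
  pre <- landmark_distance_pre(case$landmarks_b, case$landmarks_f)
  reg <- landmark_distance_reg(case$landmarks_b, case$landmarks_f,
                               identity_result(case))
  expect_equal(reg$d_reg, pre$d_pre, tolerance = 1e-12)
})

test_that("D_reg of the ground-truth transform is at discretisation level", {
  case <- small_case()
  truth_result <- list(velocity = case$truth_velocity)
  reg <- landmark_distance_reg(case$landmarks_b, case$landmarks_f,
                               truth_result)
  expect_lt(mean(reg$d_reg), 1e-3)
  expect_lt(max(reg$d_reg), 1e-3)
})

test_that("the reported D_reg is the per-landmark mean of the two directions", {
  case <- small_case()
  res <- list(velocity = case$truth_velocity)
  reg <- landmark_distance_reg(case$landmarks_b, case$landmarks_f, res)
  expect_equal(reg$d_reg, (reg$d_fwd + reg$d_bwd) / 2, tolerance = 1e-9)
})

test_that("case summaries use the documented conventions", {
  d <- data.frame(id = c("a", "b", "c"), d_pre = c(1, 2, 3))
  s <- summarize_case(d, case_id = "t")
  expect_equal(s$mean_d_pre, 2)
  expect_equal(s$median_d_pre, 2)
  expect_equal(s$sd_d_pre, 1)  # sample (n-1) convention
  expect_equal(s$n_landmarks, 3)
  one <- summarize_case(data.frame(id = "a", d_pre = 4))
  expect_equal(one$sd_d_pre, 0)
  expect_error(summarize_case(d[0, ]), "empty")
})

test_that("summaries are invariant to landmark order", {
  set.seed(11)
  d <- data.frame(id = sprintf("l%02d", 1:20), d_pre = runif(20, 0, 30))
  s1 <- summarize_case(d)
  s2 <- summarize_case(d[sample(20), ])
  expect_equal(s1[, -1], s2[, -1])
})

test_that("transform quality flags folding fields and passes the identity", {
  dims <- c(12, 12, 12)
  id <- lungreg:::zero_field(dims, diag(c(2, 2, 2, 1)))
  q <- transform_quality(id)
  expect_equal(q$min, 1)
  expect_equal(q$max, 1)
  expect_false(q$implausible)
  # u(x) = -2x folds space: det(1 - 2) = -1
  fold <- id
  pos <- (seq_len(12) - 1) * 2
  fold$disp[, , , 1] <- -2 * array(pos, dims)
  qf <- transform_quality(fold)
  expect_true(qf$implausible)
  expect_lt(qf$min, 0)
  expect_gt(qf$frac_nonpos, 0)
})

test_that("evaluate_registration combines distances and quality", {
  case <- small_case()
  rep <- evaluate_registration(list(velocity = case$truth_velocity,
                                    forward = case$truth_forward,
                                    backward = case$truth_backward),
                               case$landmarks_b, case$landmarks_f,
                               case_id = "truth")
  expect_s3_class(rep, "evaluation_report")
  expect_lt(rep$summary$mean_d_reg, 1e-3)
  expect_gt(rep$summary$mean_d_pre, 1)
  expect_false(rep$jacobian$implausible)
  expect_equal(nrow(rep$per_landmark), nrow(case$landmarks_b))
})
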