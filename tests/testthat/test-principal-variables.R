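test_that("pve matches closed forms on orthogonal variables", {
  R <- diag(4)
  dimnames(R) <- list(paste0("v", 1:4), paste0("v", 1:4))
  expect_equal(pve(R, "v1"), 25)
  expect_equal(pve(R, c("v1", "v3")), 50)
  expect_equal(pve(R, paste0("v", 1:4)), 100)
  expect_equal(pve(R, character(0)), 0)
  expect_error(pve(R, "nope"), "unknown")
})

test_that("pve equals the average squared multiple correlation", {
  for (seed in c(31, 32, 33)) {
    p <- sample(4:8, 1)
    R <- random_correlation(p, seed)
    dimnames(R) <- list(paste0("v", 1:p), paste0("v", 1:p))
    subset_idx <- sort(sample(p, sample(1:3, 1)))
    expect_equal(pve(R, subset_idx), pve_formula_oracle(R, subset_idx),
                 tolerance = 1e-10)
    # simulation-based regression oracle at Monte-Carlo tolerance
    expect_equal(pve(R, subset_idx),
                 pve_regression_oracle(R, subset_idx),
                 tolerance = 0.02)
  }
})

test_that("pve is monotone in the subset", {
  withr::with_seed(34, {
    for (rep in 1:10) {
      p <- sample(4:8, 1)
      R <- random_correlation(p, sample(1000, 1))
      s <- sample(p, sample(1:(p - 1), 1))
      extra <- sample(setdiff(seq_len(p), s), 1)
      expect_gte(pve(R, c(s, extra)), pve(R, s) - 1e-9)
    }
  })
})

test_that("duplicated variables are not selected twice", {
  # v1 and v2 identical, v3 independent: best 2 blocks are {v1 or v2} + v3
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.999
  dimnames(R) <- list(paste0("v", 1:3), paste0("v", 1:3))
  blocks <- tibble::tibble(block_id = paste0("v", 1:3),
                           members = as.list(paste0("v", 1:3)))
  sel <- select_battery(R, blocks, k = 2)
  expect_true("v3" %in% sel$block_id)
  expect_equal(length(intersect(sel$block_id, c("v1", "v2"))), 1)
})

test_that("greedy selection attains near-exhaustive cumulative PVE", {
  for (seed in c(35, 36, 37)) {
    p <- 8
    R <- random_correlation(p, seed)
    dimnames(R) <- list(paste0("v", 1:p), paste0("v", 1:p))
    blocks <- tibble::tibble(block_id = paste0("v", 1:p),
                             members = as.list(paste0("v", 1:p)))
    for (k in 1:3) {
      sel <- select_battery(R, blocks, k = k)
      greedy_pve <- attr(sel, "total_pve")
      combos <- utils::combn(p, k)
      all_pve <- apply(combos, 2, function(ix) pve(R, ix))
      top3 <- sort(all_pve, decreasing = TRUE)[min(3, length(all_pve))]
      expect_gte(greedy_pve, top3 - 1e-9)
    }
  }
})

test_that("orthogonal equal blocks give additive cumulative PVE", {
  R <- diag(6)
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  blocks <- tibble::tibble(
    block_id = c("b1", "b2", "b3"),
    members = list(c("v1", "v2"), c("v3", "v4"), c("v5", "v6")))
  sel <- select_battery(R, blocks, k = 2)
  expect_equal(sel$cumulative_pve, c(100 * 2 / 6, 100 * 4 / 6))
  expect_error(select_battery(R, blocks, k = 4), "exceeds")
})

test_that("significance breaks PVE ties in favour of significant blocks", {
  R <- diag(4)
  dimnames(R) <- list(paste0("v", 1:4), paste0("v", 1:4))
  blocks <- tibble::tibble(block_id = paste0("v", 1:4),
                           members = as.list(paste0("v", 1:4)))
  sig <- tibble::tibble(unit_id = "v3", p_adjusted = 0.001)
  sel <- select_battery(R, blocks, k = 1, significance = sig)
  expect_equal(sel$block_id, "v3")
  # determinism: repeated calls agree
  expect_identical(select_battery(R, blocks, k = 3, significance = sig),
                   select_battery(R, blocks, k = 3, significance = sig))
})

test_that("pve jointly is the leave-one-out increment in the final set", {
  R <- random_correlation(6, 38)
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  blocks <- tibble::tibble(block_id = paste0("v", 1:6),
                           members = as.list(paste0("v", 1:6)))
  sel <- select_battery(R, blocks, k = 3)
  total <- attr(sel, "total_pve")
  for (i in seq_len(3)) {
    others <- unlist(sel$members[-i])
    expect_equal(sel$pve_joint[i], total - pve(R, others), tolerance = 1e-10)
  }
  expect_false(is.unsorted(sel$cumulative_pve))
})

test_that("the encoded reference battery has 15 groups and 21 measures", {
  ref <- reference_battery()
  expect_equal(nrow(ref), 15)
  expect_equal(length(unlist(ref$members)), 21)
  expect_true(all(unlist(ref$members) %in%
                    correlation_variables(xdp_catalogue())$unit_id))
  expect_true(all(ref$pve_alone >= 0 & ref$pve_alone <= 100))
})

test_that("battery comparison counts agreement correctly", {
  ref <- reference_battery()
  sel_same <- structure(
    tibble::tibble(block_id = ref$block_id, members = ref$members,
                   pve_alone = ref$pve_alone, pve_joint = ref$pve_joint,
                   cumulative_pve = cumsum(ref$pve_joint)),
    class = c("xdp_battery", class(tibble::tibble())))
  expect_equal(report_battery(sel_same, ref)$agreement, 1)
  sel_disjoint <- sel_same
  sel_disjoint$members <- as.list(paste0("other", seq_len(15)))
  expect_equal(report_battery(sel_disjoint, ref)$agreement, 0)
})

test_that("default blocks pair bilateral measures and DDK count/duration", {
  blocks <- default_battery_blocks()
  pair_blocks <- blocks$members[lengths(blocks$members) == 2]
  expect_true(list(c("bfm_mov_rarm", "bfm_mov_larm")) %in% pair_blocks)
  expect_true(list(c("ddk_ka_count", "ddk_ka_secs")) %in% pair_blocks)
  members <- unlist(blocks$members)
  expect_false(anyDuplicated(members) > 0)
  expect_false("repeat_size" %in% members)
})
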