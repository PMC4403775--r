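test_that("signed fold-change convention matches the published dialect", {
  expect_equal(signed_fold_change(0.302), -1 / 0.302)   # prints as -3.31...
  expect_lt(abs(signed_fold_change(0.302) - (-3.3112583)), 1e-6)
  expect_equal(signed_fold_change(1), 1)
  expect_equal(signed_fold_change(8.463081), 8.463081)
  expect_error(signed_fold_change(c(1, -2)), "positive")

  # sign rule and monotonicity
  withr::with_seed(61, r <- exp(rnorm(100)))
  expect_equal(signed_fold_change(1 / r[r > 1]), -signed_fold_change(r[r > 1]))
  expect_true(all(abs(signed_fold_change(r)) >= 1))
  rs <- sort(r)
  expect_true(all(diff(signed_fold_change(rs)) >= 0))
})

test_that("fold_change equals the brute-force mean-ratio computation", {
  sim <- simulate_predation(small_scenario(seed = 62))
  fc <- fold_change(sim$matrix)
  v <- sim$matrix$values
  des <- sim$matrix$design
  ctrl_mean <- rowMeans(v[, des$sample_id[des$group == "Cont"]])
  for (tr in c("Drago", "MinusSalam")) {
    tr_mean <- rowMeans(v[, des$sample_id[des$group == tr]])
    r <- tr_mean / ctrl_mean
    expected <- ifelse(r >= 1, r, -1 / r)
    got <- fc$fold_change[fc$treatment == tr]
    expect_equal(got, unname(expected), tolerance = 1e-10)
    expect_identical(fc$direction[fc$treatment == tr],
                     unname(ifelse(r >= 1, "up", "down")))
  }
  # equal means give +1 exactly
  v2 <- matrix(5, 3, 15, dimnames = list(paste0("p", 1:3),
                                         full_design()$sample_id))
  em2 <- join_design(expression_matrix(v2), full_design())
  expect_true(all(fold_change(em2)$fold_change == 1))
  # log-scale input is refused
  expect_error(fold_change(baseline_to_median(sim$matrix)), "linear")
})

test_that("volcano screen applies a strict threshold and is monotone", {
  des <- full_design()
  v <- matrix(10, 4, 15, dimnames = list(paste0("p", 1:4), des$sample_id))
  v["p1", des$group == "Drago"] <- 10 * 8.46   # clearly in
  v["p2", des$group == "Drago"] <- 10 * 4.99   # below threshold
  v["p3", des$group == "Drago"] <- 10 * 5      # exactly at: excluded
  v["p4", des$group == "Salam"] <- 10 / 7      # down-regulated, in Salam set
  em <- join_design(expression_matrix(v), des)
  fc <- fold_change(em)
  sets <- volcano_screen(fc, 5)$sets
  expect_identical(sets$Drago, "p1")
  expect_identical(sets$Salam, "p4")
  expect_identical(sets$MinusDrago, character(0))

  # monotone: sets shrink as the threshold rises
  sim <- simulate_predation(small_scenario(seed = 63))
  fcs <- fold_change(sim$matrix)
  s3 <- volcano_screen(fcs, 3)$sets
  s6 <- volcano_screen(fcs, 6)$sets
  for (tr in names(s6)) expect_true(all(s6[[tr]] %in% s3[[tr]]))
  expect_error(volcano_screen(fcs, 0.5), ">= 1")
})

test_that("planted per-treatment set counts are recovered exactly", {
  tpl <- list(
    drago_only = list(label = "dragonfly_specific", count = 25,
                      effects = c(Cont = 1, Drago = 8, Salam = 1,
                                  MinusDrago = 1, MinusSalam = 1)),
    salam_only = list(label = "salamander_specific", count = 25,
                      effects = c(Cont = 1, Drago = 1, Salam = 8,
                                  MinusDrago = 1, MinusSalam = 1))
  )
  sim <- simulate_predation(small_scenario(seed = 64, templates = tpl))
  sets <- volcano_screen(fold_change(sim$matrix), 5)$sets
  expect_length(sets$Drago, 25)
  expect_length(sets$Salam, 25)
})

test_that("revert-to-control rule labels the worked profiles correctly", {
  fc_tbl <- tibble::tibble(
    probe_id = rep(c("pA", "pB", "pC", "pD"), each = 4),
    treatment = rep(c("Drago", "MinusDrago", "Salam", "MinusSalam"), 4),
    fold_change = c(7, 1.2, 1.1, 1.0,      # dragonfly-specific
                    6, 3.5, 6, 1.1,        # both sets -> common
                    6, 4.9, 1.2, 1.1,      # responsive but not reverting
                    1.3, 1.0, 1.1, 1.0)    # quiet
  )
  screened <- list(sets = list(Drago = c("pA", "pB", "pC"), Salam = "pB",
                               MinusDrago = character(0),
                               MinusSalam = character(0)),
                   threshold = 5)
  calls <- classify_specificity(fc_tbl, screened, revert_band = 2)
  got <- setNames(calls$label, calls$probe_id)
  expect_identical(unname(got[c("pA", "pB", "pC", "pD")]),
                   c("dragonfly_specific", "common",
                     "responsive_nonreverting", "not_responsive"))
  expect_error(classify_specificity(fc_tbl, screened, revert_band = 0.5),
               ">= 1")
})

test_that("raising the revert band only moves probes toward specific labels", {
  sim <- simulate_predation(small_scenario(seed = 65))
  fc <- fold_change(sim$matrix)
  screened <- volcano_screen(fc, 5)
  rank_of <- function(lbl) match(lbl, c("not_responsive",
                                        "responsive_nonreverting",
                                        "dragonfly_specific",
                                        "salamander_specific", "common"))
  bands <- c(1, 1.5, 2, 4, 8)
  prev <- NULL
  for (b in bands) {
    cur <- classify_specificity(fc, screened, revert_band = b)
    specific <- cur$label %in% c("dragonfly_specific", "salamander_specific")
    if (!is.null(prev)) {
      was_specific <- prev$label %in% c("dragonfly_specific",
                                        "salamander_specific")
      expect_true(all(specific[was_specific]))
    }
    # labels always partition the probes
    expect_equal(nrow(cur), length(unique(fc$probe_id)))
    prev <- cur
  }
})

test_that("known-gene flagging follows the annotation placeholder rule", {
  ann <- tibble::tibble(
    probe_id = paste0("p", 1:6),
    gene_symbol = c("elavl1-a", "LOC100495516", "EST", NA, "", "MGC130975"),
    gene_title = c("ELAV-like 1", "laminin-like", NA, NA, NA,
                   "Hypothetical protein MGC130975"),
    accession = NA_character_
  )
  flagged <- flag_known_genes(ann)
  expect_identical(flagged$known, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})
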