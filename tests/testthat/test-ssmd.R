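test_that("summarize_group computes mean, sample SD and n", {
  g <- summarize_group(c(10, 12, 14))
  expect_equal(g$mean, 12)
  expect_equal(g$sd, 2)
  expect_equal(g$n, 3)

  one <- summarize_group(7)
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sd))
  expect_equal(one$n, 1)

  expect_equal(summarize_group(c(5, 5, 5))$sd, 0)
  expect_error(summarize_group(numeric()), "no values")
})

test_that("ssmd matches direct arithmetic and handles degenerate variance", {
  g1 <- summarize_group(c(10, 12, 14))  # mean 12, sd 2
  g2 <- summarize_group(c(6, 8, 10))    # mean 8, sd 2
  expect_equal(ssmd(g1, g2), 4 / sqrt(8), tolerance = 1e-12)

  expect_equal(ssmd(g1, g1), 0)
  expect_equal(ssmd(g1, g2), -ssmd(g2, g1))

  flat1 <- summarize_group(c(5, 5))
  flat2 <- summarize_group(c(3, 3))
  expect_identical(ssmd(flat1, flat2), Inf)
  expect_identical(ssmd(flat2, flat1), -Inf)
  expect_identical(ssmd(flat1, flat1), 0)

  expect_error(ssmd(summarize_group(7), g2), "n >= 2")
})

test_that("ssmd equals an independent oracle on 1000 random group pairs and is invariant", {
  set.seed(101)
  for (i in 1:1000) {
    n1 <- sample(2:8, 1); n2 <- sample(2:40, 1)
    x1 <- rnorm(n1, sd = runif(1, 0.5, 3)) + runif(1, -5, 5)
    x2 <- rnorm(n2, sd = runif(1, 0.5, 3)) + runif(1, -5, 5)
    b <- ssmd(summarize_group(x1), summarize_group(x2))
    expect_equal(b, ssmd_oracle(x1, x2), tolerance = 1e-12)
    # antisymmetry
    expect_equal(ssmd(summarize_group(x2), summarize_group(x1)), -b,
                 tolerance = 1e-12)
  }
  # scale and location invariance
  set.seed(102)
  x1 <- rnorm(5, 10); x2 <- rnorm(8, 9)
  b <- ssmd(summarize_group(x1), summarize_group(x2))
  for (c in c(0.01, 1, 250)) {
    expect_equal(ssmd(summarize_group(c * x1), summarize_group(c * x2)), b,
                 tolerance = 1e-9)
  }
  expect_equal(ssmd(summarize_group(x1 + 17), summarize_group(x2 + 17)), b,
               tolerance = 1e-9)
})

test_that("score_plate scores against on-plate NT wells and flags gaps", {
  design <- small_design(seed = 33)
  meas <- simulate_screen(design, NULL, noise_free(), seed = 1)
  plate0 <- meas[meas$condition == "0mM", ]

  sec <- score_plate(plate0, design, "secretion")
  # null genes on a noise-free plate score exactly 0
  expect_true(all(sec$beta[sec$role == "candidate"] == 0))
  expect_equal(sec$n_nt[1], 4)

  # plate-effect invariance: scaling the whole plate leaves beta unchanged
  noisy <- simulate_screen(design, NULL, noise_config(plate_sigma = 0), seed = 2)
  p1 <- noisy[noisy$condition == "0mM", ]
  p2 <- p1
  p2$signal <- p1$signal * 3.7
  expect_equal(score_plate(p2, design, "secretion")$beta,
               score_plate(p1, design, "secretion")$beta, tolerance = 1e-12)

  # gene with all wells missing is flagged, not scored
  drop_wells <- design$layout$well[design$layout$gene_symbol %in% "G002"]
  p3 <- p1[!p1$well %in% drop_wells, ]
  s3 <- score_plate(p3, design, "secretion")
  expect_false("G002" %in% s3$gene)
  p4 <- p1[!p1$well %in% drop_wells[-1], ]  # one well left
  s4 <- score_plate(p4, design, "secretion")
  row <- s4[s4$gene == "G002", ]
  expect_true(is.na(row$beta))
  expect_match(row$flags, "insufficient_replicates")

  # < 2 NT wells -> plate unscoreable
  nt_wells <- design$layout$well[design$layout$role == "nt"]
  p5 <- p1[!p1$well %in% nt_wells[-1], ]
  expect_error(score_plate(p5, design, "secretion"), "NT wells")
})

test_that("call_hits applies inclusive cut-offs and the viability filter", {
  mk <- function(beta_sec, beta_cell, gene = "G1", condition = "20mM") {
    data.frame(gene = gene, role = "candidate", condition = condition,
               set_id = 1, beta_secretion = beta_sec,
               beta_cellnumber = beta_cell, mean_candidate = 0,
               sd_candidate = 1, n_candidate = 3, mean_nt = 0, sd_nt = 1,
               n_nt = 33, flags = "", stringsAsFactors = FALSE)
  }
  # boundary: beta = -1.5 exactly is a down hit (inclusive)
  h <- call_hits(mk(-1.5, 0))
  expect_equal(h$direction_20mM, "down")
  expect_true(h$hit)
  expect_false(h$viability_excluded)

  # down secretion AND down cell number -> excluded, not a hit
  h2 <- call_hits(mk(-2, -2))
  expect_equal(h2$direction_20mM, "none")
  expect_false(h2$hit)
  expect_true(h2$viability_excluded)

  # below threshold is not a hit
  h3 <- call_hits(mk(1.49, 0))
  expect_false(h3$hit)
  # at/above threshold is an up hit; cell-number drop never removes ups
  h4 <- call_hits(mk(1.5, -3))
  expect_equal(h4$direction_20mM, "up")
  expect_true(h4$hit)
  expect_false(h4$viability_excluded)

  # degenerate signed infinity counts as a hit by sign
  h5 <- call_hits(mk(Inf, 0))
  expect_equal(h5$direction_20mM, "up")

  # multi-condition: up in one condition suffices ("at least one")
  s <- rbind(mk(0.2, 0, condition = "0mM"), mk(1.7, 0, condition = "20mM"),
             mk(-0.3, 0, condition = "20mM+IBMX"))
  h6 <- call_hits(s)
  expect_equal(h6$conditions_hit, "20mM")
  expect_true(h6$hit)
})

test_that("integrate_conditions builds Venn regions and union counts", {
  calls <- data.frame(
    gene = c("A", "B", "C", "D"),
    direction_0mM = c("up", "none", "down", "none"),
    direction_20mM = c("up", "up", "down", "none"),
    direction_20mMIBMX = c("none", "none", "down", "none"),
    conditions_hit = c("0mM,20mM", "20mM", "0mM,20mM,20mM+IBMX", ""),
    viability_excluded = FALSE, hit = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  attr(calls, "conditions") <- c("0mM", "20mM", "20mM+IBMX")
  v <- integrate_conditions(calls)
  expect_equal(v$union$up, 2)
  expect_equal(v$union$down, 1)
  expect_equal(v$union$total, 3)
  expect_equal(v$venn$up[["0mM&20mM"]], 1)
  expect_equal(v$venn$up[["20mM"]], 1)
  expect_equal(v$venn$down[["0mM&20mM&20mM+IBMX"]], 1)
  pc <- v$per_condition
  expect_equal(pc$count[pc$condition == "20mM" & pc$direction == "up"], 2)

  # empty calls -> all-zero summary
  v0 <- integrate_conditions(calls[calls$hit & FALSE, ])
  expect_equal(v0$union$total, 0)
  expect_length(v0$venn$up, 0)
})

test_that("fold_induction recovers condition folds", {
  design <- small_design(seed = 14)
  meas <- simulate_screen(design, NULL, noise_free(), seed = 1)
  fi <- fold_induction(meas, design)
  expect_equal(fi$fold[fi$condition == "20mM"], 2.5)
  expect_equal(fi$fold[fi$condition == "20mM+IBMX"], 5.5)
  expect_equal(fi$fold[fi$condition == "0mM"], 1)

  # identical signals across conditions -> fold 1
  flat <- meas
  flat$signal <- 500
  expect_true(all(fold_induction(flat, design)$fold == 1))

  # missing basal plate -> error
  nobase <- meas[meas$condition != "0mM", ]
  expect_error(fold_induction(nobase, design), "basal")
})

test_that("qc_controls evaluates canonical control expectations", {
  lib <- synthetic_library(75)
  design <- assign_wells(lib, replicates = 3, capacity = 75, seed = 8)
  eff <- plant_effects(sprintf("GENE%04d", 1:75), n_up = 0, n_down = 0, seed = 1)
  meas <- simulate_screen(design, eff, noise_config(), seed = 3)
  scores <- score_screen(meas, design)
  qc <- qc_controls(scores, meas, design)
  expect_true(qc$all_pass)

  # all-null controls -> every check fails
  meas0 <- simulate_screen(design, NULL, noise_config(), seed = 3)
  qc0 <- qc_controls(score_screen(meas0, design), meas0, design)
  expect_false(any(qc0$controls$pass))

  # missing control wells -> marked missing, no exception
  hn_wells <- design$layout$well[design$layout$gene_symbol %in% "HNF4A"]
  meas_miss <- meas[!(meas$well %in% hn_wells & meas$condition == "20mM"), ]
  qc_m <- qc_controls(score_screen(meas_miss, design), meas_miss, design)
  row <- qc_m$controls[qc_m$controls$gene == "HNF4A" &
                         qc_m$controls$condition == "20mM", ]
  expect_true(all(row$missing))
})
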