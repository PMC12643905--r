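# confusion-matrix metrics on constructed archives with known truth

# build a fake archive: truth matrices plus per-rep anchor sets and effect
# tables, exercising the metric definitions without any model fitting
fake_archive <- function(B, Gamma, reps) {
  structure(list(
    condition = NULL,
    truth = list(B = B, Gamma = Gamma,
                 anchor = rowSums(B != 0) + rowSums(Gamma != 0) == 0),
    reps = lapply(reps, function(r) {
      list(ok = TRUE,
           anchor_report = list(anchors = r$anchors,
                                dif_items = setdiff(seq_len(nrow(B)),
                                                    r$anchors)),
           final_report = list(effects = r$effects))
    })), class = "sim_archive")
}

effects_for <- function(dif_items, p, flag = function(i, q, ty) FALSE,
                        est = function(i, q, ty) 0) {
  g <- expand.grid(item = dif_items, covariate = seq_len(p),
                   type = c("uniform", "nonuniform"),
                   stringsAsFactors = FALSE)
  if (!nrow(g))
    return(data.frame(item = integer(0), covariate = integer(0),
                      type = character(0), estimate = numeric(0),
                      se = numeric(0), p = numeric(0),
                      flagged = logical(0)))
  g$estimate <- mapply(est, g$item, g$covariate, g$type)
  g$se <- 0.1
  g$p <- ifelse(mapply(flag, g$item, g$covariate, g$type), 0.01, 0.5)
  g$flagged <- g$p < 0.05
  g
}

# world: J = 5, p = 2; items 1-2 DIF (item 1 uniform on x1 + nonuniform on
# x2; item 2 uniform on x2), items 3-5 anchors
B0 <- matrix(0, 5, 2); B0[1, 1] <- 0.5; B0[2, 2] <- 0.5
G0 <- matrix(0, 5, 2); G0[1, 2] <- 0.3

test_that("perfect detection scores perfectly", {
  eff <- effects_for(1:2, 2,
                     flag = function(i, q, ty)
                       (i == 1 && q == 1 && ty == "uniform") ||
                       (i == 1 && q == 2 && ty == "nonuniform") ||
                       (i == 2 && q == 2 && ty == "uniform"),
                     est = function(i, q, ty)
                       if (ty == "uniform") B0[i, q] else G0[i, q])
  a <- fake_archive(B0, G0, list(list(anchors = 3:5, effects = eff),
                                 list(anchors = 3:5, effects = eff)))
  expect_equal(hit_rate(a), 1)
  expect_equal(type2_error(a, "uniform"), 0)
  expect_equal(type2_error(a, "nonuniform"), 0)
  expect_equal(type1_error(a), 0)
  expect_equal(power_rate(a, "uniform"), 1)
  expect_equal(power_rate(a, "nonuniform"), 1)
  expect_equal(relative_bias(a, "uniform")$bias, 0)
  expect_equal(relative_bias(a, "nonuniform")$bias, 0)
})

test_that("partial anchor recovery and misses are counted as stated", {
  # rep 1: item 2 wrongly anchored (type II for uniform), anchor 5 wrongly
  # flagged as DIF with one significant spurious effect
  eff1 <- effects_for(c(1, 5), 2,
                      flag = function(i, q, ty)
                        (i == 1 && q == 1 && ty == "uniform") ||
                        (i == 5 && q == 1 && ty == "uniform"))
  a <- fake_archive(B0, G0,
                    list(list(anchors = c(2, 3, 4), effects = eff1)))
  expect_equal(hit_rate(a), 2 / 3)           # anchors 3,4 of 3,4,5 recovered
  expect_equal(type2_error(a, "uniform"), 1 / 2)  # item 2 of items 1,2
  expect_equal(type2_error(a, "nonuniform"), 0)   # item 1 not anchored
  # 5 x 2 x 2 = 20 effects, 3 true -> 17 DIF-free; 1 false flag
  expect_equal(type1_error(a), 1 / 17)
  # item 2 anchored: its true uniform effect is a miss; item 1 uniform hit
  expect_equal(power_rate(a, "uniform"), 1 / 2)
  expect_equal(power_rate(a, "nonuniform"), 0)  # tested but not significant
})

test_that("relative bias averages estimates over estimated reps only", {
  mk <- function(est1, items) list(
    anchors = setdiff(1:5, items),
    effects = effects_for(items, 2,
                          est = function(i, q, ty)
                            if (i == 1 && q == 1 && ty == "uniform") est1
                            else 0))
  a <- fake_archive(B0, G0, list(mk(0.6, 1:2), mk(0.5, 1:2),
                                 mk(999, 2)))     # rep 3: item 1 anchored
  rb <- relative_bias(a, "uniform")
  pe <- rb$per_effect
  i11 <- pe$item == 1 & pe$covariate == 1
  expect_equal(pe$n_est[i11], 2)                  # third rep not estimated
  expect_equal(pe$mean_est[i11], 0.55)
  expect_equal(pe$bias[i11], abs(0.55 - 0.5) / 0.5)
  expect_equal(pe$bias[i11], 0.1)
  # item 2's uniform effect estimated (as 0) in all three reps
  expect_equal(pe$n_est[pe$item == 2], 3)
})

test_that("metrics are invariant to item relabeling", {
  eff <- effects_for(1:2, 2,
                     flag = function(i, q, ty) i == 1 && ty == "uniform")
  a <- fake_archive(B0, G0, list(list(anchors = 3:5, effects = eff)))
  # relabel items with a permutation
  perm <- c(4, 1, 5, 2, 3)  # new id of old item j = perm[j]
  Bp <- B0[order(perm), ]; Gp <- G0[order(perm), ]
  effp <- eff; effp$item <- perm[eff$item]
  ap <- fake_archive(Bp, Gp,
                     list(list(anchors = perm[3:5], effects = effp)))
  for (f in list(hit_rate, type1_error))
    expect_equal(f(a), f(ap))
  for (ty in c("uniform", "nonuniform")) {
    expect_equal(type2_error(a, ty), type2_error(ap, ty))
    expect_equal(power_rate(a, ty), power_rate(ap, ty))
    expect_equal(relative_bias(a, ty)$bias, relative_bias(ap, ty)$bias)
  }
})

test_that("type I matches a brute-force count over all effects", {
  set.seed(99)
  J <- 6; p <- 3
  B <- matrix(0, J, p); B[cbind(1:2, c(3, 3))] <- 0.5
  G <- matrix(0, J, p); G[1, 1] <- 0.3
  for (r in 1:10) {
    anchors <- sort(sample(1:J, sample(2:4, 1)))
    dif <- setdiff(1:J, anchors)
    eff <- effects_for(dif, p, flag = function(i, q, ty) runif(1) < 0.3)
    a <- fake_archive(B, G, list(list(anchors = anchors, effects = eff)))
    # brute force: loop every item x covariate x type
    num <- 0; den <- 0
    for (j in 1:J) for (q in 1:p) for (ty in c("uniform", "nonuniform")) {
      tr <- if (ty == "uniform") B[j, q] else G[j, q]
      if (tr != 0) next
      den <- den + 1
      row <- eff[eff$item == j & eff$covariate == q & eff$type == ty, ]
      if (nrow(row) == 1 && row$flagged) num <- num + 1
    }
    expect_equal(type1_error(a), num / den)
  }
})

test_that("degenerate worlds return the stated values", {
  # all items anchors in truth and in every report: nothing can be flagged
  Bz <- matrix(0, 4, 2); Gz <- matrix(0, 4, 2)
  a <- fake_archive(Bz, Gz, list(list(
    anchors = 1:4,
    effects = effects_for(integer(0), 2))))
  expect_equal(hit_rate(a), 1)
  expect_equal(type1_error(a), 0)
  expect_true(is.na(type2_error(a, "uniform")))
  expect_true(is.na(power_rate(a, "uniform")))
  expect_true(is.na(relative_bias(a, "uniform")$bias))
})
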