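test_that("the minimum density implements the 2 ln N degree floor", {
  d <- minimum_density(148)
  expect_equal(as.numeric(d), 2 * log(148) / 147)
  expect_identical(attr(d, "percent_label"), "6%")  # truncated, not rounded
  # continuous check: at N = e^2 the average-degree floor 2 ln N equals 4
  expect_equal(as.numeric(minimum_density(exp(2))), 4 / (exp(2) - 1))
  expect_error(minimum_density(2), ">= 3")
})

test_that("density thresholding keeps exactly the strongest edges", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.5; w[1, 4] <- 0.2
  w[2, 3] <- 0.4; w[2, 4] <- 0.3; w[3, 4] <- 0.8
  w <- w + t(w)
  g <- suppressWarnings(threshold_by_density(w, 0.5))
  expect_equal(g$n_kept, 3L)
  expect_equal(g$edges[, c("i", "j")],
               data.frame(i = c(1, 3, 1), j = c(2, 4, 3)))
  gall <- threshold_by_density(w, 1)
  expect_equal(gall$n_kept, 6L)
  expect_equal(gall$total_weight, sum(w) / 2)
  # ties break lexicographically on (i, j)
  wt <- matrix(1, 4, 4); diag(wt) <- 0
  gt <- suppressWarnings(threshold_by_density(wt, 2 / 6))
  expect_equal(gt$edges[, c("i", "j")], data.frame(i = c(1, 1), j = c(2, 3)))
  expect_error(threshold_by_density(w, 0), "\\(0, 1\\]")
  expect_warning(threshold_by_density(w, 0.2), "below the minimum density")
})

test_that("kept-edge counts match the closed form across random densities", {
  w <- random_wpli_matrix(148, seed = 61)
  set.seed(62)
  for (d in runif(20, 0.01, 1)) {
    g <- suppressWarnings(threshold_by_density(w, d))
    expect_equal(g$n_kept, floor(d * 148 * 147 / 2 + 0.5))
    expect_equal(nrow(g$edges), g$n_kept)
    # every kept weight >= every discarded weight
    expect_gte(min(g$edges$w), max(w[upper.tri(w)][!paste(row(w)[upper.tri(w)], col(w)[upper.tri(w)]) %in%
                                                     paste(g$edges$i, g$edges$j)], -Inf))
  }
})

test_that("area metrics reproduce the worked toy example", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[3, 4] <- 0.8; w[1, 3] <- 0.5; w[2, 4] <- 0.3
  w <- w + t(w)
  part <- data.frame(roi_id = 1:4, roi_name = letters[1:4],
                     area = c("A", "A", "B", "B"))
  m <- area_metrics(suppressWarnings(threshold_by_density(w, 4 / 6)), part)
  expect_equal(unname(m$S_k), c(0.9, 0.8))
  expect_equal(m$S_all, 1.7)
  expect_equal(unname(m$L_k), c(0.8, 0.8))  # each inter edge counts twice
  expect_equal(m$L_all, 1.6)
  expect_equal(m$Ratio, 1.6 / 1.7)
  # no inter-area edges -> Ratio 0
  w2 <- matrix(0, 4, 4); w2[1, 2] <- 0.9; w2[3, 4] <- 0.8; w2 <- w2 + t(w2)
  m2 <- suppressWarnings(area_metrics(threshold_by_density(w2, 2 / 6), part))
  expect_equal(m2$L_all, 0)
  expect_equal(m2$Ratio, 0)
  # only inter-area edges -> S_all 0, Ratio NA with a warning
  w3 <- matrix(0, 4, 4); w3[1, 3] <- 0.9; w3[2, 4] <- 0.8; w3 <- w3 + t(w3)
  g3 <- suppressWarnings(threshold_by_density(w3, 2 / 6))
  expect_warning(m3 <- area_metrics(g3, part), "S_all is 0")
  expect_true(is.na(m3$Ratio))
})

test_that("metrics match the exhaustive classification oracle on small graphs", {
  part6 <- data.frame(roi_id = 1:6, roi_name = letters[1:6],
                      area = c("A", "A", "B", "B", "C", "C"))
  set.seed(63)
  for (rep in 1:8) {
    w <- random_wpli_matrix(6, seed = 63 + rep)
    d <- sample(c(0.3, 0.5, 0.8, 1), 1)
    m <- suppressWarnings(area_metrics(threshold_by_density(w, d), part6))
    o <- metrics_oracle(w, d, part6)
    expect_equal(m$S_k, o$S_k)
    expect_equal(m$L_k, o$L_k)
    expect_equal(m$S_all, o$S_all)
    expect_equal(m$L_all, o$L_all)
  }
})

test_that("conservation S_all + L_all/2 = kept weight holds at every density", {
  part <- make_test_partition(2L)  # 28 ROIs
  w <- random_wpli_matrix(28, seed = 64)
  sw <- suppressWarnings(density_sweep(w, part, seq(0.06, 0.9, by = 0.02)))
  for (r in seq_len(nrow(sw$per_density))) {
    g <- suppressWarnings(threshold_by_density(w, sw$per_density$density[r]))
    expect_equal(sw$per_density$S_all[r] + sw$per_density$L_all[r] / 2,
                 g$total_weight, tolerance = 1e-9)
  }
  # at density 1, conservation against the full matrix total
  m1 <- area_metrics(threshold_by_density(w, 1), part)
  expect_equal(m1$S_all + m1$L_all / 2, sum(w) / 2, tolerance = 1e-9)
})

test_that("L_all and S_all are non-decreasing in density and sweeps are consistent", {
  part <- make_test_partition(2L)
  w <- random_wpli_matrix(28, seed = 65)
  sw <- suppressWarnings(density_sweep(w, part, seq(0.06, 0.9, by = 0.01)))
  expect_true(all(diff(sw$per_density$L_all) >= 0))
  expect_true(all(diff(sw$per_density$S_all) >= 0))
  # sweep rows equal direct single-density computations
  for (d in c(0.1, 0.5, 0.9)) {
    m <- suppressWarnings(area_metrics(threshold_by_density(w, d), part))
    r <- sw$per_density[abs(sw$per_density$density - d) < 1e-9, ]
    expect_equal(r$L_all, m$L_all)
    expect_equal(r$S_all, m$S_all)
    expect_equal(unname(unlist(r[paste0("L_", names(m$L_k))])), unname(m$L_k))
  }
  # a one-point grid's summary is that point
  sw1 <- density_sweep(w, part, 0.5)
  expect_equal(sw1$summary$Ratio, sw1$per_density$Ratio[1])
})

test_that("raising an inter-area weight raises the Ratio; intra lowers it", {
  part <- make_test_partition(2L)
  w <- random_wpli_matrix(28, seed = 66)
  g0 <- threshold_by_density(w, 0.5)
  base <- suppressWarnings(area_metrics(g0, part)$Ratio)
  a_of <- part$area[match(1:28, part$roi_id)]
  kept_inter <- g0$edges[a_of[g0$edges$i] != a_of[g0$edges$j], ][1, ]
  kept_intra <- g0$edges[a_of[g0$edges$i] == a_of[g0$edges$j], ][1, ]
  w_up <- w
  w_up[kept_inter$i, kept_inter$j] <- w_up[kept_inter$j, kept_inter$i] <-
    min(kept_inter$w + 0.2, 1)
  expect_gt(area_metrics(threshold_by_density(w_up, 0.5), part)$Ratio, base)
  w_dn <- w
  w_dn[kept_intra$i, kept_intra$j] <- w_dn[kept_intra$j, kept_intra$i] <-
    min(kept_intra$w + 0.2, 1)
  expect_lt(area_metrics(threshold_by_density(w_dn, 0.5), part)$Ratio, base)
})

test_that("the shipped atlas validates and custom atlases are checked", {
  part <- default_area_partition()
  expect_equal(nrow(part), 148L)
  expect_equal(length(unique(part$area)), 14L)
  expect_true(all(table(part$area) > 0))
  expect_setequal(unique(sub("^[LR]", "", part$area)),
                  c("VPF", "DPF", "C", "T", "P", "O", "Cing"))
  # a mapping with a missing ROI is rejected, naming the gap
  bad <- part[-10, ]
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_area_partition(path), "1..n")
})
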