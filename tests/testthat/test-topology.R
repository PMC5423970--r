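test_that("excitatory positions form the integer lattice, inhibitory are uniform and reproducible", {
  pos <- build_positions(grid_spec(100), seed = 3)
  expect_equal(sum(pos$pop == "E"), 10000)
  expect_equal(sum(pos$pop == "I"), 2500)
  p2 <- build_positions(grid_spec(2), seed = 1)
  expect_setequal(paste(p2$x[p2$pop == "E"], p2$y[p2$pop == "E"]),
                  c("0 0", "0 1", "1 0", "1 1"))
  expect_identical(build_positions(grid_spec(10), seed = 7),
                   build_positions(grid_spec(10), seed = 7))
  expect_true(all(pos$x[pos$pop == "I"] >= 0 & pos$x[pos$pop == "I"] < 100))
  expect_error(grid_spec(10, n_inh = 30), "n_inh")
})

test_that("torus distance uses the minimal image and is bounded", {
  expect_equal(torus_distance(c(0, 0), c(99, 0), 100), 1)
  expect_equal(torus_distance(c(0, 0), c(50, 50), 100), 50 * sqrt(2))
  expect_equal(torus_distance(c(10, 10), c(13, 14), 100), 5)
  set.seed(4)
  p <- matrix(runif(40, 0, 60), ncol = 2)
  q <- matrix(runif(40, 0, 60), ncol = 2)
  expect_equal(torus_distance(p, q, 60), torus_distance(q, p, 60))
  expect_true(all(torus_distance(p, q, 60) <= 60 * sqrt(2) / 2 + 1e-12))
})

test_that("sampled connectivity has exact in-degrees, no self-connections, linear delays", {
  topo <- fx_topo_small()
  ed <- tidy(topo)
  deg <- ed |> dplyr::count(.data$target_id, .data$source_pop)
  expect_true(all(deg$n[deg$source_pop == "E"] == 20))
  expect_true(all(deg$n[deg$source_pop == "I"] == 10))
  expect_equal(nrow(ed), 125 * 30)  # in-degree conservation
  expect_false(any(ed$target_id == ed$source_id))
  # delay linearity at the conduction velocity
  expect_equal(ed$delay_ms, ed$distance_px / 13000 * 1000)
  d1 <- 13.3 / 13000 * 1000
  expect_equal(26.6 / 13000 * 1000, 2 * d1)
  # determinism
  topo2 <- build_topology(grid_spec(10), kernel_spec(3, 4, K_E = 20, K_I = 10),
                          seed = 1)
  expect_identical(tidy(topo), tidy(topo2))
  # in-degree beyond the population errors out
  expect_error(build_topology(grid_spec(4), kernel_spec(2, 2, K_E = 50, K_I = 2)),
               "in-degree")
})

test_that("source-distance distributions match the kernel oracle for each sigma", {
  # brute-force oracle: normalise exp(-d^2 / 2 sigma^2) over all lattice
  # offsets; sampled with tiny per-target in-degree so that
  # without-replacement depletion is negligible, pooled over many topologies
  L <- 40
  lag1 <- pmin(0:(L - 1), L - (0:(L - 1)))
  offs <- expand.grid(dx = lag1, dy = lag1)[-1, ]  # exclude self
  dall <- sqrt(offs$dx^2 + offs$dy^2)
  pos <- build_positions(grid_spec(L), seed = 5)
  for (sigma in c(5, 10, 15, 25)) {
    w <- exp(-dall^2 / (2 * sigma^2))
    draws <- unlist(lapply(1:25, function(s) {
      topo <- sample_connections(pos, kernel_spec(sigma, sigma, K_E = 2, K_I = 1),
                                 grid_spec(L), seed = 100 * sigma + s)
      topo$distance[rep(c(TRUE, TRUE, FALSE), 2000)][
        topo$target[rep(c(TRUE, TRUE, FALSE), 2000)] <= 1600]
    }))
    breaks <- c(seq(0, 20, by = 1), L * sqrt(2) / 2 + 1e-9)
    p_exp <- tapply(w, cut(dall, breaks), sum)
    p_exp[is.na(p_exp)] <- 0
    p_exp <- p_exp / sum(w)
    obs <- table(cut(draws, breaks))
    keep <- p_exp > 5 / length(draws)
    chi <- sum((obs[keep] - length(draws) * p_exp[keep])^2 /
                 (length(draws) * p_exp[keep]))
    pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("very wide kernels approach the uniform-distance null", {
  L <- 40
  pos <- build_positions(grid_spec(L), seed = 6)
  topo <- sample_connections(pos, kernel_spec(1e6, 1e6, K_E = 30, K_I = 10),
                             grid_spec(L), seed = 7)
  dE <- topo$distance[topo$target <= 1600][rep(c(rep(TRUE, 30), rep(FALSE, 10)), 1600)]
  lag1 <- pmin(0:(L - 1), L - (0:(L - 1)))
  offs <- expand.grid(dx = lag1, dy = lag1)[-1, ]
  dall <- sqrt(offs$dx^2 + offs$dy^2)
  breaks <- c(seq(0, 24, by = 2), L * sqrt(2) / 2 + 1e-9)
  p_exp <- as.numeric(table(cut(dall, breaks))) / nrow(offs)
  obs <- table(cut(dE, breaks))
  chi <- sum((obs - length(dE) * p_exp)^2 / (length(dE) * p_exp))
  pval <- stats::pchisq(chi, df = length(p_exp) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("orientation map has the stated pinwheel count, wraps, and winds by 180 degrees", {
  for (L in c(50, 100)) {
    m <- build_orientation_map(grid_spec(L), 4)
    expect_equal(count_pinwheels(m), 4)
    expect_true(all(m >= -90 & m < 90))
  }
  m <- build_orientation_map(grid_spec(60), 4)
  expect_equal(count_pinwheels(build_orientation_map(grid_spec(60), 16)), 16)
  expect_error(build_orientation_map(grid_spec(60), 5), "n_pinwheels")
  # full-circle walk around a pinwheel centre accumulates +-180 degrees
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  px <- 15 + 6 * cos(th); py <- 15 + 6 * sin(th)  # centre (L/4, L/4)
  po <- orientation_at(m, px, py)
  dphi <- diff(c(2 * po, 2 * po[1]))
  dphi <- ((dphi + 180) %% 360) - 180
  expect_equal(abs(sum(dphi)), 360, tolerance = 1e-6)
  # periodicity: one full period along each axis returns the same value
  expect_equal(orientation_at(m, 7, 11), orientation_at(m, 7 + 60, 11))
  expect_equal(orientation_at(m, 7, 11), orientation_at(m, 7, 11 + 60))
  # off-lattice (inhibitory) positions inherit the nearest lattice value
  expect_equal(orientation_at(m, 12.3, 40.8), m[12 + 1, 41 + 1])
})
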