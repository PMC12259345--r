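# Tissue network: grid geometry, the series/extracellular conductances,
# lambda, and the coupling operator.

test_that("grid geometry and neighbor structure follow the box packing", {
  g <- cell_grid(15, 20)
  expect_equal(g$Am, 2 * pi * g$l * g$d)
  expect_equal(g$delta_i, pi / 4)
  expect_equal(nrow(g$edges), 14 * 20 + 15 * 19)
  # neighbor counts: corners 2, sides 3, interior 4; axial only
  deg <- tabulate(c(g$edges$a, g$edges$b), nbins = g$n_cells)
  co <- grid_coords(g)
  expected <- 4 - (co$x %in% c(1, g$nx)) - (co$y %in% c(1, g$ny))
  expect_identical(deg, as.integer(expected))
  gx <- connection_geometry("x", g)
  gy <- connection_geometry("y", g)
  expect_equal(gx$L, g$l); expect_equal(gx$A, g$d^2)
  expect_equal(gy$L, g$d); expect_equal(gy$A, g$l * g$d)
})

test_that("intercellular conductance follows the series formula", {
  g <- cell_grid(2, 1)
  gx <- connection_geometry("x", g)
  # 600 nS: myoplasmic 795.77 in series with 1666.67 (1/mS)
  expect_equal(intracellular_conductance(gx, 600, g), 4.0610e-4,
               tolerance = 1e-4)
  # infinite gap junction -> pure myoplasmic path
  expect_equal(intracellular_conductance(gx, 1e15, g),
               g$delta_i * gx$A * g$sigma_i / gx$L, tolerance = 1e-6)
  expect_equal(g$delta_i * gx$A * g$sigma_i / gx$L, 1.2566e-3,
               tolerance = 1e-4)
  expect_identical(intracellular_conductance(gx, 0, g), 0)
  expect_error(intracellular_conductance(gx, -1, g), ">= 0")
})

test_that("extracellular conductance matches the direct evaluation", {
  g <- cell_grid(2, 2)
  gx <- connection_geometry("x", g)
  gy <- connection_geometry("y", g)
  expect_equal(extracellular_conductance(gx, g), 1.7168e-3, tolerance = 1e-4)
  # y-direction simplifies to (1 - delta_i) * l * sigma_e
  expect_equal(extracellular_conductance(gy, g),
               (1 - g$delta_i) * g$l * g$sigma_e)
  g1 <- g; g1$delta_i <- 1
  expect_equal(extracellular_conductance(gx, g1), 0)
})

test_that("lambda is the x-direction conductance ratio and is monotone", {
  g <- cell_grid(2, 1)
  lam <- lambda_constant(g, 600)
  expect_equal(lam, 4.228, tolerance = 1e-3)
  expect_equal(lam / (1 + lam), 0.809, tolerance = 1e-3)
  # lambda = Ge,x / Gi,x(Gg*) falls monotonically as the gap junctions open
  # (Gi grows with Gg), approaching (1-delta_i)*sigma_e/(delta_i*sigma_i)
  lams <- vapply(c(2, 4, 6, 60, 600), function(gg) lambda_constant(g, gg), 0)
  expect_true(all(diff(lams) < 0))
  lim <- (1 - g$delta_i) * g$sigma_e / (g$delta_i * g$sigma_i)
  expect_equal(lambda_constant(g, 1e15), lim, tolerance = 1e-6)
  expect_error(lambda_constant(g, 0), "positive")
  expect_error(lambda_constant(g, -5), "positive")
})

test_that("Eq.-4 sanity: lambda * Gi,x equals Ge,x at the average coupling", {
  g <- cell_grid(3, 3)
  gx <- connection_geometry("x", g)
  for (gg in c(4, 60, 600)) {
    lam <- lambda_constant(g, gg)
    expect_equal(lam * intracellular_conductance(gx, gg, g),
                 extracellular_conductance(gx, g), tolerance = 1e-12)
  }
})

test_that("coupling operator: zero on uniform fields, conservative, correct
           on the two-cell hand calculation", {
  g <- cell_grid(4, 3)
  coup <- build_coupling(g, 600)
  expect_equal(coupling_rhs(rep(-80, g$n_cells), coup, g),
               rep(0, g$n_cells))
  set.seed(7)
  v <- runif(g$n_cells, -90, 40)
  contrib <- coupling_rhs(v, coup, g)
  expect_lt(abs(sum(contrib)), 1e-12 * max(abs(contrib)))
  expect_error(coupling_rhs(c(v[-1], NaN), coup, g), "finite")

  # 2-cell unit-tracked hand calculation: v = (0, 10) mV, Gg = 600 nS
  g2 <- cell_grid(2, 1)
  c2 <- build_coupling(g2, 600)
  lam <- c2$lambda
  Gi <- intracellular_conductance(connection_geometry("x", g2), 600, g2)
  # lambda/(1+lambda) * Gi[mS] * dv[mV] / (Cm*Am)[uF] -> mV/ms
  expected1 <- lam / (1 + lam) * Gi * 10 / (g2$Cm * g2$Am)
  expect_equal(expected1, 0.809 * 4.061e-4 * 10 / 1.2566e-4,
               tolerance = 1e-3)
  expect_equal(coupling_rhs(c(0, 10), c2, g2), c(expected1, -expected1))
})

test_that("per-connection variation keeps the matrix symmetric and positive", {
  g <- cell_grid(6, 4)
  sp <- variation_spec(3, gap_level = 0.5, seed = 3)
  gv <- draw_gap_variation(sp, g, 60)
  coup <- build_coupling(g, 60, gv$Gg)
  expect_true(all(coup$edges$Gi > 0))
  expect_true(all(coup$w > 0))
  # one conductance per undirected connection by construction
  expect_equal(nrow(coup$edges), nrow(g$edges))
})

test_that("y-reflection symmetry: reflected inputs give reflected coupling", {
  g <- cell_grid(5, 4)
  coup <- build_coupling(g, 600)
  co <- grid_coords(g)
  perm <- (g$ny - co$y) * g$nx + co$x             # reflected cell index
  set.seed(11)
  v <- runif(g$n_cells, -90, 40)
  out <- coupling_rhs(v, coup, g)
  expect_equal(coupling_rhs(v[perm], coup, g), out[perm])
})
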