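test_that("a minimal two-node network loads and validates", {
  nodes <- tibble::tibble(node = 1:2, x = c(0, 50), y = 0, z = 0)
  vessels <- tibble::tibble(vessel = 1L, from = 1L, to = 2L, diameter = 5)
  net <- capnet(nodes, vessels)
  expect_s3_class(net, "capnet")
  expect_equal(nrow(net$vessels), 1)
  expect_true(all(net$nodes$boundary != "interior"))
  expect_equal(net$vessels$length, 50)
})

test_that("save/load round-trips are lossless in both formats", {
  net <- make_diamond_net()
  for (fmt in c("csv", "json")) {
    path <- file.path(withr::local_tempdir(),
                      if (fmt == "json") "net.json" else "netdir")
    save_network(net, path, format = fmt)
    net2 <- load_network(path, format = fmt)
    expect_equal(net2$nodes$x, net$nodes$x, tolerance = 0)
    expect_equal(net2$vessels$diameter, net$vessels$diameter, tolerance = 0)
    expect_equal(net2$vessels$length, net$vessels$length, tolerance = 0)
    for (k in seq_len(nrow(net$vessels))) {
      expect_equal(net2$vessels$centerline[[k]],
                   unname(net$vessels$centerline[[k]]), tolerance = 0)
    }
  }
})

test_that("structural violations raise errors naming the offender", {
  nodes <- tibble::tibble(node = 1:2, x = c(0, 50), y = 0, z = 0)
  vessels <- tibble::tibble(vessel = 1L, from = 1L, to = 99L, diameter = 5)
  expect_error(capnet(nodes, vessels), "99")
  nodes4 <- tibble::tibble(node = 1:4, x = c(0, 50, 100, 150), y = 0, z = 0)
  disconnected <- tibble::tibble(vessel = 1:2, from = c(1L, 3L),
                                 to = c(2L, 4L), diameter = 5)
  expect_error(capnet(nodes4, disconnected), "disconnected")
  dup <- tibble::tibble(vessel = c(1L, 1L), from = c(1L, 2L), to = c(2L, 3L),
                        diameter = 5)
  nodes3 <- tibble::tibble(node = 1:3, x = c(0, 50, 100), y = 0, z = 0)
  expect_error(capnet(nodes3, dup), "duplicate vessel")
})

test_that("diameter rescaling hits the target moments and the floor", {
  nodes <- tibble::tibble(node = 1:5, x = seq(0, 200, by = 50), y = 0, z = 0)
  vessels <- tibble::tibble(vessel = 1:4, from = 1:4, to = 2:5,
                            diameter = c(3.5, 5, 6.5, 5))
  net <- capnet(nodes, vessels)
  # distribution already at the target and above the floor: unchanged
  d0 <- net$vessels$diameter
  out <- rescale_diameters(net, target_mean = mean(d0),
                           target_sd = stats::sd(d0), floor = 3)
  expect_equal(out$vessels$diameter, d0, tolerance = 1e-12)
  # wide target: the floor binds but no diameter goes below it
  out2 <- rescale_diameters(net, target_mean = 5, target_sd = 4, floor = 3)
  expect_true(all(out2$vessels$diameter >= 3))
  # length sum invariant under rescaling
  expect_equal(sum(out2$vessels$length), sum(net$vessels$length))
  # degenerate zero-variance input becomes the constant target mean
  net$vessels$diameter <- rep(4, 4)
  expect_warning(out3 <- rescale_diameters(net, 5, 1.5, 3), "degenerate")
  expect_equal(out3$vessels$diameter, rep(5, 4))
})

test_that("derived radii follow the ratio and clamping rules", {
  nodes <- tibble::tibble(node = 1:4, x = seq(0, 150, by = 50), y = 0, z = 0)
  vessels <- tibble::tibble(vessel = 1:3, from = 1:3, to = 2:4,
                            diameter = c(4, 10, 3))
  net <- derive_radii(capnet(nodes, vessels))
  expect_equal(net$vessels$r_p, c(2, 5, 1.5))
  # r_p = 2 -> r_c = 1.6, r_w = 2.5
  expect_equal(net$vessels$r_c[1], 1.6)
  expect_equal(net$vessels$r_w[1], 2.5)
  # diameter 10: RBC diameter clamps at 8 -> r_c = 4
  expect_equal(net$vessels$r_c[2], 4)
  # diameter 3: 0.8 * 1.5 = 1.2 -> RBC diameter 2.4 < 3 clamps to r_c = 1.5
  expect_equal(net$vessels$r_c[3], 1.5)
})

test_that("bifurcation classification matches a brute-force in-degree count", {
  y <- make_y_net()
  cls <- classify_bifurcations(y)
  expect_equal(cls$class[cls$vessel == 3], "after_converging")
  expect_equal(attr(cls, "n_converging"), 1)
  chain <- make_chain_net(3)
  cls2 <- classify_bifurcations(chain)
  expect_false(any(cls2$class == "after_converging"))
  net <- quiet_generate(small_stats(40), seed = 3)
  cls3 <- classify_bifurcations(net)
  de <- directed_ends(net)
  live <- de[!de$zero_flow, ]
  brute <- sum(table(live$head[live$head %in%
    net$nodes$node[net$nodes$boundary == "interior"]]) >= 2)
  expect_equal(attr(cls3, "n_converging"), brute)
})

test_that("VTK export writes a polydata file with per-vessel scalars", {
  net <- make_y_net()
  f <- file.path(withr::local_tempdir(), "net.vtk")
  write_network_vtk(net, f)
  txt <- readLines(f)
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^LINES", txt)))
  expect_true(any(grepl("SCALARS diameter", txt)))
})
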