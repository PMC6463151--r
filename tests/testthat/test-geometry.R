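test_that("trabecula profile matches its closed form and clamping", {
  hT <- 0.064; rT <- 0.10
  expect_equal(trabecula_profile(0, hT, rT), hT)           # both factors 1
  expect_equal(trabecula_profile(rT, hT, rT), 0)           # rim
  expect_equal(trabecula_profile(-rT, hT, rT), 0)
  expect_equal(trabecula_profile(0.05, hT, rT),
               hT * 0.75 * exp(-(0.5 / 0.7)^8))            # hand evaluation
  # even, clamped outside the radius, maximal at the center
  x <- seq(-0.2, 0.2, length.out = 201)
  p <- trabecula_profile(x, hT, rT)
  expect_equal(p, rev(p))
  expect_true(all(p[abs(x) >= rT] == 0))
  expect_equal(max(p), hT)
  expect_equal(x[which.max(p)], 0)
  expect_error(trabecula_profile(0, hT, rT = 0), "rT")
  expect_error(trabecula_profile(0, hT = -1, rT), "hT")
})

test_that("geometry parameter validation enforces the model invariants", {
  expect_error(geometry_params(aV = -1), "positive")
  expect_error(geometry_params(hT = 0.9), "bV")
  expect_error(geometry_params(wAV = 0.8, wSV = 0.7), "wAV == wSV")
  gp <- geometry_params()
  expect_equal(gp$aV, 1.0)
  expect_equal(gp$bV, 0.8)
  expect_equal(gp$wAV, 0.8)
  expect_equal(gp$rT, 0.10)
})

test_that("smooth chamber boundary matches the analytic half-ellipse", {
  h <- 0.05
  cv <- build_idealized_chamber(geometry_params(hT = 0), h)
  expect_s3_class(cv, "boundary_curve")
  lay <- cv$layout
  arc <- cv$points[cv$labels == "chamber-wall", ]
  expect_gt(nrow(arc), 50)
  # every arc point on the ellipse ((x-xc)/aV)^2 + ((y-y_top)/bV)^2 = 1
  r <- ((arc[, 1] - lay$xc) / 1.0)^2 + ((arc[, 2] - lay$y_top) / 0.8)^2
  expect_lt(max(abs(sqrt(r) - 1)), cv$ds)
  expect_equal(sum(grepl("trabecula", cv$labels)), 0)
})

test_that("trabeculated chamber has the full region-label partition", {
  cv <- cached_chamber(0.08)
  labs <- cv$labels
  expect_true(all(nzchar(labs)))
  expect_equal(length(unique(labs[grepl("^trabecula\\[", labs)])), 6)
  # 5 interior valleys + 2 flanking regions
  expect_equal(length(unique(labs[grepl("^intertrabecular", labs)])), 7)
  # consecutive spacing within [0.5 ds, 1.5 ds] along the top curve
  top <- cv$points[cv$segment == "top", ]
  seg <- sqrt(diff(top[, 1])^2 + diff(top[, 2])^2)
  expect_true(all(seg > 0.5 * cv$ds & seg < 1.5 * cv$ds))
  # normals are unit length
  expect_equal(rowSums(cv$normals^2), rep(1, nrow(cv$points)), tolerance = 1e-8)
})

test_that("trabecula segments have the arc length of the ridge profile", {
  cv <- cached_chamber(0.08)
  hT <- 0.064; rT <- 0.10; aV <- 1; bV <- 0.8
  # independent oracle: rebuild each ridge by fine quadrature -- ellipse
  # arc plus the profile applied along the inward normal (which slightly
  # compresses arc length on the concave side of a curved wall) -- and
  # measure its length over the labeled support
  th <- seq(pi, 0, length.out = 40001)
  ax <- 3.2 + aV * cos(th); ay <- 1.6 + bV * sin(th)
  s <- c(0, cumsum(sqrt(diff(ax)^2 + diff(ay)^2)))
  L <- s[length(s)]
  nlen <- sqrt((bV * cos(th))^2 + (aV * sin(th))^2)
  nx <- -bV * cos(th) / nlen; ny <- -aV * sin(th) / nlen
  for (k in c(1, 3, 6)) {
    ck <- L * (2 * k - 1) / 12
    height <- trabecula_profile(s - ck, hT, rT)
    px <- ax + height * nx; py <- ay + height * ny
    on_seg <- abs(s - ck) <= rT
    expected <- sum(sqrt(diff(px[on_seg])^2 + diff(py[on_seg])^2))
    seg_pts <- cv$points[cv$labels == sprintf("trabecula[%d]", k), ]
    got <- sum(sqrt(diff(seg_pts[, 1])^2 + diff(seg_pts[, 2])^2))
    # the discretized segment loses up to one spacing at each end
    expect_equal(got, expected, tolerance = 0.05 + 2 * cv$ds / expected)
  }
})

test_that("doubling grid resolution doubles boundary point counts", {
  cv1 <- build_idealized_chamber(geometry_params(hT = 0.064), 0.05)
  cv2 <- build_idealized_chamber(geometry_params(hT = 0.064), 0.025)
  n1_top <- sum(cv1$segment == "top")
  n2_top <- sum(cv2$segment == "top")
  expect_lt(abs(n2_top - 2 * n1_top), 5)
  n1_bot <- sum(cv1$segment == "bottom")
  n2_bot <- sum(cv2$segment == "bottom")
  expect_lt(abs(n2_bot - 2 * n1_bot), 5)
})

test_that("trabecula overlap is rejected", {
  expect_error(
    build_idealized_chamber(geometry_params(hT = 0.05, rT = 0.25, n_trab = 6),
                            0.05),
    "overlap")
})

test_that("synthetic ventricles are reproducible and labeled", {
  spec <- synthetic_ventricle_spec(n_trab = 6, depth_mean = 0.08, seed = 42)
  a <- build_synthetic_ventricle(spec)
  b <- build_synthetic_ventricle(spec)
  expect_identical(a$points, b$points)
  expect_identical(a$labels, b$labels)
  expect_equal(length(unique(grep("^trabecula\\[", a$labels, value = TRUE))), 6)

  smooth <- build_synthetic_ventricle(synthetic_ventricle_spec(depth_mean = 0))
  expect_equal(sum(grepl("trabecula", smooth$labels)), 0)
})

test_that("synthetic trabeculae appear as curvature features", {
  spec <- synthetic_ventricle_spec(n_trab = 6, depth_mean = 0.08,
                                   depth_sd = 0.01, seed = 7)
  cv <- build_synthetic_ventricle(spec)
  # each labeled protrusion contains a local radius minimum relative to
  # its surroundings (protrusions point inward)
  ctr <- cv$center
  r <- sqrt((cv$points[, 1] - ctr[1])^2 + (cv$points[, 2] - ctr[2])^2)
  for (k in 1:6) {
    on_k <- grepl(sprintf("^trabecula\\[%d\\]$", k), cv$labels)
    if (!any(on_k)) next
    near <- grepl("^intertrabecular", cv$labels)
    expect_lt(min(r[on_k]), mean(r[near]))
  }
})

test_that("vertex files round-trip points and labels", {
  cv <- cached_chamber(0.08)
  f <- tempfile(fileext = ".vertex")
  write_vertex_file(cv, f)
  back <- read_vertex_file(f)
  expect_equal(back$points, unname(cv$points), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$labels, cv$labels)
  expect_equal(back$ds, cv$ds)
})
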