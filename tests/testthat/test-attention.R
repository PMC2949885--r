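test_that("otsu_threshold separates a clean bimodal map", {
  set.seed(2)
  v <- sample(c(rep(10, 900), rep(200, 100)))
  m <- matrix(v, 25, 40)
  mask <- otsu_threshold(m)
  expect_equal(as.vector(mask), as.vector(m > 100))
  expect_equal(sum(mask), sum(m > attr(mask, "threshold")))
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("fill_holes is a disc closing and never removes foreground", {
  rr <- row(matrix(0, 40, 40)); cc <- col(matrix(0, 40, 40))
  d2 <- (rr - 20)^2 + (cc - 20)^2
  disc <- d2 <= 12^2
  expect_identical(fill_holes(disc, 5), disc)      # solid: unchanged
  annulus <- disc & d2 >= 4^2                      # hole radius 4 < 2 * 5
  expect_identical(fill_holes(annulus, 5), brute_closing(annulus, 5))
  expect_true(all(fill_holes(annulus, 5)[disc]))   # hole is filled
  empty <- matrix(FALSE, 10, 10)
  expect_identical(fill_holes(empty, 5), empty)
  # extensivity on random blobs
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(900) > 0.7, 30, 30)
    expect_true(all(fill_holes(m, 2)[m]))
  }
})

test_that("remove_small_regions applies the strict-below-threshold rule", {
  m <- matrix(FALSE, 100, 100)
  m[10:34, 10:29] <- TRUE    # 500 px
  m[60:79, 60:69] <- TRUE    # 200 px
  res <- remove_small_regions(m, 0.03)  # threshold 300 px
  expect_equal(sum(res$mask), 500)
  expect_identical(res$ids, 1L)
  # exactly at threshold: survives
  m2 <- matrix(FALSE, 100, 100); m2[1:30, 1:10] <- TRUE  # 300 px
  expect_equal(sum(remove_small_regions(m2, 0.03)$mask), 300)
  # all regions small: empty result
  m3 <- matrix(FALSE, 100, 100); m3[1:5, 1:5] <- TRUE
  res3 <- remove_small_regions(m3, 0.03)
  expect_equal(sum(res3$mask), 0)
  expect_length(res3$ids, 0)
  # labeling is 8-connected: a diagonal chain is one region
  m4 <- matrix(FALSE, 10, 10); m4[cbind(1:10, 1:10)] <- TRUE
  expect_equal(max(cellcarve:::cpp_label8(m4)), 1L)
})

test_that("initial_windows are per-component bounding boxes", {
  lab <- matrix(0L, 60, 80)
  lab[21:30, 31:40] <- 1L
  w <- initial_windows(lab)
  expect_equal(unlist(w[1, c("x", "y", "width", "height")]),
               c(x = 31, y = 21, width = 10, height = 10))
  # two components, ordered by label
  lab[5:8, 60:70] <- 2L
  w2 <- initial_windows(lab)
  expect_equal(w2$label, c(1, 2))
  expect_equal(w2$width, c(10, 11))
  # L-shaped component: tight bounding box of member pixels
  labL <- matrix(0L, 20, 20)
  labL[5:15, 5] <- 1L; labL[15, 5:12] <- 1L
  wL <- initial_windows(labL)
  expect_equal(unlist(wL[1, c("x", "y", "width", "height")]),
               c(x = 5, y = 5, width = 8, height = 11))
})

test_that("fit_ellipse centers on the window and clips to the image", {
  w <- data.frame(label = 1L, x = 31, y = 21, width = 10, height = 10)
  e <- fit_ellipse(w, c(60, 80))
  expect_equal(c(e$cx, e$cy, e$rx, e$ry), c(35.5, 25.5, 5, 5))
  e2 <- fit_ellipse(data.frame(label = 1, x = 11, y = 11, width = 40,
                               height = 20), c(60, 80))
  expect_equal(c(e2$rx, e2$ry), c(20, 10))
  # window flush with the border: semi-axes shrink to stay inside
  e3 <- fit_ellipse(data.frame(label = 1, x = 1, y = 1, width = 10,
                               height = 10), c(60, 80))
  expect_true(e3$cx - e3$rx >= 0.5 && e3$cy - e3$ry >= 0.5)
})

test_that("eaw_strength is the distance transform of the ellipse union", {
  # disc of radius 20: raw center distance ~ 20, zero outside
  e <- data.frame(label = 1, cx = 30, cy = 30, rx = 20, ry = 20)
  raw <- eaw_strength(e, c(60, 60), normalize = FALSE)
  expect_equal(raw[30, 30], 20, tolerance = 1)
  outside <- ((col(raw) - 30) / 20)^2 + ((row(raw) - 30) / 20)^2 >= 1
  expect_true(all(raw[outside] == 0))
  expect_true(all(raw[!outside] > 0))
  # normalized version peaks at 255
  norm <- eaw_strength(e, c(60, 60))
  expect_equal(max(norm), 255)
  expect_equal(which.max(norm), which.max(raw))
  # two disjoint ellipses: independent peaks, valley of zeros between
  e2 <- data.frame(label = 1:2, cx = c(15, 45), cy = c(30, 30),
                   rx = c(8, 8), ry = c(12, 12))
  raw2 <- eaw_strength(e2, c(60, 60), normalize = FALSE)
  expect_gt(raw2[30, 15], 0)
  expect_gt(raw2[30, 45], 0)
  expect_equal(raw2[30, 30], 0)
  # empty list: zero map with a warning
  expect_warning(
    z <- eaw_strength(data.frame(cx = numeric(0), cy = numeric(0),
                                 rx = numeric(0), ry = numeric(0)),
                      c(20, 20)),
    "no elliptical")
  expect_equal(max(z), 0)
})

test_that("the exact EDT matches brute force on random masks", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- matrix(runif(30 * 25) > 0.45, 30, 25)
    m[1, 1] <- FALSE   # keep at least one background pixel
    expect_equal(cellcarve:::cpp_edt(m), brute_edt(m), tolerance = 1e-12)
  }
  # all-foreground columns must not break the transform
  m <- matrix(TRUE, 20, 20); m[10, 10] <- FALSE
  expect_equal(cellcarve:::cpp_edt(m), brute_edt(m), tolerance = 1e-12)
})

test_that("detection recovers the nuclei of a small synthetic smear", {
  sm <- generate_smear(small_spec(seed = 2))
  cm <- saliency_map(sm$image)
  f <- mean(dim(cm) / c(600, 800))
  det <- detect_eaws(cm, closing_radius = max(1, 5 * f))
  expect_equal(nrow(det$eaws), length(sm$truth$masks))
  for (k in seq_len(nrow(det$eaws))) {
    e <- det$eaws[k, ]
    inside <- vapply(sm$truth$masks, function(m)
      m[round(e$cy), round(e$cx)], logical(1))
    expect_true(any(inside))
  }
  # Otsu foreground fraction within +-50% of the true nucleus fraction
  truth_frac <- mean(Reduce(`|`, sm$truth$masks))
  fg <- mean(otsu_threshold(cm))
  expect_gt(fg, truth_frac * 0.5)
  expect_lt(fg, truth_frac * 1.5)
})
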