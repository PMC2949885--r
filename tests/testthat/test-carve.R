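test_that("forward costs match hand evaluation", {
  # constant raster: every cost vanishes
  const <- matrix(42, 5, 5)
  expect_equal(unname(forward_costs(const, 3, 3)), c(0, 0, 0))
  # hand case: right 10, left 4, upper 7 -> cU 6, cL 9, cR 9
  v <- matrix(0, 3, 3)
  v[2, 3] <- 10; v[2, 1] <- 4; v[1, 2] <- 7
  expect_equal(forward_costs(v, 2, 2),
               c(cL = 9, cU = 6, cR = 9))
  # left border: out-of-range differences contribute 0
  expect_equal(unname(forward_costs(v, 2, 1)),
               unname(c(0, 0, 0 + abs(v[1, 1] - v[2, 2]))))
  # brute-force agreement at every interior/border position
  x <- rand_mat(6, 7, seed = 50)
  for (i in 1:6) for (j in 1:7)
    expect_equal(forward_costs(x, i, j), brute_step(x, i, j))
})

test_that("cost matrix satisfies the recurrence and trivial cases", {
  # one row: M equals the local gradient term
  row1 <- matrix(c(5, 1, 8, 2), 1, 4)
  m <- build_cost_matrix(row1)
  expect_equal(m$values, ssm_gradient(row1))
  # constant raster: everything zero
  mc <- build_cost_matrix(matrix(7, 6, 6))
  expect_equal(max(abs(mc$values)), 0)
  # P term matches the independent gradient oracle
  x <- rand_mat(9, 11, seed = 51)
  expect_equal(ssm_gradient(x), brute_grad(x), tolerance = 1e-12)
  expect_equal(build_cost_matrix(x)$values[1, ], brute_grad(x)[1, ])
})

test_that("minimum seam equals exhaustive path enumeration", {
  set.seed(60)
  for (rep in 1:40) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    v <- matrix(runif(h * w, 0, 255), h, w)
    m <- build_cost_matrix(v)
    seam <- find_min_seam(m)
    expect_equal(min(m$values[h, ]), brute_min_seam_cost(v),
                 tolerance = 1e-9)
    # the traced seam is monotone, connected, and realizes the DP cost
    expect_true(all(abs(diff(seam)) <= 1))
    expect_equal(m$values[h, seam[h]], min(m$values[h, ]))
  }
})

test_that("seam selection honors corridors and the leftmost tie rule", {
  # a flat corridor in a noisy field: column 5 is the only column whose
  # local gradient and step costs all vanish
  set.seed(55)
  v <- matrix(runif(90, 0, 255), 10, 9)
  v[, 4:6] <- 0
  seam <- find_min_seam(build_cost_matrix(v))
  expect_true(all(seam == 5))
  # full tie: leftmost column wins
  seam0 <- find_min_seam(build_cost_matrix(matrix(3, 8, 6)))
  expect_true(all(seam0 == 1))
  # 1-column image: the only possible seam
  seam1 <- find_min_seam(build_cost_matrix(matrix(1:5, 5, 1)))
  expect_true(all(seam1 == 1))
})

test_that("remove_seam does exact pixel bookkeeping", {
  a <- array(1:27, c(3, 3, 3))
  img <- rgb_image((a %% 200))
  out <- remove_seam(img, c(2L, 2L, 2L))
  expect_equal(dim(out), c(3L, 2L, 3L))
  expect_equal(unclass(out)[, , 1], unclass(img)[, c(1, 3), 1])
  # conservation: H fewer pixels per channel
  expect_equal(length(out), length(img) - 3 * 3)
  # removing W - 1 seams leaves a single column
  m <- rand_mat(4, 5, seed = 70)
  for (k in 1:4) m <- remove_seam(m, find_min_seam(build_cost_matrix(m)))
  expect_equal(dim(m), c(4L, 1L))
})

test_that("gradient_energy matches central-difference arithmetic", {
  expect_equal(gradient_energy(rgb_image(array(9, c(8, 8, 3)))),
               matrix(0, 8, 8))
  # horizontal ramp in luminance: interior gradient exactly 1
  ramp <- matrix(rep(0:19, each = 12), 12, 20)
  g <- gradient_energy(rgb_image(array(rep(ramp, 3), c(12, 20, 3))))
  expect_equal(g[2:11, 2:19], matrix(1, 10, 18))
  # vertical step edge: maxima on the two adjacent columns
  st <- matrix(0, 10, 10); st[, 6:10] <- 100
  gs <- gradient_energy(rgb_image(array(rep(st, 3), c(10, 10, 3))))
  expect_true(all(which(gs == max(gs), arr.ind = TRUE)[, 2] %in% c(5, 6)))
})

test_that("auto_target_size implements both extent policies", {
  e <- data.frame(label = 1, cx = 200, cy = 150, rx = 100, ry = 50)
  # one EAW spanning columns 100..300 plus 2 * 10 margin
  expect_equal(auto_target_size(e, c(600, 800), margin = 10),
               c(height = 120, width = 220))
  # EAWs spanning the full width: clamp to the image
  wide <- data.frame(label = 1, cx = 400, cy = 300, rx = 400, ry = 40)
  expect_equal(auto_target_size(wide, c(600, 800), margin = 10)[["width"]],
               800L)
  # two EAWs: union span vs sum of extents
  e2 <- data.frame(label = 1:2, cx = c(100, 650), cy = c(100, 100),
                   rx = c(50, 50), ry = c(30, 30))
  expect_equal(auto_target_size(e2, c(600, 800), margin = 10)[["width"]],
               670L)   # union span 50..700 (650) plus 2 * 10 margin
  expect_equal(auto_target_size(e2, c(600, 800), margin = 10,
                                policy = "extent-sum")[["width"]],
               220L)   # 100 + 100 + 2 * 10
  expect_error(auto_target_size(e[0, ], c(600, 800)), "no elliptical")
})

test_that("seam carving hits the target and preserves surviving pixels", {
  set.seed(80)
  img <- rgb_image(array(runif(40 * 50 * 3, 0, 255), c(40, 50, 3)))
  energy <- rand_mat(40, 50, seed = 81)
  res <- seam_carve(img, c(30, 35), energy)
  expect_equal(dim(res$image)[1:2], c(30L, 35L))
  expect_equal(length(res$seams), 10 + 15)
  # every surviving pixel keeps its original value bit-exactly
  a0 <- unclass(img); a1 <- unclass(res$image)
  for (k in 1:3)
    expect_identical(as.vector(a1[, , k]),
                     a0[cbind(as.vector(res$orig_rows),
                              as.vector(res$orig_cols), k)])
  # strict alternation while both dimensions shrink
  orients <- vapply(res$seams, `[[`, "", "orientation")
  expect_equal(orients[1:20], rep(c("vertical", "horizontal"), 10))
  # idempotence: carving to the reached size is the identity
  res2 <- seam_carve(res$image, c(30, 35), res$energy)
  expect_identical(unclass(res2$image), unclass(res$image))
  expect_length(res2$seams, 0)
  # target larger than source is refused
  expect_error(seam_carve(res$image, c(50, 60), res$energy), "insertion")
})

test_that("seams avoid a high plateau when a corridor exists", {
  v <- matrix(0, 40, 40)
  plateau <- ((col(v) - 15) / 8)^2 + ((row(v) - 20) / 12)^2 < 1
  v[plateau] <- 200
  for (rep in 1:5) {
    seam <- find_min_seam(build_cost_matrix(v))
    expect_false(any(plateau[cbind(1:40, seam)]))
    v <- remove_seam(v, seam)
    plateau <- remove_seam(plateau * 1, seam) > 0.5
  }
})
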