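# Habitat covariate layers and the transition-model design matrix.

test_that("NDVI follows its definition and bounds", {
  expect_equal(ndvi(matrix(0.2), matrix(0.6))[1, 1], 0.5)
  expect_equal(ndvi(matrix(0.4), matrix(0.4))[1, 1], 0)
  expect_true(is.na(ndvi(matrix(0), matrix(0))[1, 1]))
  expect_error(ndvi(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(ndvi(matrix(-0.1), matrix(0.5)), ">= 0")
  set.seed(11)
  r <- matrix(runif(400, 0.01, 1), 20)
  n <- matrix(runif(400, 0.01, 1), 20)
  v <- ndvi(r, n)
  expect_true(all(v >= -1 & v <= 1))
})

test_that("K-means vegetation classes are ordered by density", {
  # two well-separated clumps
  x <- c(rep(0.1, 500), rep(0.9, 500)) + rnorm(1000, 0, 1e-4)
  km <- kmeans_classify(x, K = 2, seed = 1)
  expect_equal(sort(unique(km$veg_class)), c(0, 1))
  expect_equal(km$class_means, c(0.1, 0.9), tolerance = 1e-3)
  expect_true(all(km$veg_class[x > 0.5] == 1))
  # class means strictly increasing for larger K
  set.seed(12)
  v <- runif(2000)
  km <- kmeans_classify(v, K = 6, seed = 3)
  expect_true(all(diff(km$class_means) > 0))
  # determinism given seed
  km2 <- kmeans_classify(v, K = 6, seed = 3)
  expect_identical(km$veg_class, km2$veg_class)
  # degenerate inputs
  expect_error(kmeans_classify(rep(0.5, 100), K = 2), "distinct")
  expect_error(kmeans_classify(runif(100), K = 1), ">= 2")
})

test_that("1-D K-means attains the optimal threshold partition", {
  # the 1-D 2-means optimum is a contiguous split: brute-force all splits
  set.seed(13)
  x <- runif(20)
  km <- kmeans_classify(x, K = 2, seed = 5)
  wss <- function(v) sum((v - mean(v))^2)
  xs <- sort(x)
  best <- min(vapply(1:19, function(i)
    wss(xs[1:i]) + wss(xs[(i + 1):20]), numeric(1)))
  got <- wss(x[km$veg_class == 0]) + wss(x[km$veg_class == 1])
  expect_equal(got, best, tolerance = 1e-10)
})

test_that("distance to woodland edge matches brute force and its bounds", {
  set.seed(14)
  mask <- matrix(rbinom(2500, 1, 0.06), 50, 50)
  if (sum(mask) == 0) mask[17, 31] <- 1
  ls <- landscape_raster(list(woodland_mask = mask), resolution = 30)
  D <- distance_to_edge(ls)
  # brute-force all-pairs oracle on cell centers
  wood <- which(mask != 0, arr.ind = TRUE)
  for (cell in list(c(1, 1), c(25, 40), c(50, 50), c(13, 2))) {
    ref <- 30 * sqrt(min((wood[, 1] - cell[1])^2 + (wood[, 2] - cell[2])^2))
    expect_equal(D[cell[1], cell[2]], ref, tolerance = 1e-9)
  }
  expect_true(all(D >= 0))
  expect_true(all(D[mask == 1] == 0))
  # 1-Lipschitz between neighboring cell centers (<= cell size)
  expect_true(all(abs(diff(D)) <= 30 + 1e-9))
  expect_true(all(abs(t(diff(t(D)))) <= 30 + 1e-9))
  # full-grid agreement with brute force
  ref_all <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    ref_all[i, j] <- 30 * sqrt(min((wood[, 1] - i)^2 + (wood[, 2] - j)^2))
  expect_equal(D, ref_all, tolerance = 1e-9)
})

test_that("point-form distance to edge handles interior and lateral cases", {
  mask <- matrix(0, 10, 10)
  mask[3, 3] <- 1
  ls <- landscape_raster(list(woodland_mask = mask), resolution = 30)
  # point inside a woodland cell
  expect_equal(distance_to_edge(ls, points = cbind(x = 75, y = 75)), 0)
  # nearest woodland cell center two cells away laterally: 60 m
  expect_equal(
    distance_to_edge(ls, points = cbind(x = 135, y = 75)), 60)
  expect_error(distance_to_edge(
    landscape_raster(list(woodland_mask = matrix(0, 5, 5))), points = NULL),
    "empty")
})

test_that("covariate sampling uses the containing cell", {
  vals <- matrix(as.numeric(1:9), 3, 3)
  ls <- landscape_raster(list(v = vals), resolution = 10)
  tracks <- data.frame(animal_id = "A", night = 1, slot = 1:4,
                       x = c(5, 15, 29.9, NA), y = c(5, 25, 29.9, 5))
  out <- attach_covariates(tracks, ls, layers = "v")
  expect_equal(out$v, c(vals[1, 1], vals[2, 3], vals[3, 3], NA))
  # outside the extent: NA with a warning
  tracks$x[4] <- 1000; tracks$y[4] <- 5
  expect_warning(out <- attach_covariates(tracks, ls, layers = "v"),
                 "outside")
  expect_true(is.na(out$v[4]))
  # cell centers give that cell's value exactly
  expect_equal(raster_extract(ls, "v", 15, 15), vals[2, 2])
})

test_that("simulator tracks stay covariate-complete on their own landscape", {
  s <- small_sim()
  tr <- s$tracks
  present <- !is.na(tr$x)
  # gps error is 0 in this fixture, so all present fixes are in-extent
  expect_false(anyNA(tr$veg_class[present]))
  expect_false(anyNA(tr$canopy_pct[present]))
  expect_false(anyNA(tr$dist_edge[present]))
})

test_that("design matrices code covariates as specified", {
  set.seed(15)
  d <- data.frame(animal_id = "A", night = 1, slot = 1:120,
                  canopy = runif(120, 0, 100),
                  sex = sample(c("F", "M"), 120, replace = TRUE),
                  veg = sample(c(0, 1, 2, 3), 120, replace = TRUE))
  des <- build_design(d, numeric = "canopy", categorical = c("veg", "sex"),
                      merge_rare = 0)
  # intercept first; K-1 indicators for a 4-level factor; 1 for sex
  expect_equal(des$colnames[1], "(Intercept)")
  expect_equal(sum(grepl("^veg", des$colnames)), 3)
  expect_equal(sum(grepl("^sex", des$colnames)), 1)
  # sex reference F: indicator is 1 exactly for males
  expect_equal(des$X[, "sexM"], as.numeric(d$sex == "M"))
  # standardized numeric column: mean 0, sd 1
  expect_equal(mean(des$X[, "canopy"]), 0, tolerance = 1e-12)
  expect_equal(sd(des$X[, "canopy"]), 1, tolerance = 1e-12)
  # prediction on new data with an unseen level errors, naming the level
  d2 <- d[1:4, ]
  d2$veg <- c(0, 1, 9, 2)
  expect_error(design_matrix(des, d2), "'9'")
})

test_that("rare vegetation classes merge into their nearest neighbor", {
  d <- data.frame(animal_id = "A", night = 1, slot = 1:200,
                  veg = c(rep(0, 90), rep(1, 95), rep(3, 15)))
  des <- build_design(d, categorical = "veg", merge_rare = 50)
  # class 3 (15 slots) merges into class 1, leaving a single indicator
  expect_equal(sort(unique(des$merge_map$veg)), c("0", "1"))
  expect_equal(unname(des$merge_map$veg["3"]), "1")
  expect_equal(sum(grepl("^veg", des$colnames)), 1)
})
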